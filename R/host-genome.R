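#' Simulate a host genome with gene annotation
#'
#' Generates i.i.d. uniform ACGT scaffolds and places non-overlapping gene
#' intervals so that the genic fraction of each scaffold equals
#' `geneDensity` to within one base (gene lengths are drawn around
#' `geneMeanLen` and the final gene is truncated to hit the target exactly;
#' intergenic space is split randomly among the gaps). Deterministic for a
#' given seed.
#'
#' @param nScaffolds number of scaffolds (0 gives a valid empty genome).
#' @param scaffoldLengths integer vector of scaffold lengths (>= 1 kb),
#'   recycled to `nScaffolds`.
#' @param geneDensity target genic fraction per scaffold, in \[0, 1\].
#' @param seed integer seed (required).
#' @param geneMeanLen,geneSdLen,minGeneLen gene-length model (nt).
#' @return a [HostGenome] object.
#' @export
generateHostGenome <- function(nScaffolds, scaffoldLengths, geneDensity = 0.4,
                               seed, geneMeanLen = 2000, geneSdLen = 400,
                               minGeneLen = 200) {
  nScaffolds <- as.integer(nScaffolds)
  if (nScaffolds < 0L) stop("nScaffolds must be >= 0")
  if (geneDensity < 0 || geneDensity > 1) stop("geneDensity must be in [0,1]")
  if (nScaffolds == 0L) {
    return(new("HostGenome", seqs = DNAStringSet(),
               genes = GRanges(seqinfo = Seqinfo())))
  }
  scaffoldLengths <- as.integer(rep_len(scaffoldLengths, nScaffolds))
  if (any(scaffoldLengths < 1000L))
    stop("scaffold lengths must be >= 1000 nt")
  withSeed(seed, {
    nm <- sprintf("scaffold_%02d", seq_len(nScaffolds))
    seqs <- DNAStringSet(vapply(scaffoldLengths, randomDNA, character(1)))
    names(seqs) <- nm
    grl <- lapply(seq_len(nScaffolds), function(i) {
      L <- scaffoldLengths[i]
      target <- floor(geneDensity * L)
      if (target < minGeneLen) return(NULL)
      lens <- integer()
      tot <- 0L
      while (tot < target) {
        l <- max(minGeneLen, as.integer(round(rnorm(1, geneMeanLen, geneSdLen))))
        l <- min(l, target - tot)
        if (l > 0L && l < minGeneLen && length(lens)) {
          # fold a too-small remainder into the previous gene
          lens[length(lens)] <- lens[length(lens)] + l
          tot <- tot + l
        } else if (l > 0L) {
          lens <- c(lens, l); tot <- tot + l
        } else break
      }
      ngene <- length(lens)
      intergenic <- L - sum(lens)
      gaps <- as.vector(stats::rmultinom(1, intergenic, rep(1, ngene + 1L)))
      starts <- cumsum(c(1L, lens[-ngene])) + cumsum(gaps[-(ngene + 1L)])
      data.frame(scaffold = nm[i], start = starts, end = starts + lens - 1L,
                 strand = sample(c("+", "-"), ngene, replace = TRUE))
    })
    gdf <- do.call(rbind, grl)
    genes <- if (is.null(gdf) || nrow(gdf) == 0L) {
      GRanges(seqinfo = Seqinfo(nm, scaffoldLengths))
    } else {
      g <- GRanges(gdf$scaffold, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand,
                   seqinfo = Seqinfo(nm, scaffoldLengths))
      mcols(g)$ID <- sprintf("gene_%05d", seq_along(g))
      mcols(g)$type <- "gene"
      g
    }
    new("HostGenome", seqs = seqs, genes = genes)
  })
}

#' Write a host genome as FASTA + GFF3
#'
#' @param host a [HostGenome].
#' @param fastaPath,gffPath output paths.
#' @export
writeHostGenome <- function(host, fastaPath, gffPath) {
  writeXStringSet(hostSeqs(host), fastaPath)
  g <- hostGenes(host)
  if (is.null(mcols(g)$type) && length(g)) mcols(g)$type <- "gene"
  mcols(g)$source <- "himseek"
  rtracklayer::export(g, gffPath, format = "gff3")
  invisible(c(fasta = fastaPath, gff = gffPath))
}

#' Read a host genome from FASTA + GFF3, validating gene bounds
#'
#' Features lying outside their scaffold (or on unknown scaffolds) are
#' rejected with their coordinates in the error message.
#'
#' @param fastaPath,gffPath input paths.
#' @return a [HostGenome].
#' @export
readHostGenome <- function(fastaPath, gffPath = NULL) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genes <- if (is.null(gffPath)) {
    GRanges(seqinfo = Seqinfo(names(seqs), width(seqs)))
  } else {
    g <- rtracklayer::import(gffPath, format = "gff3")
    g <- g[is.null(mcols(g)$type) | as.character(mcols(g)$type) %in%
             c("gene", NA)]
    bad <- !(as.character(seqnames(g)) %in% names(seqs))
    oob <- !bad & (start(g) < 1L |
                     end(g) > setNames(width(seqs), names(seqs))[
                       as.character(seqnames(g))])
    if (any(bad | oob))
      stop("GFF3 features out of bounds or on unknown scaffolds: ",
           paste(sprintf("%s:%d-%d", as.character(seqnames(g))[bad | oob],
                         start(g)[bad | oob], end(g)[bad | oob]),
                 collapse = ", "), call. = FALSE)
    g2 <- GRanges(as.character(seqnames(g)), IRanges(start(g), end(g)),
                  strand = strand(g),
                  seqinfo = Seqinfo(names(seqs), width(seqs)))
    mcols(g2)$ID <- mcols(g)$ID %||% sprintf("gene_%05d", seq_along(g2))
    mcols(g2)$type <- "gene"
    g2
  }
  new("HostGenome", seqs = seqs, genes = genes)
}
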