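## Host insertion landscape: where do integrated circles land? Genic vs
## intergenic preference per circle, insertion-event counts in fixed-width
## windows, and an information-content scan of the host flanks.

#' Collapse chimera host junctions into insertion sites and annotate them
#'
#' Host-side junction positions of the same circle lying within `clusterTol`
#' nt on one scaffold are merged into a single insertion site with summed
#' read support (duplicate-read collapse). Each site is annotated genic when
#' it falls within any gene interval, and per-circle genic fractions are
#' compared against the genome-wide genic fraction as background.
#'
#' @param chimeras chimera table from [extractChimeras()].
#' @param host a [HostGenome] (scaffold lengths + gene annotation), or a
#'   [GenomicRanges::GRanges] of genes with seqlengths set.
#' @param clusterTol merge distance in nt.
#' @return list with `sites` (a [GenomicRanges::GRanges]; mcols: circle_id,
#'   support, annotation), `perCircle` (data.frame of genic fractions) and
#'   `backgroundGenicFraction`.
#' @export
annotateSites <- function(chimeras, host, clusterTol = 3) {
  genes <- if (is(host, "HostGenome")) hostGenes(host) else host
  sl <- seqlengths(genes)
  if (nrow(chimeras)) {
    bad <- setdiff(unique(chimeras$host_scaffold), names(sl))
    if (length(bad))
      stop("chimera scaffolds missing from the annotation: ",
           paste(bad, collapse = ", "))
  }
  key <- paste(chimeras$circle_id, chimeras$host_scaffold)
  rows <- lapply(unique(key), function(kk) {
    sel <- which(key == kk)
    pos <- sort(chimeras$host_junction_pos[sel])
    cl <- cumsum(c(TRUE, diff(pos) > clusterTol))
    repPos <- vapply(split(pos, cl), function(p) {
      t <- table(p)
      as.integer(names(t)[which.max(t)])
    }, integer(1))
    data.frame(circle_id = chimeras$circle_id[sel[1]],
               scaffold = chimeras$host_scaffold[sel[1]],
               pos = unname(repPos), support = tabulate(cl),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(circle_id = character(), scaffold = character(),
               pos = integer(), support = integer())
  sites <- GRanges(df$scaffold, IRanges(df$pos, width = 1L),
                   seqinfo = Seqinfo(names(sl), unname(sl)))
  mcols(sites)$circle_id <- df$circle_id
  mcols(sites)$support <- df$support
  mcols(sites)$annotation <- ifelse(countOverlaps(sites, genes) > 0L,
                                    "genic", "intergenic")
  bg <- if (length(genes)) sum(width(reduce(genes))) / sum(as.double(sl))
        else 0
  perCircle <- if (length(sites)) {
    sp <- split(mcols(sites)$annotation, mcols(sites)$circle_id)
    data.frame(circle_id = names(sp),
               n_sites = lengths(sp),
               genic_fraction = vapply(sp, function(x)
                 mean(x == "genic"), numeric(1)),
               background = bg,
               preference = vapply(sp, function(x) {
                 f <- mean(x == "genic")
                 if (f > bg) "genic" else "intergenic"
               }, character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(circle_id = character(), n_sites = integer(),
                    genic_fraction = numeric(), background = numeric(),
                    preference = character())
  list(sites = sites, perCircle = perCircle, backgroundGenicFraction = bg)
}

#' Count insertion sites in fixed-width genomic windows
#'
#' Scaffolds are tiled into half-open windows of `windowSize` nt (the last
#' partial window is kept); the per-window count of insertion sites is
#' returned as a coverage-style track. Counts are conserved: they sum to the
#' number of sites.
#'
#' @param sites [GenomicRanges::GRanges] of insertion sites (seqlengths set).
#' @param windowSize window width in nt (default 100 kb).
#' @return [GenomicRanges::GRanges] of windows with a `score` column.
#' @export
windowCounts <- function(sites, windowSize = 100000) {
  if (windowSize < 1) stop("windowSize must be >= 1")
  sl <- seqlengths(sites)
  if (!length(sl)) return(GRanges())
  ## genomes smaller than one window get a single window per scaffold
  tiles <- tileGenome(sl, tilewidth = min(windowSize, sum(as.double(sl))),
                      cut.last.tile.in.chrom = TRUE)
  mcols(tiles)$score <- countOverlaps(tiles, sites)
  tiles
}

#' Write a window-count track as bedGraph
#' @param track GRanges from [windowCounts()].
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Information-content scan of host flanks around insertion sites
#'
#' Extracts `flank` nt on each side of every insertion site (a window of
#' `2*flank+1` aligned columns), computes the position frequency matrix and
#' per-column Shannon information content (2 - H bits on the 4-letter
#' alphabet), and reports the maximum. Sites too close to a scaffold edge
#' are dropped and counted in `nTruncated`.
#'
#' @param sites [GenomicRanges::GRanges] of insertion sites.
#' @param host a [HostGenome] or [Biostrings::DNAStringSet] of scaffolds.
#' @param flank half-window in nt (default 20).
#' @return list with `maxIC`, `icByColumn`, `pfm`, `nUsed`, `nTruncated`.
#' @export
flankMotifScan <- function(sites, host, flank = 20) {
  seqs <- if (is(host, "HostGenome")) hostSeqs(host) else host
  w <- 2L * as.integer(flank) + 1L
  empty <- list(maxIC = NA_real_, icByColumn = numeric(0),
                pfm = matrix(numeric(0), 4, 0,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
                nUsed = 0L, nTruncated = 0L)
  if (!length(sites)) return(empty)
  sl <- setNames(width(seqs), names(seqs))
  pos <- start(sites)
  sc <- as.character(seqnames(sites))
  ok <- pos - flank >= 1L & pos + flank <= sl[sc]
  nTrunc <- sum(!ok)
  if (!any(ok)) { empty$nTruncated <- nTrunc; return(empty) }
  fl <- DNAStringSet(rep("", sum(ok)))
  idx <- which(ok)
  for (s in unique(sc[idx])) {
    sel <- idx[sc[idx] == s]
    fl[match(sel, idx)] <- extractAt(seqs[[s]],
                                     IRanges(pos[sel] - flank,
                                             pos[sel] + flank))
  }
  pfm <- consensusMatrix(fl, as.prob = TRUE, baseOnly = TRUE)
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  ic <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  list(maxIC = max(ic), icByColumn = ic, pfm = pfm, nUsed = sum(ok),
       nTruncated = nTrunc)
}

#' Export / import insertion sites as BED6
#'
#' BED is 0-based half-open; the conversion runs through the package's
#' single coordinate chokepoint so sites round-trip exactly.
#'
#' @param sites GRanges from [annotateSites()].
#' @param path BED path.
#' @export
writeSitesBed <- function(sites, path) {
  if (length(sites)) {
    b <- toBed0(start(sites), end(sites))
    bed <- data.frame(chrom = as.character(seqnames(sites)), start = b$start,
                      end = b$end,
                      name = paste(mcols(sites)$circle_id,
                                   mcols(sites)$annotation, sep = "|"),
                      score = mcols(sites)$support, strand = ".")
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else file.create(path)
  invisible(path)
}

#' @rdname writeSitesBed
#' @param seqlengths named scaffold lengths for the imported object.
#' @export
readSitesBed <- function(path, seqlengths = NULL) {
  if (file.size(path) == 0)
    return(GRanges(seqinfo = Seqinfo(names(seqlengths),
                                     unname(seqlengths))))
  bed <- read.delim(path, header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  pos <- fromBed0(bed$start, bed$end)
  gr <- GRanges(bed$chrom, IRanges(pos$start, pos$end),
                seqinfo = if (is.null(seqlengths)) NULL else
                  Seqinfo(names(seqlengths), unname(seqlengths)))
  nm <- strsplit(bed$name, "|", fixed = TRUE)
  mcols(gr)$circle_id <- vapply(nm, `[`, character(1), 1L)
  mcols(gr)$support <- bed$score
  mcols(gr)$annotation <- vapply(nm, `[`, character(1), 2L)
  gr
}
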