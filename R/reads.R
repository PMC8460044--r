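#' Simulate 150 bp paired-end reads with substitution errors
#'
#' Fragments are sampled uniformly along each input sequence; the two mates
#' are the first and last `readLen` bases of the fragment (mate 2 reverse
#' complemented). The number of pairs per sequence is
#' `round(coverage * length / (2 * readLen))`. Substitution errors are placed
#' at `errorRate` per base; each error replaces the base with a different
#' one. When integration `truth` is supplied, every read carries a provenance
#' tag in its FASTQ comment: `chimeric` (spans an integration junction with
#' at least `minOverhang` bases on both sides, with the event id),
#' `junction_margin` (spans a junction more thinly), `viral` (entirely inside
#' an integrated copy) or `host`.
#'
#' @param seqs a [Biostrings::DNAStringSet], [HostGenome], or the result of
#'   [simulateIntegrations()] (its integrated scaffolds are then used and
#'   `truth` defaults to it).
#' @param coverage target fold coverage (> 0).
#' @param readLen read length (default 150).
#' @param errorRate per-base substitution rate.
#' @param fragMean,fragSd fragment-length model; fragments are clamped to
#'   `[readLen, sequence length]`.
#' @param seed integer seed (required).
#' @param truth optional result of [simulateIntegrations()] for provenance.
#' @param minOverhang minimum bases on each side of a junction for the
#'   `chimeric` tag (default 28, matching the detection filter).
#' @return list with `r1`, `r2` (named [Biostrings::DNAStringSet]) and
#'   `meta` (data.frame: read_id, mate, scaffold, start, end, tag, event_id).
#' @export
simulateReads <- function(seqs, coverage, readLen = 150, errorRate = 0.002,
                          fragMean = 400, fragSd = 30, seed, truth = NULL,
                          minOverhang = 28L) {
  if (is.list(seqs) && !is.null(seqs$integratedSeqs)) {
    if (is.null(truth)) truth <- seqs
    seqs <- seqs$integratedSeqs
  }
  if (is(seqs, "HostGenome")) seqs <- hostSeqs(seqs)
  if (!is(seqs, "DNAStringSet")) seqs <- readDNAStringSet(seqs)
  if (coverage <= 0) stop("coverage must be > 0")
  readLen <- as.integer(readLen)
  if (any(width(seqs) < readLen))
    stop("invalid argument: readLen exceeds an input sequence length")
  withSeed(seed, {
    perSeq <- pmax(0L, as.integer(round(coverage * width(seqs) /
                                          (2 * readLen))))
    scIdx <- rep(seq_along(seqs), perSeq)
    n <- length(scIdx)
    if (n == 0L)
      return(list(r1 = DNAStringSet(), r2 = DNAStringSet(),
                  meta = data.frame()))
    L <- width(seqs)[scIdx]
    fragLen <- pmin(pmax(as.integer(round(rnorm(n, fragMean, fragSd))),
                         readLen), L)
    fs <- 1L + as.integer(floor(runif(n) * (L - fragLen + 1L)))
    r1s <- fs; r1e <- fs + readLen - 1L
    r2e <- fs + fragLen - 1L; r2s <- r2e - readLen + 1L
    ord <- order(scIdx)
    ext <- function(starts, ends) {
      out <- DNAStringSet(rep("", n))
      for (i in seq_along(seqs)) {
        sel <- which(scIdx == i)
        if (length(sel))
          out[sel] <- extractAt(seqs[[i]], IRanges(starts[sel], ends[sel]))
      }
      out
    }
    r1 <- ext(r1s, r1e)
    r2 <- reverseComplement(ext(r2s, r2e))
    addErrors <- function(reads) {
      if (errorRate <= 0) return(reads)
      nerr <- rbinom(n, readLen, errorRate)
      tot <- sum(nerr)
      if (tot == 0L) return(reads)
      ri <- rep.int(seq_len(n), nerr)
      pos <- sample.int(readLen, tot, replace = TRUE)
      keep <- !duplicated(cbind(ri, pos))
      ri <- ri[keep]; pos <- pos[keep]
      f <- factor(ri, levels = seq_len(n))
      at <- S4Vectors::splitAsList(IRanges(pos, width = 1L), f)
      names(at) <- NULL
      orig <- as.character(unlist(extractAt(reads, at), use.names = FALSE))
      code <- match(orig, DNA_BASES4)
      newb <- DNA_BASES4[((code - 1L + sample.int(3L, length(code),
                                                  replace = TRUE)) %% 4L) + 1L]
      val <- S4Vectors::splitAsList(newb, f)
      names(val) <- NULL
      replaceAt(reads, at, value = val)
    }
    r1 <- addErrors(r1)
    r2 <- addErrors(r2)
    scafNames <- names(seqs)[scIdx]
    tagOne <- function(starts, ends) {
      tag <- rep("host", n); ev <- rep(NA_character_, n)
      if (!is.null(truth) && nrow(truth$junctions %||% data.frame())) {
        jn <- truth$junctions
        for (i in seq_along(seqs)) {
          sel <- which(scIdx == i)
          jsel <- jn[jn$scaffold == names(seqs)[i], ]
          if (!length(sel)) next
          if (!nrow(jsel)) next
          jpos <- sort(unique(c(jsel$int_start - 1L, jsel$int_end)))
          jev <- c(jsel$event_id, jsel$event_id)[
            order(c(jsel$int_start - 1L, jsel$int_end))]
          rg <- GRanges("x", IRanges(starts[sel], ends[sel]))
          jp <- GRanges("x", IRanges(jpos, width = 1L))
          ## chimeric: junction j with >= minOverhang bases on both sides
          hitC <- findOverlaps(GRanges("x", IRanges(
            starts[sel] + minOverhang - 1L,
            pmax(ends[sel] - minOverhang, starts[sel] + minOverhang - 1L))),
            jp)
          ## any junction coverage at all (>= 1 base each side)
          hitM <- findOverlaps(GRanges("x", IRanges(starts[sel],
                                                    ends[sel] - 1L)), jp)
          tag[sel][unique(queryHits(hitM))] <- "junction_margin"
          first <- !duplicated(queryHits(hitC))
          tag[sel][queryHits(hitC)[first]] <- "chimeric"
          ev[sel][queryHits(hitC)[first]] <- jev[subjectHits(hitC)[first]]
          ## fully-viral reads
          vir <- GRanges("x", IRanges(jsel$int_start, jsel$int_end))
          win <- findOverlaps(rg, vir, type = "within")
          inV <- setdiff(unique(queryHits(win)),
                         unique(c(queryHits(hitM), queryHits(hitC))))
          tag[sel][inV] <- "viral"
        }
      }
      list(tag = tag, ev = ev)
    }
    t1 <- tagOne(r1s, r1e)
    t2 <- tagOne(r2s, r2e)
    ids <- sprintf("rd%07d", seq_len(n))
    names(r1) <- sprintf("%s/1 tag=%s;ev=%s", ids, t1$tag,
                         ifelse(is.na(t1$ev), ".", t1$ev))
    names(r2) <- sprintf("%s/2 tag=%s;ev=%s", ids, t2$tag,
                         ifelse(is.na(t2$ev), ".", t2$ev))
    meta <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      mate = rep(1:2, each = n),
      scaffold = c(scafNames, scafNames),
      start = c(r1s, r2s), end = c(r1e, r2e),
      tag = c(t1$tag, t2$tag), event_id = c(t1$ev, t2$ev),
      stringsAsFactors = FALSE)
    list(r1 = r1, r2 = r2, meta = meta)
  })
}

#' Write simulated reads as FASTQ (optionally gzipped)
#'
#' @param reads result of [simulateReads()].
#' @param r1Path,r2Path output paths; `.gz` suffix enables compression.
#' @param qualityChar constant Phred character for all bases.
#' @export
writeReads <- function(reads, r1Path, r2Path, qualityChar = "I") {
  wq <- function(x, path) {
    q <- BStringSet(strrep(qualityChar, width(x)))
    names(q) <- names(x)
    writeXStringSet(x, path, format = "fastq", qualities = q,
                    compress = grepl("\\.gz$", path))
  }
  wq(reads$r1, r1Path)
  wq(reads$r2, r2Path)
  invisible(c(r1 = r1Path, r2 = r2Path))
}

#' Parse provenance tags from FASTQ read names
#'
#' @param nm character vector of full FASTQ name lines (id + comment).
#' @return data.frame with read_id, tag, event_id.
#' @export
parseReadTags <- function(nm) {
  id <- sub("\\s.*$", "", nm)
  tag <- sub(".*tag=([^;]+);.*", "\\1", nm)
  tag[!grepl("tag=", nm)] <- NA_character_
  ev <- sub(".*ev=([^;[:space:]]+).*", "\\1", nm)
  ev[ev == "." | !grepl("ev=", nm)] <- NA_character_
  data.frame(read_id = id, tag = tag, event_id = ev, stringsAsFactors = FALSE)
}
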