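## Karlin-Altschul parameters for the +1/-2 ungapped scoring system used by
## the internal aligner (fixed approximations, BLASTN-like).
KA_LAMBDA <- 1.28
KA_K <- 0.46

#' Karlin-Altschul style significance for an ungapped local score
#'
#' @param score alignment score under +1 match / -2 mismatch.
#' @param m query length; `n` total database length.
#' @param n database length.
#' @return expected number of chance alignments with at least this score.
#' @export
evalueKA <- function(score, m, n) {
  KA_K * as.double(m) * as.double(n) * exp(-KA_LAMBDA * score)
}

#' Local alignment of reads against a sequence database
#'
#' Seed-and-extend ungapped local alignment on both strands with +1/-2
#' scoring and X-drop extension. Every reference position is indexed with
#' k-mers (default k = 15); query k-mers are sampled at a stride small enough
#' that any exact match of at least `k + stride - 1` nt (20 nt at the
#' defaults, so in particular any >= 28 nt exact match) is guaranteed to
#' contain a sampled seed and be found. Circular references are searched
#' across their origin by internal doubling; coordinates are reported wrapped
#' back onto `1..length`.
#'
#' @param reads character vector or [Biostrings::DNAStringSet].
#' @param refs named character vector, [Biostrings::DNAStringSet],
#'   [CircleSet] (implies `circular = TRUE`) or [HostGenome].
#' @param circular logical, recycled over references.
#' @param k seed length (default 15); reads must be at least `k` long.
#' @param stride spacing of sampled query seeds.
#' @param match,mismatch,xdrop scoring and extension-drop parameters.
#' @param maxHits alignments reported per read (best first).
#' @param minScore minimum reported score.
#' @return data.frame with one row per alignment: `read_idx`, `read`, `ref`,
#'   `strand` ("+"/"-"), `read_lo`/`read_hi` (0-based half-open span on the
#'   original read), `ref_at_lo`/`ref_at_hi` (1-based reference coordinates
#'   aligned to the first and last read base of the span; descending on the
#'   minus strand), `matches`, `mismatches`, `score`, `evalue`. Rows are
#'   grouped by read and sorted by decreasing score.
#' @export
alignLocal <- function(reads, refs, circular = FALSE, k = 15, stride = 5,
                       match = 1, mismatch = -2, xdrop = 20, maxHits = 5,
                       minScore = 16) {
  if (is(refs, "CircleSet")) {
    circular <- TRUE
    refs <- circleSeqs(refs)
  } else if (is(refs, "HostGenome")) {
    refs <- hostSeqs(refs)
  }
  refNames <- names(refs)
  refChr <- as.character(refs)
  if (length(refChr) == 0L || any(!nzchar(refChr)))
    stop("invalid argument: empty reference")
  refNames <- refNames %||% as.character(seq_along(refChr))
  readNames <- names(reads)
  readChr <- as.character(reads)
  readNames <- readNames %||% as.character(seq_along(readChr))
  df <- .align_cpp(unname(readChr), unname(refChr),
                   as.logical(rep_len(circular, length(refChr))),
                   as.integer(k), as.integer(stride), as.integer(match),
                   as.integer(mismatch), as.integer(xdrop),
                   as.integer(maxHits), as.integer(minScore))
  df$read <- readNames[df$read_idx]
  df$ref <- refNames[df$ref_idx]
  df$strand <- ifelse(df$strand > 0, "+", "-")
  df$evalue <- evalueKA(df$score, nchar(readChr)[df$read_idx],
                        sum(nchar(refChr)))
  df[, c("read_idx", "read", "ref", "strand", "read_lo", "read_hi",
         "ref_at_lo", "ref_at_hi", "matches", "mismatches", "score",
         "evalue")]
}
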