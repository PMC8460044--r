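## Internal helpers: seeded RNG scoping, random DNA, circular arithmetic and
## the single coordinate-basis conversion chokepoint.

#' Evaluate code under a required, restorable random seed
#'
#' Every stochastic operation in the package takes an explicit integer seed;
#' an absent seed is an error, never silent entropy. The caller's RNG state is
#' restored afterwards.
#' @noRd
withSeed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is required for stochastic operations", call. = FALSE)
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## derive a child seed for stage `offset`, kept below 2^31
childSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% .Machine$integer.max)
}

DNA_BASES4 <- c("A", "C", "G", "T")

## uniform i.i.d. DNA as a single character string
randomDNA <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

## filler restricted to {A,C}: its reverse complement contains only {G,T},
## so A/C-filler can never take part in an inverted repeat. Used to insulate
## planted motif arms.
fillerAC <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C"), n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) as.character(reverseComplement(DNAStringSet(x)))

## ---- circular arithmetic (1-based, inclusive, length L) -------------------

## wrap any integer position onto 1..L
circWrap <- function(pos, L) ((pos - 1L) %% L) + 1L

## number of positions strictly between up-junction u and down-junction d
## walking forward (the deleted stretch)
circGapLen <- function(u, d, L) (d - u - 1L) %% L

## minimal circular distance between two positions (for clustering)
circDist <- function(a, b, L) {
  d <- abs(a - b)
  pmin(d, L - d)
}

## extract seq[from..to] on a circle given as a character string
circSubstr <- function(seqchr, from, to, L = nchar(seqchr)) {
  from <- circWrap(from, L); to <- circWrap(to, L)
  if (from <= to) substr(seqchr, from, to)
  else paste0(substr(seqchr, from, L), substr(seqchr, 1L, to))
}

## ---- coordinate-basis conversion chokepoint -------------------------------
## All conversions between 1-based inclusive (FASTA/GFF/TSV) and 0-based
## half-open (BED) coordinates go through these two helpers.

toBed0 <- function(start1, end1) {
  stopifnot(all(start1 >= 1L), all(end1 >= start1))
  list(start = start1 - 1L, end = end1)
}

fromBed0 <- function(start0, end0) {
  stopifnot(all(start0 >= 0L), all(end0 > start0))
  list(start = start0 + 1L, end = end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
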