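# Brute-force ungapped local alignment oracle, independent of the package's
# seed-and-extend implementation: enumerates every diagonal on both strands
# and takes the best-scoring contiguous stretch (Kadane on the +1/-2 score
# vector). Quadratic, for small references only.

oracleBestDiagonal <- function(qv, rv, match = 1L, mismatch = -2L) {
  m <- length(qv); n <- length(rv)
  best <- 0L
  for (d in (-(m - 1L)):(n - 1L)) {
    qi <- max(1L, 1L - d):min(m, n - d)
    if (!length(qi)) next
    s <- ifelse(qv[qi] == rv[qi + d], as.integer(match),
                as.integer(mismatch))
    cs <- cumsum(s)
    run <- cs - cummin(c(0L, cs[-length(cs)]))
    best <- max(best, run)
  }
  as.integer(best)
}

oracleLocalScore <- function(read, ref, match = 1L, mismatch = -2L) {
  qv <- strsplit(read, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  qrc <- rev(chartr("ACGT", "TGCA", qv))
  max(oracleBestDiagonal(qv, rv, match, mismatch),
      oracleBestDiagonal(qrc, rv, match, mismatch))
}

# plant a mutated substring of `ref` as a read; returns the read, the error
# positions, and the longest error-free run (the seedable guarantee)
plantRead <- function(ref, readLen, errorRate, revcomp = FALSE) {
  L <- nchar(ref)
  s <- sample.int(L - readLen + 1L, 1L)
  read <- substr(ref, s, s + readLen - 1L)
  nerr <- rbinom(1L, readLen, errorRate)
  errPos <- sort(sample.int(readLen, nerr))
  if (nerr > 0L) {
    rv <- strsplit(read, "")[[1]]
    for (p in errPos) {
      alt <- setdiff(c("A", "C", "G", "T"), rv[p])
      rv[p] <- sample(alt, 1L)
    }
    read <- paste(rv, collapse = "")
  }
  maxRun <- max(diff(c(0L, errPos, readLen + 1L)) - 1L)
  if (revcomp)
    read <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(read)))
  list(read = read, errPos = errPos, maxRun = maxRun, start = s)
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
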