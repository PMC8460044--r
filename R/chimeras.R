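## Chimeric-read screening: a read is chimeric when its best viral and best
## host local alignments are compatible split segments of the read, each
## covering >= minAlnLen read bases at significance <= evalueMax. The
## junction is read off the viral and host coordinates adjacent to the split.

## vectorised core shared by classifyRead() and extractChimeras().
## vb, hb: one row per read (best viral / best host alignment), aligned by
## position; either may contain NA rows.
.classifyChimeras <- function(vb, hb, minAlnLen = 28, evalueMax = 1e-5,
                              maxOverlap = 10, maxGap = 10) {
  ok <- !is.na(vb$score) & !is.na(hb$score)
  vlen <- vb$read_hi - vb$read_lo
  hlen <- hb$read_hi - hb$read_lo
  ok <- ok & vlen >= minAlnLen & hlen >= minAlnLen
  ok <- ok & vb$evalue <= evalueMax & hb$evalue <= evalueMax
  ## non-nested on the read
  nested <- (vb$read_lo >= hb$read_lo & vb$read_hi <= hb$read_hi) |
    (hb$read_lo >= vb$read_lo & hb$read_hi <= vb$read_hi)
  ok <- ok & !nested
  overlap <- pmax(0L, pmin(vb$read_hi, hb$read_hi) -
                    pmax(vb$read_lo, hb$read_lo))
  gap <- pmax(0L, pmax(vb$read_lo, hb$read_lo) -
                pmin(vb$read_hi, hb$read_hi))
  ok <- ok & overlap <= maxOverlap & gap <= maxGap
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(NULL)
  vb <- vb[ok, , drop = FALSE]
  hb <- hb[ok, , drop = FALSE]
  viralLeft <- vb$read_lo < hb$read_lo
  geometry <- ifelse(viralLeft, "viral-left", "viral-right")
  vjp <- ifelse(viralLeft, vb$ref_at_hi, vb$ref_at_lo)
  hjp <- ifelse(viralLeft, hb$ref_at_lo, hb$ref_at_hi)
  ## junction side on the circle: "U" = retained arc ends at the junction
  ## (viral coordinates increase toward it), "D" = retained arc begins there.
  side <- ifelse(viralLeft == (vb$strand == "+"), "U", "D")
  data.frame(
    read_id = vb$read, circle_id = vb$ref,
    viral_junction_pos = as.integer(vjp), junction_side = side,
    geometry = geometry, viral_strand = vb$strand,
    host_scaffold = hb$ref, host_junction_pos = as.integer(hjp),
    host_strand = hb$strand,
    junction_read_offset = as.integer(ifelse(viralLeft, vb$read_hi,
                                             hb$read_hi)),
    viral_len = as.integer(vb$read_hi - vb$read_lo),
    host_len = as.integer(hb$read_hi - hb$read_lo),
    viral_score = vb$score, host_score = hb$score,
    viral_evalue = vb$evalue, host_evalue = hb$evalue,
    stringsAsFactors = FALSE)
}

## best alignment per read index, as a data.frame with one row per read slot
.bestPerRead <- function(alns, nReads) {
  cols <- c("read", "ref", "strand", "read_lo", "read_hi", "ref_at_lo",
            "ref_at_hi", "score", "evalue")
  out <- data.frame(read = rep(NA_character_, nReads), ref = NA_character_,
                    strand = NA_character_, read_lo = NA_integer_,
                    read_hi = NA_integer_, ref_at_lo = NA_real_,
                    ref_at_hi = NA_real_, score = NA_integer_,
                    evalue = NA_real_, stringsAsFactors = FALSE)
  if (nrow(alns)) {
    best <- alns[!duplicated(alns$read_idx), , drop = FALSE]
    out[best$read_idx, ] <- best[, cols]
  }
  out
}

#' Classify one read as chimeric or not
#'
#' Applies the screening rules to precomputed viral and host alignments of a
#' single read: both best segments must cover at least `minAlnLen` read bases
#' (default 28 nt), pass `evalueMax` (default 1e-5), be non-nested on the
#' read, and overlap/leave unaligned at most `maxOverlap`/`maxGap` bases
#' between them. Absence of a chimera is a valid outcome (`NULL`).
#'
#' @param viralAlns,hostAlns alignment data.frames from [alignLocal()] for
#'   this read (best row first, as returned).
#' @param minAlnLen minimum aligned read bases per segment.
#' @param evalueMax significance cutoff per segment.
#' @param maxOverlap,maxGap allowed overlap / unaligned gap between the two
#'   read segments.
#' @return one-row data.frame describing the chimera, or `NULL`.
#' @export
classifyRead <- function(viralAlns, hostAlns, minAlnLen = 28,
                         evalueMax = 1e-5, maxOverlap = 10, maxGap = 10) {
  v <- if (!is.null(viralAlns) && nrow(viralAlns)) {
    viralAlns$read_idx <- 1L
    .bestPerRead(viralAlns, 1L)
  } else .bestPerRead(data.frame(), 1L)
  h <- if (!is.null(hostAlns) && nrow(hostAlns)) {
    hostAlns$read_idx <- 1L
    .bestPerRead(hostAlns, 1L)
  } else .bestPerRead(data.frame(), 1L)
  .classifyChimeras(v, h, minAlnLen, evalueMax, maxOverlap, maxGap)
}

#' Extract chimeric reads from a read set
#'
#' Aligns all reads to the viral circles (circular references) and to the
#' host scaffolds, keeps the best alignment per read on each side, and
#' applies the chimera screen. One row is returned per chimeric read with
#' junction coordinates on both references; a per-circle count summary is
#' attached as `attr(, "summary")`.
#'
#' @param reads a [Biostrings::DNAStringSet], character vector, FASTQ path(s)
#'   (plain or gzipped), or the list returned by [simulateReads()].
#' @param circles a [CircleSet] (or named sequences, treated as circular).
#' @param host a [HostGenome] (or named sequences, linear).
#' @param minAlnLen,evalueMax,maxOverlap,maxGap screening parameters, see
#'   [classifyRead()].
#' @param k,stride,xdrop aligner parameters, see [alignLocal()].
#' @return data.frame of chimeric reads (possibly 0 rows).
#' @export
extractChimeras <- function(reads, circles, host, minAlnLen = 28,
                            evalueMax = 1e-5, maxOverlap = 10, maxGap = 10,
                            k = 15, stride = 5, xdrop = 20) {
  if (is.list(reads) && !is.null(reads$r1)) {
    reads <- c(reads$r1, reads$r2)
  } else if (is.character(reads) && all(file.exists(reads))) {
    reads <- do.call(c, lapply(reads, function(p)
      readDNAStringSet(p, format = "fastq")))
  }
  readChr <- as.character(reads)
  names(readChr) <- names(reads) %||% as.character(seq_along(reads))
  names(readChr) <- sub("\\s.*$", "", names(readChr))
  n <- length(readChr)
  valn <- alignLocal(readChr, circles, circular = TRUE, k = k,
                     stride = stride, xdrop = xdrop, maxHits = 1,
                     minScore = min(minAlnLen, 16L))
  haln <- alignLocal(readChr, host, circular = FALSE, k = k, stride = stride,
                     xdrop = xdrop, maxHits = 1,
                     minScore = min(minAlnLen, 16L))
  out <- .classifyChimeras(.bestPerRead(valn, n), .bestPerRead(haln, n),
                           minAlnLen, evalueMax, maxOverlap, maxGap)
  if (is.null(out))
    out <- data.frame(read_id = character(), circle_id = character(),
                      viral_junction_pos = integer(),
                      junction_side = character(), geometry = character(),
                      viral_strand = character(), host_scaffold = character(),
                      host_junction_pos = integer(), host_strand = character(),
                      junction_read_offset = integer(), viral_len = integer(),
                      host_len = integer(), viral_score = integer(),
                      host_score = integer(), viral_evalue = numeric(),
                      host_evalue = numeric(), stringsAsFactors = FALSE)
  counts <- table(out$circle_id)
  attr(out, "summary") <- data.frame(circle_id = names(counts),
                                     n_chimeras = as.integer(counts),
                                     stringsAsFactors = FALSE)
  out
}

#' Write / read a chimera table (TSV) and its BEDPE companion
#'
#' The TSV keeps 1-based coordinates as in the table itself; the BEDPE file
#' reports the viral side as a 0-based half-open single-base interval on the
#' circle and the host side likewise on its scaffold.
#'
#' @param chimeras data.frame from [extractChimeras()].
#' @param tsvPath,bedpePath output paths (`bedpePath` optional).
#' @export
writeChimeras <- function(chimeras, tsvPath, bedpePath = NULL) {
  write.table(chimeras, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bedpePath)) {
    if (nrow(chimeras)) {
      bv <- toBed0(chimeras$viral_junction_pos, chimeras$viral_junction_pos)
      bh <- toBed0(chimeras$host_junction_pos, chimeras$host_junction_pos)
      bed <- data.frame(chimeras$circle_id, bv$start, bv$end,
                        chimeras$host_scaffold, bh$start, bh$end,
                        chimeras$read_id, chimeras$viral_score,
                        chimeras$viral_strand, chimeras$host_strand)
      write.table(bed, bedpePath, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else file.create(bedpePath)
  }
  invisible(tsvPath)
}

#' @rdname writeChimeras
#' @export
readChimeras <- function(tsvPath) {
  read.delim(tsvPath, stringsAsFactors = FALSE)
}
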