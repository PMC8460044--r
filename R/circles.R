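## Canonical HIM arm sequences ("8+5" motif): two pairs of exact reverse
## complements that border the deletable spacer, 8-nt pair outermost.
HIM_ARM8_UP <- "TAAATTTC"
HIM_ARM8_DOWN <- "GAAATTTA"   # revcomp(TAAATTTC)
HIM_ARM5_UP <- "CTGGT"
HIM_ARM5_DOWN <- "ACCAG"      # revcomp(CTGGT)
HIM_ARM_GAP <- 3L             # non-complementary linker between the arm pairs

#' Per-circle conserved-break fractions reported for the 19 CBC circles
#'
#' One minus the published per-circle random-break percentages (12% for
#' CvBV_04 up to 62% for CvBV_05). Used as the default conservative-break
#' probabilities when simulating a 19-CBC cohort.
#'
#' @return named numeric vector of length 19.
#' @export
reportedConservedFractions <- function() {
  pct_random <- c(CvBV_04 = 12, CvBV_06 = 13, CvBV_02 = 15, CvBV_10 = 17,
                  CvBV_13 = 20, CvBV_07 = 22, CvBV_20 = 23, CvBV_15 = 26,
                  CvBV_17 = 27, CvBV_12 = 29, CvBV_25 = 29, CvBV_21 = 29,
                  CvBV_22 = 30, CvBV_24 = 30, CvBV_27 = 31, CvBV_23 = 31,
                  CvBV_30 = 33, CvBV_29 = 39, CvBV_05 = 62)
  1 - pct_random / 100
}

.emptyCircleInfo <- function(n = 0L) {
  DataFrame(circle_id = character(n), length = integer(n),
            wim_end = integer(n), has_him = logical(n),
            mutation = character(n),
            arm8_up_start = integer(n), arm8_up_len = integer(n),
            arm5_up_start = integer(n), arm5_up_len = integer(n),
            spacer_start = integer(n), spacer_end = integer(n),
            arm5_down_start = integer(n), arm5_down_len = integer(n),
            arm8_down_start = integer(n), arm8_down_len = integer(n),
            proximity = integer(n))
}

#' Simulate circular viral segments with optional planted HIMs
#'
#' Every circle starts at its WIM (position 1 = first WIM base); the WIM is
#' 8-12 nt and always contains the tetramer AGCT. `nWithHim` circles (a
#' seeded random subset) additionally carry an intact host integration motif:
#' the 8-nt arm pair `TAAATTTC`/`GAAATTTA` outermost and the 5-nt pair
#' `CTGGT`/`ACCAG` directly bordering a non-conserved spacer, with a short
#' non-complementary linker between the pairs so the two arm pairs remain
#' distinct inverted repeats. The bases immediately flanking the planted arms
#' are drawn from \{A, C\} so that planted arm lengths are exact ground truth.
#'
#' @param nCircles number of circles (default 30, the size of the segmented
#'   viral genome this models).
#' @param lengthRange circle length range in nt (default 3.8-38.8 kb).
#' @param nWithHim how many circles carry an intact HIM (default 19).
#' @param spacerLenRange deletable spacer length range (default 39-72 nt).
#' @param proximityRange WIM-to-deletion distance range (exclusive gap from
#'   WIM base 1 to the base before the spacer; default 128-472 nt).
#' @param wimLenRange WIM length range.
#' @param seed integer seed (required).
#' @return a [CircleSet].
#' @export
generateCircles <- function(nCircles = 30, lengthRange = c(3800, 38800),
                            nWithHim = 19, spacerLenRange = c(39, 72),
                            proximityRange = c(128, 472),
                            wimLenRange = c(8, 12), seed) {
  nCircles <- as.integer(nCircles); nWithHim <- as.integer(nWithHim)
  if (nWithHim > nCircles) stop("nWithHim must be <= nCircles")
  if (min(lengthRange) < 500L) stop("circle lengths must be >= 500 nt")
  maxFoot <- max(proximityRange) + 2L + max(spacerLenRange) +
    2L * (8L + 5L + HIM_ARM_GAP) + 2L  # HIM footprint incl. insulators
  if (maxFoot >= min(lengthRange))
    stop("spacer/proximity ranges exceed the minimum circle length")
  withSeed(seed, {
    ids <- sprintf("circle_%02d", seq_len(nCircles))
    lens <- if (lengthRange[1] == lengthRange[2]) rep(lengthRange[1], nCircles)
            else sample(seq(lengthRange[1], lengthRange[2]), nCircles,
                        replace = TRUE)
    himIdx <- sort(sample(nCircles, nWithHim))
    info <- .emptyCircleInfo(nCircles)
    seqs <- character(nCircles)
    for (i in seq_len(nCircles)) {
      L <- lens[i]
      s <- randomDNA(L)
      k <- sample(seq(wimLenRange[1], wimLenRange[2]), 1)
      off <- sample.int(k - 3L, 1)  # AGCT start within WIM
      wim <- randomDNA(k)
      substr(wim, off, off + 3L) <- "AGCT"
      substr(s, 1L, k) <- wim
      row <- list(circle_id = ids[i], length = L, wim_end = k,
                  has_him = FALSE, mutation = "none",
                  arm8_up_start = NA_integer_, arm8_up_len = NA_integer_,
                  arm5_up_start = NA_integer_, arm5_up_len = NA_integer_,
                  spacer_start = NA_integer_, spacer_end = NA_integer_,
                  arm5_down_start = NA_integer_, arm5_down_len = NA_integer_,
                  arm8_down_start = NA_integer_, arm8_down_len = NA_integer_,
                  proximity = NA_integer_)
      if (i %in% himIdx) {
        P <- sample(seq(proximityRange[1], proximityRange[2]), 1)
        S <- sample(seq(spacerLenRange[1], spacerLenRange[2]), 1)
        ds <- P + 2L                      # spacer start (deletion start)
        de <- ds + S - 1L                 # spacer end
        a5u <- ds - 5L
        a8u <- a5u - HIM_ARM_GAP - 8L
        a5d <- de + 1L
        a8d <- a5d + 5L + HIM_ARM_GAP
        block_up <- paste0(fillerAC(1L), HIM_ARM8_UP, fillerAC(HIM_ARM_GAP),
                           HIM_ARM5_UP)
        block_dn <- paste0(HIM_ARM5_DOWN, fillerAC(HIM_ARM_GAP),
                           HIM_ARM8_DOWN, fillerAC(1L))
        substr(s, a8u - 1L, ds - 1L) <- block_up
        substr(s, a5d, a8d + 8L) <- block_dn
        row[c("has_him", "arm8_up_start", "arm8_up_len", "arm5_up_start",
              "arm5_up_len", "spacer_start", "spacer_end", "arm5_down_start",
              "arm5_down_len", "arm8_down_start", "arm8_down_len",
              "proximity")] <-
          list(TRUE, a8u, 8L, a5u, 5L, ds, de, a5d, 5L, a8d, 8L, P)
      }
      seqs[i] <- s
      info[i, ] <- DataFrame(row)
    }
    dss <- DNAStringSet(seqs)
    names(dss) <- ids
    new("CircleSet", seqs = dss, info = info)
  })
}

#' Assemble a single-circle CircleSet from explicit parts
#'
#' Fixture-oriented constructor: builds one circle of length `length` whose
#' sequence is `seq` (or random filler), with WIM `1..wimEnd` (AGCT planted if
#' absent) and an optional HIM whose spacer occupies `spacerStart..spacerEnd`.
#'
#' @param circleId identifier.
#' @param seq optional character sequence; random if NULL.
#' @param length circle length (ignored when `seq` given).
#' @param wimEnd last WIM base (default 10).
#' @param spacerStart,spacerEnd optional spacer (deletable region) span; when
#'   given, canonical arms are planted around it.
#' @param seed seed for random filler (required when `seq` is NULL).
#' @return a [CircleSet] of length 1.
#' @export
makeCircle <- function(circleId = "circle_01", seq = NULL, length = 5000,
                       wimEnd = 10, spacerStart = NULL, spacerEnd = NULL,
                       seed = NULL) {
  if (is.null(seq)) {
    seq <- withSeed(seed, randomDNA(as.integer(length)))
  }
  L <- nchar(seq)
  wimEnd <- as.integer(wimEnd)
  wim <- substr(seq, 1L, wimEnd)
  if (!grepl("AGCT", wim, fixed = TRUE)) {
    substr(seq, 2L, 5L) <- "AGCT"
  }
  info <- .emptyCircleInfo(1L)
  row <- list(circle_id = circleId, length = L, wim_end = wimEnd,
              has_him = FALSE, mutation = "none",
              arm8_up_start = NA_integer_, arm8_up_len = NA_integer_,
              arm5_up_start = NA_integer_, arm5_up_len = NA_integer_,
              spacer_start = NA_integer_, spacer_end = NA_integer_,
              arm5_down_start = NA_integer_, arm5_down_len = NA_integer_,
              arm8_down_start = NA_integer_, arm8_down_len = NA_integer_,
              proximity = NA_integer_)
  if (!is.null(spacerStart)) {
    ds <- as.integer(spacerStart); de <- as.integer(spacerEnd)
    a5u <- ds - 5L
    a8u <- a5u - HIM_ARM_GAP - 8L
    a5d <- de + 1L
    a8d <- a5d + 5L + HIM_ARM_GAP
    substr(seq, a8u - 1L, ds - 1L) <- paste0("A", HIM_ARM8_UP,
                                             strrep("A", HIM_ARM_GAP),
                                             HIM_ARM5_UP)
    substr(seq, a5d, a8d + 8L) <- paste0(HIM_ARM5_DOWN,
                                         strrep("A", HIM_ARM_GAP),
                                         HIM_ARM8_DOWN, "A")
    row[c("has_him", "arm8_up_start", "arm8_up_len", "arm5_up_start",
          "arm5_up_len", "spacer_start", "spacer_end", "arm5_down_start",
          "arm5_down_len", "arm8_down_start", "arm8_down_len", "proximity")] <-
      list(TRUE, a8u, 8L, a5u, 5L, ds, de, a5d, 5L, a8d, 8L, ds - 2L)
  }
  info[1, ] <- DataFrame(row)
  dss <- DNAStringSet(seq)
  names(dss) <- circleId
  new("CircleSet", seqs = dss, info = info)
}

#' Delete HIM arm sequence from circles (M1/M2/M3 mutants)
#'
#' Reproduces the mutant constructs used to probe whether the "8+5" motif is
#' required for integration: `M1` removes the 4 nt `TTTC` from the upstream
#' 8-nt arm, `M2` removes the entire upstream 5-nt arm (`CTGGT`), `M3` both.
#' Downstream annotation coordinates shift accordingly and `mutation` is set;
#' mutated circles are treated as HIM-less by the integration simulator.
#'
#' @param circles a [CircleSet].
#' @param ids circles to mutate (default: all HIM carriers).
#' @param mutation one of "M1", "M2", "M3".
#' @return a modified copy of `circles`.
#' @export
mutateHim <- function(circles, ids = NULL, mutation = c("M1", "M2", "M3")) {
  mutation <- match.arg(mutation)
  info <- circleInfo(circles)
  if (is.null(ids)) ids <- circleIds(circles)[info$has_him]
  idx <- match(ids, circleIds(circles))
  if (anyNA(idx)) stop("unknown circle ids: ", paste(ids[is.na(idx)],
                                                     collapse = ", "))
  seqs <- as.character(circles@seqs)
  for (i in idx) {
    if (!info$has_him[i] || info$mutation[i] != "none")
      stop("invalid argument: circle ", info$circle_id[i],
           " has no intact HIM to mutate")
    cuts <- NULL
    if (mutation %in% c("M1", "M3"))
      cuts <- rbind(cuts, c(info$arm8_up_start[i] + 4L,
                            info$arm8_up_start[i] + 7L))   # TTTC
    if (mutation %in% c("M2", "M3"))
      cuts <- rbind(cuts, c(info$arm5_up_start[i],
                            info$arm5_up_start[i] + 4L))   # CTGGT
    cuts <- cuts[order(cuts[, 1]), , drop = FALSE]
    s <- seqs[i]
    for (j in rev(seq_len(nrow(cuts))))
      s <- paste0(substr(s, 1L, cuts[j, 1] - 1L),
                  substr(s, cuts[j, 2] + 1L, nchar(s)))
    seqs[i] <- s
    shift <- function(pos) {
      if (is.na(pos)) return(pos)
      pos - sum((cuts[, 2] - cuts[, 1] + 1L)[cuts[, 2] < pos])
    }
    removed <- sum(cuts[, 2] - cuts[, 1] + 1L)
    info$length[i] <- info$length[i] - removed
    if (mutation %in% c("M1", "M3")) info$arm8_up_len[i] <- 4L
    if (mutation %in% c("M2", "M3")) {
      info$arm5_up_len[i] <- 0L
      info$arm5_up_start[i] <- NA_integer_
    } else {
      info$arm5_up_start[i] <- shift(info$arm5_up_start[i])
    }
    info$spacer_start[i] <- shift(info$spacer_start[i])
    info$spacer_end[i] <- shift(info$spacer_end[i])
    info$arm5_down_start[i] <- shift(info$arm5_down_start[i])
    info$arm8_down_start[i] <- shift(info$arm8_down_start[i])
    info$mutation[i] <- mutation
  }
  dss <- DNAStringSet(seqs)
  names(dss) <- circleIds(circles)
  new("CircleSet", seqs = dss, info = info)
}

#' Circles with an intact (unmutated) HIM
#' @param circles a [CircleSet]
#' @return character vector of circle ids
#' @export
intactHimIds <- function(circles) {
  info <- circleInfo(circles)
  as.character(info$circle_id[info$has_him & info$mutation == "none"])
}

#' Write / read circles as FASTA plus a motif-annotation TSV
#'
#' The FASTA holds the sequences; the sidecar TSV persists the per-circle
#' metadata so a [CircleSet] round-trips through files.
#'
#' @param circles a [CircleSet].
#' @param fastaPath,infoPath output paths.
#' @export
writeCircles <- function(circles, fastaPath, infoPath) {
  writeXStringSet(circleSeqs(circles), fastaPath)
  write.table(as.data.frame(circleInfo(circles)), infoPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, info = infoPath))
}

#' @rdname writeCircles
#' @export
readCircles <- function(fastaPath, infoPath) {
  seqs <- readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  df <- read.delim(infoPath, stringsAsFactors = FALSE)
  info <- DataFrame(df)
  for (cc in grep("_start$|_len$|_end$|^length$|^proximity$", colnames(info)))
    info[[cc]] <- as.integer(info[[cc]])
  ord <- match(names(seqs), info$circle_id)
  new("CircleSet", seqs = seqs, info = info[ord, ])
}
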