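## HIM discovery: from a circle's modal junction pair, call the deleted
## spacer, detect the "8+5" inverted-repeat arms around the junctions, and
## measure WIM-HIM proximity on the circle.

#' Infer the deleted spacer from a break-site profile
#'
#' For a circle whose chimeric junctions cluster at a modal pair (U, D), the
#' deleted stretch is `U+1 .. D-1` under circular arithmetic: U is the last
#' retained base before the deletion and D the first retained base after it.
#' A profile without a modal pair (random-broken circle) yields a
#' `"not_applicable"` call rather than an error; a zero-length deletion
#' (D = U + 1) is flagged `"degenerate"`.
#'
#' @param profile a [BreakSiteProfile] with a modal pair, or a length-2
#'   integer vector `c(U, D)`.
#' @param circle a [CircleSet] of length 1, or the integer circle length.
#' @return a [DeletionCall].
#' @export
inferDeletion <- function(profile, circle) {
  if (is(circle, "CircleSet")) {
    stopifnot(length(circle) == 1L)
    L <- circleInfo(circle)$length[1]
    cid <- circleIds(circle)
  } else {
    L <- as.integer(circle)
    cid <- NA_character_
  }
  if (is(profile, "BreakSiteProfile")) {
    U <- profile@modalUp; D <- profile@modalDown
    if (!is.na(profile@circleId)) cid <- profile@circleId
  } else {
    U <- as.integer(profile[1]); D <- as.integer(profile[2])
  }
  if (is.na(U) || is.na(D))
    return(new("DeletionCall", circleId = cid, status = "not_applicable",
               delStart = NA_integer_, delEnd = NA_integer_,
               delLen = NA_integer_, upJunction = NA_integer_,
               downJunction = NA_integer_, circleLength = L))
  len <- circGapLen(U, D, L)
  if (len == 0L)
    return(new("DeletionCall", circleId = cid, status = "degenerate",
               delStart = NA_integer_, delEnd = NA_integer_, delLen = 0L,
               upJunction = U, downJunction = D, circleLength = L))
  new("DeletionCall", circleId = cid, status = "ok",
      delStart = circWrap(U + 1L, L), delEnd = circWrap(D - 1L, L),
      delLen = len, upJunction = U, downJunction = D, circleLength = L)
}

#' Detect the inverted-repeat (HIM) arm pairs around a deletion
#'
#' Scans up to `searchWindow` nt of retained sequence on each side of the
#' deletion for pairs of exact reverse-complementary arms at mirrored
#' offsets: an upstream arm ending `d` bases before the upstream junction
#' paired with a downstream arm starting `d` bases after the downstream
#' junction. The longest such pair and the longest non-overlapping second
#' pair are reported; the call is `intact` only when an 8-nt-or-longer pair
#' and a distinct 5-nt-or-longer pair are both present (the "8+5" motif).
#' Arms not found exactly are searched again allowing one mismatch and
#' reported in the `degraded` tier.
#'
#' @param circleSeq circle sequence (character, [Biostrings::DNAString], or a
#'   length-1 [CircleSet]).
#' @param deletion a [DeletionCall] with status `"ok"`.
#' @param armLens expected arm lengths, longest first (default `c(8, 5)`).
#' @param searchWindow how far from each junction to scan (default 30 nt).
#' @return a [HimCall].
#' @export
detectInvertedRepeat <- function(circleSeq, deletion, armLens = c(8, 5),
                                 searchWindow = 30) {
  if (is(circleSeq, "CircleSet")) circleSeq <- as.character(circleSeq@seqs[[1]])
  if (is(circleSeq, "DNAString")) circleSeq <- as.character(circleSeq)
  L <- nchar(circleSeq)
  if (searchWindow >= L)
    stop("invalid argument: searchWindow must be smaller than the circle")
  if (deletion@status != "ok")
    return(new("HimCall", deletion = deletion, arm8 = list(), arm5 = list(),
               intact = FALSE, degraded = list(),
               proximity = NA_integer_))
  U <- deletion@upJunction; D <- deletion@downJunction
  w <- as.integer(searchWindow)
  ## A pair of length l at mirrored offset d is exact iff
  ## base(D+d+t) == complement(base(U-d-t)) for t in 0..l-1. With
  ## upC[j] = complement(base at U-(j-1)) and dn[j] = base at D+(j-1), that
  ## is: eq[d+1 .. d+l] all TRUE, where eq = (upC == dn).
  upFlank <- circSubstr(circleSeq, U - w + 1L, U, L)
  dnFlank <- circSubstr(circleSeq, D, D + w - 1L, L)
  upC <- rev(strsplit(chartr("ACGT", "TGCA", upFlank), "")[[1]])
  dn <- strsplit(dnFlank, "")[[1]]
  eq <- upC == dn
  ## run length starting at each offset index (1-based: offset d = idx-1)
  runLen <- integer(w)
  for (i in w:1) runLen[i] <- if (eq[i]) runLen[min(i + 1L, w)] *
      (i < w) + 1L else 0L
  ## candidate pairs: maximal runs (start where previous position mismatches)
  starts <- which(eq & !c(FALSE, eq[-w]))
  lens <- runLen[starts]
  ord <- order(-lens, starts)
  starts <- starts[ord]; lens <- lens[ord]
  mkArm <- function(s, l) {
    d <- s - 1L
    upEnd <- circWrap(U - d, L); upStart <- circWrap(U - d - l + 1L, L)
    dnStart <- circWrap(D + d, L); dnEnd <- circWrap(D + d + l - 1L, L)
    list(up_seq = circSubstr(circleSeq, upStart, upEnd, L),
         down_seq = circSubstr(circleSeq, dnStart, dnEnd, L),
         up_start = upStart, up_end = upEnd,
         down_start = dnStart, down_end = dnEnd, len = l, offset = d)
  }
  first <- NULL; second <- NULL
  if (length(starts) && lens[1] >= min(armLens)) {
    first <- mkArm(starts[1], lens[1])
    span1 <- c(starts[1], starts[1] + lens[1] - 1L)
    for (i in seq_along(starts)[-1]) {
      if (lens[i] < min(armLens)) break
      s2 <- c(starts[i], starts[i] + lens[i] - 1L)
      if (s2[2] < span1[1] || s2[1] > span1[2]) {
        second <- mkArm(starts[i], lens[i])
        break
      }
    }
  }
  arms <- list(first, second)
  lensFound <- vapply(arms, function(a) if (is.null(a)) 0L else a$len,
                      integer(1))
  ## assign: the longer found pair is the "8-nt" arm candidate, the shorter
  ## the "5-nt" candidate; an arm8 must reach armLens[1]
  ordA <- order(-lensFound)
  arm8 <- list(); arm5 <- list()
  for (a in arms[ordA]) {
    if (is.null(a)) next
    if (!length(arm8) && a$len >= armLens[1]) arm8 <- a
    else if (!length(arm5) && a$len >= armLens[2]) arm5 <- a
  }
  degraded <- list()
  if (!length(arm8)) {
    ## one-mismatch rescue scan for reporting only
    best <- NULL
    for (d in 0:(w - armLens[1])) {
      mm <- sum(upC[(d + 1):(d + armLens[1])] != dn[(d + 1):(d + armLens[1])])
      if (mm == 1L) { best <- mkArm(d + 1L, armLens[1]); best$mismatches <- 1L
        break }
    }
    if (!is.null(best)) degraded$arm8 <- best
  }
  new("HimCall", deletion = deletion, arm8 = arm8, arm5 = arm5,
      intact = length(arm8) > 0L && length(arm5) > 0L,
      degraded = degraded, proximity = NA_integer_)
}

#' WIM-HIM proximity on the circle
#'
#' The distance between the first WIM base (circle position 1) and the
#' nearest deletion boundary, counted exclusively of both endpoints and
#' minimised over the two circular directions. In the common linear case
#' this is `del_start - 2`; for deletions lying close to the origin on the
#' far side the wrap-around gap `L - del_end` is smaller and is returned
#' instead.
#'
#' @param circle a [CircleSet] of length 1 (provides length and WIM), or an
#'   integer circle length (WIM then assumed to start at position 1).
#' @param deletion a [DeletionCall] with status `"ok"`.
#' @return integer distance in nt (NA for non-`ok` calls).
#' @export
wimHimProximity <- function(circle, deletion) {
  if (deletion@status != "ok") return(NA_integer_)
  L <- if (is(circle, "CircleSet")) circleInfo(circle)$length[1]
       else as.integer(circle)
  back <- (deletion@delStart - 2L) %% L   # forward gap from WIM base 1
  fwd <- (L - deletion@delEnd) %% L       # wrap-around gap to WIM base 1
  as.integer(min(back, fwd))
}

#' Extract junction flanks of a deletion
#'
#' @param circleSeq circle sequence (character / DNAString / CircleSet).
#' @param deletion a [DeletionCall] with status `"ok"`.
#' @param width flank width in nt.
#' @return named character vector with `upstream` (the `width` retained
#'   bases ending at the upstream junction) and `downstream` (starting at
#'   the downstream junction).
#' @export
junctionFlanks <- function(circleSeq, deletion, width = 20) {
  if (is(circleSeq, "CircleSet")) circleSeq <- as.character(circleSeq@seqs[[1]])
  if (is(circleSeq, "DNAString")) circleSeq <- as.character(circleSeq)
  L <- nchar(circleSeq)
  c(upstream = circSubstr(circleSeq, deletion@upJunction - width + 1L,
                          deletion@upJunction, L),
    downstream = circSubstr(circleSeq, deletion@downJunction,
                            deletion@downJunction + width - 1L, L))
}

#' Position-frequency matrix and consensus of aligned flanks
#'
#' Column-wise base frequencies over equal-length aligned sequences (e.g.
#' the junction flanks of all CBCs), with the most frequent base per column
#' as the consensus string.
#'
#' @param flanks character vector or [Biostrings::DNAStringSet] of aligned,
#'   equal-length sequences (>= 2).
#' @param asProb return frequencies (TRUE) or counts.
#' @return list with `pfm` (4 x width matrix, rows ACGT), `consensus`
#'   (character), and `maxColFreq` (highest per-column frequency).
#' @export
consensusLogo <- function(flanks, asProb = TRUE) {
  if (is.character(flanks)) flanks <- DNAStringSet(flanks)
  if (length(flanks) < 2L)
    stop("invalid argument: need at least 2 aligned flanks")
  if (length(unique(width(flanks))) != 1L)
    stop("invalid argument: flanks must have equal lengths")
  m <- consensusMatrix(flanks, as.prob = asProb, baseOnly = TRUE)
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  cons <- paste(rownames(m)[apply(m, 2, which.max)], collapse = "")
  fr <- if (asProb) m else sweep(m, 2, colSums(m), "/")
  list(pfm = m, consensus = cons, maxColFreq = max(apply(fr, 2, max)))
}

#' Write a position-frequency matrix as TSV
#' @param pfm matrix from [consensusLogo()].
#' @param path output path.
#' @export
writePfm <- function(pfm, path) {
  df <- data.frame(base = rownames(pfm), pfm, check.names = FALSE)
  colnames(df) <- c("base", sprintf("pos%d", seq_len(ncol(pfm))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full HIM call for one circle from its chimeras
#'
#' Convenience wrapper: profile -> deletion -> inverted repeats -> proximity.
#'
#' @param chimeras chimera table.
#' @param circle a [CircleSet] of length 1.
#' @param clusterTol,searchWindow see [buildProfile()] and
#'   [detectInvertedRepeat()].
#' @return a [HimCall] with proximity filled in.
#' @export
callHim <- function(chimeras, circle, clusterTol = 3, searchWindow = 30) {
  prof <- buildProfile(chimeras, circleIds(circle), clusterTol,
                       circleInfo(circle)$length[1])
  del <- inferDeletion(prof, circle)
  hc <- detectInvertedRepeat(circle, del, searchWindow = searchWindow)
  if (del@status == "ok")
    hc@proximity <- wimHimProximity(circle, del)
  hc
}

#' Tabulate HIM calls in the style of the published motif table
#'
#' @param himCalls named list of [HimCall] (circle id -> call).
#' @param circles a [CircleSet] (for WIM spans).
#' @param path optional TSV output path.
#' @return data.frame with WIM span, deleted span and length, proximity,
#'   arm sequences and intact flag per circle.
#' @export
himTable <- function(himCalls, circles, path = NULL) {
  info <- circleInfo(circles)
  rows <- lapply(names(himCalls), function(id) {
    hc <- himCalls[[id]]
    d <- hc@deletion
    i <- match(id, info$circle_id)
    data.frame(
      circle_id = id, wim_span = sprintf("1-%d", info$wim_end[i]),
      del_start = d@delStart, del_end = d@delEnd, del_len = d@delLen,
      proximity = hc@proximity,
      arm8_up = if (length(hc@arm8)) hc@arm8$up_seq else NA_character_,
      arm8_down = if (length(hc@arm8)) hc@arm8$down_seq else NA_character_,
      arm5_up = if (length(hc@arm5)) hc@arm5$up_seq else NA_character_,
      arm5_down = if (length(hc@arm5)) hc@arm5$down_seq else NA_character_,
      intact = hc@intact, status = d@status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
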