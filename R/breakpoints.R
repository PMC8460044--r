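## Breakpoint profiling: aggregate viral-side junction positions per circle,
## find the modal junction pair, and classify circles as conservative-broken
## (CBC) or random-broken (RBC).

## modal cluster of a named count vector (names = positions) within +/- tol,
## with circular wrap when L is known. Returns list(center, clusterCount,
## modalPos) or NULL for empty input.
.modalCluster <- function(counts, tol, L = NA_integer_) {
  if (!length(counts)) return(NULL)
  pos <- as.integer(names(counts))
  cnt <- as.integer(counts)
  score <- vapply(seq_along(pos), function(i) {
    d <- abs(pos - pos[i])
    if (!is.na(L)) d <- pmin(d, L - d)
    sum(cnt[d <= tol])
  }, integer(1))
  best <- which(score == max(score))
  center <- best[which.min(pos[best])]
  d <- abs(pos - pos[center])
  if (!is.na(L)) d <- pmin(d, L - d)
  inCl <- which(d <= tol)
  modal <- inCl[order(-cnt[inCl], pos[inCl])][1]
  list(center = pos[center], clusterCount = sum(cnt[inCl]),
       modalPos = pos[modal])
}

#' Build a break-site profile for one circle
#'
#' Tallies viral-side junction positions of the chimeras of one circle,
#' split by junction side ("U": the retained arc ends at the junction; "D":
#' it begins there). Junctions within `clusterTol` nt are clustered; the
#' modal pair is the highest-count cluster on each side, and a conservative
#' break contributes to both. The conserved count is the number of chimeras
#' falling in either modal cluster, so `conservedFraction` estimates the
#' fraction of breaks at the circle's dominant (HIM) site.
#'
#' @param chimeras chimera table from [extractChimeras()] (any circles; rows
#'   of other circles are ignored when `circleId` is given).
#' @param circleId circle to profile; required when the table mixes circles.
#' @param clusterTol clustering tolerance in nt (default 3, absorbing
#'   alignment-end jitter from sequencing errors).
#' @param circleLength circle length for circular clustering (optional).
#' @return a [BreakSiteProfile].
#' @export
buildProfile <- function(chimeras, circleId = NULL, clusterTol = 3,
                         circleLength = NA) {
  if (is.null(circleId)) {
    ids <- unique(chimeras$circle_id)
    if (length(ids) > 1L)
      stop("chimeras reference multiple circles; supply circleId")
    circleId <- if (length(ids)) ids else NA_character_
  }
  ch <- chimeras[!is.na(chimeras$circle_id) & chimeras$circle_id == circleId,
                 , drop = FALSE]
  tab <- function(side) {
    x <- ch$viral_junction_pos[ch$junction_side == side]
    if (!length(x)) return(setNames(integer(0), character(0)))
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  up <- tab("U"); down <- tab("D")
  nCh <- nrow(ch)
  L <- if (is.na(circleLength)) NA_integer_ else as.integer(circleLength)
  mu <- .modalCluster(up, clusterTol, L)
  md <- .modalCluster(down, clusterTol, L)
  conserved <- sum(c(if (!is.null(mu)) mu$clusterCount,
                     if (!is.null(md)) md$clusterCount))
  new("BreakSiteProfile", circleId = as.character(circleId),
      upCounts = up, downCounts = down, nChimeras = as.integer(nCh),
      modalUp = if (is.null(mu)) NA_integer_ else as.integer(mu$modalPos),
      modalDown = if (is.null(md)) NA_integer_ else as.integer(md$modalPos),
      conservedCount = as.integer(conserved),
      conservedFraction = if (nCh) conserved / nCh else 0,
      clusterTol = as.integer(clusterTol), circleLength = L)
}

#' Profiles for every circle in a chimera table
#'
#' @param chimeras chimera table.
#' @param circles optional [CircleSet] providing circle lengths (and ensuring
#'   circles without chimeras still get an empty profile).
#' @param clusterTol clustering tolerance in nt.
#' @return named list of [BreakSiteProfile] objects.
#' @export
buildProfiles <- function(chimeras, circles = NULL, clusterTol = 3) {
  ids <- if (is.null(circles)) sort(unique(chimeras$circle_id))
         else circleIds(circles)
  lens <- if (is.null(circles)) setNames(rep(NA_integer_, length(ids)), ids)
          else setNames(circleInfo(circles)$length, ids)
  setNames(lapply(ids, function(id)
    buildProfile(chimeras, id, clusterTol, lens[[id]])), ids)
}

#' Classify a circle as conservative- or random-broken
#'
#' A circle is a CBC when its conserved break fraction reaches `threshold`
#' with at least `minSupport` chimeras; otherwise it is an RBC. Below
#' `minSupport` the label is withheld as `"insufficient_support"`.
#'
#' @param profile a [BreakSiteProfile].
#' @param threshold conserved-fraction cutoff (default 0.35, separating the
#'   weakest reported CBC, 38% conserved, from fully random circles).
#' @param minSupport minimum chimeras for a confident label.
#' @return one-row data.frame: circle_id, label, conserved_fraction,
#'   random_fraction, support.
#' @export
classifyCircle <- function(profile, threshold = 0.35, minSupport = 20) {
  frac <- conservedFraction(profile)
  label <- if (nChimeras(profile) < minSupport) "insufficient_support"
           else if (frac >= threshold) "CBC" else "RBC"
  data.frame(circle_id = profile@circleId, label = label,
             conserved_fraction = frac, random_fraction = 1 - frac,
             support = nChimeras(profile), stringsAsFactors = FALSE)
}

#' @rdname classifyCircle
#' @param profiles list of [BreakSiteProfile] (from [buildProfiles()]).
#' @export
classifyCircles <- function(profiles, threshold = 0.35, minSupport = 20) {
  out <- do.call(rbind, lapply(profiles, classifyCircle, threshold,
                               minSupport))
  rownames(out) <- NULL
  out
}

#' Chimeric-read share per break class
#'
#' Aggregates per-circle chimera support by CBC/RBC label: total reads per
#' class and the percentage of all chimeras contributed by each class.
#'
#' @param classifications data.frame with `label` and `support` columns
#'   (from [classifyCircles()], or any table of per-class read counts).
#' @return data.frame with columns label, reads, pct.
#' @export
classShareReport <- function(classifications) {
  agg <- tapply(classifications$support, classifications$label, sum)
  out <- data.frame(label = names(agg), reads = as.integer(agg),
                    stringsAsFactors = FALSE)
  out$pct <- 100 * out$reads / sum(out$reads)
  rownames(out) <- NULL
  out[order(out$label), ]
}

#' Per-circle random-break percentage report
#'
#' @param classifications data.frame from [classifyCircles()].
#' @param path optional TSV output path.
#' @return data.frame sorted by circle_id with random-break percentages.
#' @export
randomFractionReport <- function(classifications, path = NULL) {
  out <- classifications[order(classifications$circle_id),
                         c("circle_id", "label", "conserved_fraction",
                           "random_fraction", "support")]
  out$random_pct <- 100 * out$random_fraction
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
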