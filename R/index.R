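## Integration index: qPCR-derived statistic for the fraction of circle
## copies disrupted at their HIM. Two amplicons per circle: one across the
## HIM (lost upon integration) and one across the WIM (internal control).
## index = (1 - 2^-ddCT) x 100%, ddCT = dCT(t) - dCT(0 h),
## dCT = CT(HIM) - CT(WIM).

#' Simulate qPCR CT measurements from true disrupted fractions
#'
#' The inverse model of the readout: when a fraction `f` of a circle's
#' copies is disrupted at the HIM, the HIM amplicon template drops to
#' `1 - f` of baseline, delaying its CT by `-log(1-f)/log(1+efficiency)`
#' cycles; the WIM amplicon is unaffected. Gaussian noise is added per
#' replicate. A fraction of 1 would imply an infinite CT and is rejected.
#'
#' @param fractions data.frame with columns `circle_id`, `timepoint_h`,
#'   `fraction` (true disrupted fraction, in \[0, 1)).
#' @param baselineCtHim,baselineCtWim baseline cycle numbers.
#' @param efficiency amplification efficiency, in (0.8, 1\]; 1 means perfect
#'   doubling per cycle (the base-2 of the index formula).
#' @param noiseSd per-replicate Gaussian CT noise (cycles).
#' @param replicates replicates per (circle, timepoint).
#' @param seed integer seed (required).
#' @return long-format data.frame: circle_id, timepoint_h, replicate,
#'   ct_him, ct_wim.
#' @export
simulateCT <- function(fractions, baselineCtHim = 24, baselineCtWim = 22,
                       efficiency = 1.0, noiseSd = 0.15, replicates = 3,
                       seed) {
  stopifnot(all(c("circle_id", "timepoint_h", "fraction") %in%
                  colnames(fractions)))
  f <- fractions$fraction
  if (any(f < 0 | f > 1)) stop("fractions must be in [0, 1)")
  if (any(f == 1)) stop("fraction = 1 implies an infinite CT; rejected")
  if (efficiency <= 0.8 || efficiency > 1)
    stop("efficiency must be in (0.8, 1]")
  withSeed(seed, {
    n <- nrow(fractions)
    rep_idx <- rep(seq_len(replicates), times = n)
    base <- fractions[rep(seq_len(n), each = replicates), ]
    shift <- -log(1 - base$fraction) / log(1 + efficiency)
    m <- n * replicates
    out <- data.frame(
      circle_id = base$circle_id, timepoint_h = base$timepoint_h,
      replicate = rep_idx,
      ct_him = baselineCtHim + shift + rnorm(m, 0, noiseSd),
      ct_wim = baselineCtWim + rnorm(m, 0, noiseSd),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (any(out$ct_him <= 0 | out$ct_him >= 45 | out$ct_wim <= 0 |
              out$ct_wim >= 45))
      stop("simulated CT values left the valid range (0, 45)")
    out
  })
}

#' Compute the integration-index time course from CT measurements
#'
#' For each circle, per-replicate dCT = ct_him - ct_wim is referenced to the
#' mean 0 h baseline, converted to an index (1 - 2^-ddCT) x 100, and
#' summarised per timepoint (mean, sd). By construction the 0 h index is 0.
#' Negative indices (below-baseline) are reported as-is with a flag, never
#' clamped. A missing 0 h baseline is an error; fewer than 3 replicates per
#' point triggers a warning but is computed anyway.
#'
#' @param ct long-format data.frame as from [simulateCT()] (columns
#'   circle_id, timepoint_h, replicate, ct_him, ct_wim).
#' @return a named list of [IntegrationIndexSeries], one per circle.
#' @export
computeIndex <- function(ct) {
  stopifnot(all(c("circle_id", "timepoint_h", "ct_him", "ct_wim") %in%
                  colnames(ct)))
  lapply(setNames(nm = unique(ct$circle_id)), function(id) {
    x <- ct[ct$circle_id == id, ]
    if (!any(x$timepoint_h == 0))
      stop("circle ", id, ": no 0 h baseline measurement")
    reps <- table(x$timepoint_h)
    if (any(reps < 3))
      warning("circle ", id, ": fewer than 3 replicates at some timepoints",
              call. = FALSE)
    dct <- x$ct_him - x$ct_wim
    base <- mean(dct[x$timepoint_h == 0])
    idx <- (1 - 2^(-(dct - base))) * 100
    tp <- sort(unique(x$timepoint_h))
    tab <- data.frame(
      timepoint_h = tp,
      mean_index_pct = vapply(tp, function(t)
        if (t == 0) 0 else mean(idx[x$timepoint_h == t]), numeric(1)),
      sd_index_pct = vapply(tp, function(t)
        sd(idx[x$timepoint_h == t]), numeric(1)),
      n_replicates = as.integer(vapply(tp, function(t)
        sum(x$timepoint_h == t), numeric(1))))
    tab$below_baseline <- tab$mean_index_pct < 0
    new("IntegrationIndexSeries", circleId = id, table = tab,
        timingClass = NA_character_)
  })
}

#' Classify the integration timing of a circle
#'
#' The onset is the earliest timepoint whose mean index reaches
#' `onsetThresholdPct` and stays at or above it at every later timepoint
#' (a sustained onset; transient noise blips that fall back below the
#' threshold do not count). Onset at or before 0.5 h makes an early
#' integrated circle (EIC), at or before 1 h mid (MIC), at or before 2 h
#' late (LIC); circles never reaching a sustained threshold within 2 h are
#' unclassified.
#'
#' @param series an [IntegrationIndexSeries] (must cover the measurement
#'   grid 0, 0.5, 1, 2, 4 h).
#' @param onsetThresholdPct index threshold defining onset (default 25).
#' @param binsH upper edges of the early and mid bins (default 0.5 and 1 h).
#' @return the series with `timingClass` set ("EIC", "MIC", "LIC" or
#'   "unclassified").
#' @export
classifyTiming <- function(series, onsetThresholdPct = 25,
                           binsH = c(0.5, 1)) {
  tab <- indexTable(series)
  grid <- c(0, 0.5, 1, 2, 4)
  if (!all(grid %in% tab$timepoint_h))
    stop("series must cover the timepoint grid 0, 0.5, 1, 2, 4 h")
  tab <- tab[order(tab$timepoint_h), ]
  m <- tab$mean_index_pct
  onset <- NA_real_
  for (i in which(tab$timepoint_h > 0)) {
    if (m[i] < onsetThresholdPct) next
    if (all(m[seq(i, nrow(tab))] >= onsetThresholdPct)) {
      onset <- tab$timepoint_h[i]
      break
    }
  }
  cls <- if (is.na(onset)) "unclassified"
         else if (onset <= binsH[1]) "EIC"
         else if (onset <= binsH[2]) "MIC"
         else if (onset <= 2) "LIC"
         else "unclassified"
  initialize(series, timingClass = cls)
}

#' True disrupted-fraction time course implied by simulated events
#'
#' Converts the event times of an integration simulation into per-circle
#' true disrupted fractions on the qPCR grid: the fraction at time t is
#' `fMax` times the fraction of that circle's events with `time_h <= t`
#' (integration saturates at `fMax` of copies).
#'
#' @param events events data.frame from [simulateIntegrations()].
#' @param times measurement grid (h).
#' @param fMax saturating disrupted fraction (default 0.7).
#' @return data.frame circle_id, timepoint_h, fraction.
#' @export
waveFractions <- function(events, times = c(0, 0.5, 1, 2, 4), fMax = 0.7) {
  ids <- unique(events$circle_id)
  out <- expand.grid(circle_id = ids, timepoint_h = times,
                     stringsAsFactors = FALSE)
  out$fraction <- mapply(function(id, t) {
    tt <- events$time_h[events$circle_id == id]
    fMax * mean(tt <= t)
  }, out$circle_id, out$timepoint_h)
  out[order(out$circle_id, out$timepoint_h), ]
}

#' Flatten index series to a table with timing classes
#'
#' @param seriesList named list from [computeIndex()] (after
#'   [classifyTiming()]).
#' @param path optional TSV output path.
#' @return data.frame of all per-timepoint summaries plus timing class.
#' @export
indexReport <- function(seriesList, path = NULL) {
  out <- do.call(rbind, lapply(seriesList, function(s) {
    tab <- indexTable(s)
    tab$circle_id <- s@circleId
    tab$timing_class <- timingClass(s)
    tab
  }))
  rownames(out) <- NULL
  out <- out[, c("circle_id", "timepoint_h", "mean_index_pct",
                 "sd_index_pct", "n_replicates", "below_baseline",
                 "timing_class")]
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
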