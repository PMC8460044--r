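#' Simulate integration of viral circles into a host genome
#'
#' Each event opens a circle and splices the linearized sequence into the
#' host. Circles with an intact HIM draw each event *conservative* with the
#' given probability: the circle breaks at its HIM, the spacer between the
#' 5-nt arms is deleted and both arm pairs are retained on the integrated
#' copy. All other events are *random*: the circle opens at a uniform
#' position with nothing deleted. HIM-less or HIM-mutated circles can only
#' break randomly. Events are stamped with an integration wave (early < 0.5 h,
#' mid 0.5-1 h, late 1-2 h post parasitization) and a time drawn within it.
#'
#' @param circles a [CircleSet].
#' @param host a [HostGenome].
#' @param nEventsPerCircle scalar or named integer vector of event counts.
#' @param conservativeProb probability that an event on an intact-HIM circle
#'   is conservative. Scalar, or named vector over circle ids, or NULL for
#'   the default: the published per-CBC conserved fractions when exactly 19
#'   circles carry intact HIMs, 0.75 otherwise. Requesting a positive
#'   probability for a circle without an intact HIM is a contract violation.
#' @param waveAssignment optional named character vector (circle id ->
#'   "early"/"mid"/"late"). Default splits intact-HIM circles 11:5:3 in id
#'   order (the published EIC/MIC/LIC class sizes) and recycles waves over
#'   the remaining circles.
#' @param orientationProb probability of forward insertion orientation.
#' @param seed integer seed (required).
#' @return a list with `events` (data.frame: event_id, circle_id, mode,
#'   up_junction, down_junction, deleted_len, host_scaffold, host_pos,
#'   orientation, wave, time_h), `integratedSeqs` (DNAStringSet of rewritten
#'   scaffolds), and `junctions` (data.frame mapping each event to its
#'   integrated-coordinate span `int_start..int_end`).
#' @export
simulateIntegrations <- function(circles, host, nEventsPerCircle,
                                 conservativeProb = NULL,
                                 waveAssignment = NULL,
                                 orientationProb = 0.5, seed) {
  ids <- circleIds(circles)
  info <- circleInfo(circles)
  intact <- intactHimIds(circles)
  nEv <- if (is.null(names(nEventsPerCircle)))
    setNames(rep_len(as.integer(nEventsPerCircle), length(ids)), ids)
  else {
    v <- setNames(rep(0L, length(ids)), ids)
    v[names(nEventsPerCircle)] <- as.integer(nEventsPerCircle)
    v
  }
  pCons <- setNames(rep(0, length(ids)), ids)
  if (is.null(conservativeProb)) {
    pCons[intact] <- if (length(intact) == 19L)
      unname(reportedConservedFractions()) else 0.75
  } else if (is.null(names(conservativeProb))) {
    if (any(conservativeProb < 0 | conservativeProb > 1))
      stop("conservativeProb must be in [0,1]")
    pCons[intact] <- conservativeProb
  } else {
    if (any(conservativeProb < 0 | conservativeProb > 1))
      stop("conservativeProb must be in [0,1]")
    bad <- setdiff(names(conservativeProb)[conservativeProb > 0], intact)
    if (length(bad))
      stop("contract violation: conservative events requested for circles ",
           "without an intact HIM: ", paste(bad, collapse = ", "))
    pCons[names(conservativeProb)] <- conservativeProb
  }
  waves <- c("early", "mid", "late")
  if (is.null(waveAssignment)) {
    wv <- setNames(rep(waves, length.out = length(ids)), ids)
    if (length(intact)) {
      k <- length(intact)
      nE <- round(k * 11 / 19); nM <- round(k * 5 / 19)
      wv[intact] <- rep(waves, c(nE, nM, k - nE - nM))
    }
  } else {
    stopifnot(all(waveAssignment %in% waves))
    wv <- setNames(rep("early", length(ids)), ids)
    wv[names(waveAssignment)] <- waveAssignment
  }

  scafLen <- scaffoldLengths(host)
  withSeed(seed, {
    evl <- lapply(ids, function(id) {
      n <- nEv[[id]]
      if (n == 0L) return(NULL)
      i <- match(id, ids)
      L <- info$length[i]
      isCons <- runif(n) < pCons[[id]]
      if (!(id %in% intact)) isCons[] <- FALSE
      up <- integer(n); dn <- integer(n); del <- integer(n)
      if (any(isCons)) {
        up[isCons] <- info$spacer_start[i] - 1L
        dn[isCons] <- info$spacer_end[i] + 1L
        del[isCons] <- info$spacer_end[i] - info$spacer_start[i] + 1L
      }
      if (any(!isCons)) {
        b <- sample.int(L, sum(!isCons), replace = TRUE)
        up[!isCons] <- b
        dn[!isCons] <- circWrap(b + 1L, L)
        del[!isCons] <- 0L
      }
      tw <- wv[[id]]
      t_h <- switch(tw, early = runif(n, 0, 0.5), mid = runif(n, 0.5, 1),
                    late = runif(n, 1, 2))
      data.frame(circle_id = id,
                 mode = ifelse(isCons, "conservative", "random"),
                 up_junction = up, down_junction = dn, deleted_len = del,
                 orientation = ifelse(runif(n) < orientationProb,
                                      "forward", "reverse"),
                 wave = tw, time_h = t_h, stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, evl)
    if (is.null(events) || nrow(events) == 0L) {
      return(list(events = data.frame(), integratedSeqs = hostSeqs(host),
                  junctions = data.frame()))
    }
    nTot <- nrow(events)
    events$event_id <- sprintf("ev%07d", seq_len(nTot))
    if (length(scafLen) == 0L)
      stop("host genome has no scaffolds to integrate into")
    events$host_scaffold <- names(scafLen)[
      sample.int(length(scafLen), nTot, replace = TRUE, prob = scafLen)]
    events$host_pos <- NA_integer_
    for (sc in unique(events$host_scaffold)) {
      sel <- events$host_scaffold == sc
      events$host_pos[sel] <- sample.int(scafLen[[sc]] - 1L, sum(sel))
    }
    ## integrated copies: retained arc runs down_junction .. up_junction
    seqsChr <- as.character(circleSeqs(circles))
    insSeq <- vapply(seq_len(nTot), function(r) {
      i <- match(events$circle_id[r], ids)
      circSubstr(seqsChr[[i]], events$down_junction[r],
                 events$up_junction[r], info$length[i])
    }, character(1))
    isRev <- events$orientation == "reverse"
    if (any(isRev)) insSeq[isRev] <- revcompChr(insSeq[isRev])
    intSeqs <- hostSeqs(host)
    juncl <- vector("list", length(scafLen))
    names(juncl) <- names(scafLen)
    for (sc in unique(events$host_scaffold)) {
      sel <- which(events$host_scaffold == sc)
      ord <- sel[order(events$host_pos[sel])]
      insLens <- nchar(insSeq[ord])
      offs <- cumsum(c(0L, insLens[-length(insLens)]))
      intStart <- events$host_pos[ord] + offs + 1L
      juncl[[sc]] <- data.frame(scaffold = sc, event_id = events$event_id[ord],
                                int_start = intStart,
                                int_end = intStart + insLens - 1L,
                                stringsAsFactors = FALSE)
      intSeqs[[sc]] <- replaceAt(
        intSeqs[[sc]], IRanges(start = events$host_pos[ord] + 1L, width = 0L),
        value = DNAStringSet(insSeq[ord]))
    }
    junctions <- do.call(rbind, juncl[!vapply(juncl, is.null, logical(1))])
    rownames(junctions) <- NULL
    events <- events[, c("event_id", "circle_id", "mode", "up_junction",
                         "down_junction", "deleted_len", "host_scaffold",
                         "host_pos", "orientation", "wave", "time_h")]
    list(events = events, integratedSeqs = intSeqs, junctions = junctions)
  })
}

#' Write / read ground-truth integration events (BED6 + JSON)
#'
#' The BED6 file records, per event, the host base immediately upstream of
#' the insertion point as a 0-based half-open interval, with
#' `circle_id|mode` in the name field and the insertion orientation as the
#' strand. The JSON file carries the full event records and round-trips
#' exactly.
#'
#' @param events the `events` data.frame from [simulateIntegrations()].
#' @param bedPath,jsonPath output paths.
#' @export
writeTruthEvents <- function(events, bedPath, jsonPath) {
  if (nrow(events)) {
    b <- toBed0(events$host_pos, events$host_pos)
    bed <- data.frame(chrom = events$host_scaffold, start = b$start,
                      end = b$end,
                      name = paste(events$circle_id, events$mode, sep = "|"),
                      score = events$deleted_len,
                      strand = ifelse(events$orientation == "forward",
                                      "+", "-"))
    write.table(bed, bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    file.create(bedPath)
  }
  jsonlite::write_json(events, jsonPath, digits = NA, na = "null")
  invisible(c(bed = bedPath, json = jsonPath))
}

#' @rdname writeTruthEvents
#' @export
readTruthEvents <- function(jsonPath) {
  df <- jsonlite::fromJSON(jsonPath)
  if (length(df) == 0L) return(data.frame())
  for (cc in c("up_junction", "down_junction", "deleted_len", "host_pos"))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' @rdname writeTruthEvents
#' @param bedPath path to a truth BED6 file.
#' @export
readTruthBed <- function(bedPath) {
  if (file.size(bedPath) == 0) return(data.frame())
  bed <- read.delim(bedPath, header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"))
  pos <- fromBed0(bed$start, bed$end)
  nm <- strsplit(bed$name, "|", fixed = TRUE)
  data.frame(host_scaffold = bed$chrom, host_pos = pos$start,
             circle_id = vapply(nm, `[`, character(1), 1L),
             mode = vapply(nm, `[`, character(1), 2L),
             deleted_len = bed$score,
             orientation = ifelse(bed$strand == "+", "forward", "reverse"),
             stringsAsFactors = FALSE)
}
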