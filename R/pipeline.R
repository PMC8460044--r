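## End-to-end driver: simulate -> detect -> profile -> him -> landscape ->
## index, with all stage outputs, seeds and content hashes recorded in a
## manifest so identical configurations reproduce byte-identical results.

.stageSeeds <- function(seed) {
  c(host = childSeed(seed, 1L), circles = childSeed(seed, 2L),
    events = childSeed(seed, 3L), reads = childSeed(seed, 4L),
    ct = childSeed(seed, 5L))
}

#' Run the full integration-discovery pipeline on simulated data
#'
#' Simulates a host genome, a circle cohort and integration events, sequences
#' the integrated genome, detects chimeric reads, profiles break sites,
#' classifies circles (CBC/RBC), calls HIMs on the CBCs, summarises the host
#' insertion landscape, and computes integration-index time courses from the
#' event waves. All stage outputs are written under `outdir`; a
#' `manifest.json` records the configuration, derived stage seeds, package
#' version and md5 hash of every output file. Re-running with an identical
#' configuration reproduces identical files.
#'
#' @param config configuration list (see [defaultConfig()]); validated and
#'   completed via [validateConfig()].
#' @param outdir output directory (created; existing files overwritten).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all in-memory stage results
#'   (`circles`, `host`, `sim`, `chimeras`, `profiles`, `classification`,
#'   `himCalls`, `himTable`, `landscape`, `index`, `manifest`).
#' @export
runPipeline <- function(config = list(), outdir, quiet = FALSE) {
  cfg <- validateConfig(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stageSeeds(cfg$seed)
  say <- function(...) if (!quiet) message(...)
  pth <- function(f) file.path(outdir, f)

  ## ---- stage 1: simulate --------------------------------------------------
  say("[simulate] host genome (seed ", seeds[["host"]], ")")
  host <- generateHostGenome(cfg$host$nScaffolds, cfg$host$scaffoldLength,
                             cfg$host$geneDensity, seed = seeds[["host"]])
  writeHostGenome(host, pth("host.fa"), pth("host.gff3"))
  say("[simulate] circles (seed ", seeds[["circles"]], ")")
  circles <- generateCircles(
    nCircles = cfg$circles$nCircles, lengthRange = cfg$circles$lengthRange,
    nWithHim = cfg$circles$nWithHim,
    spacerLenRange = cfg$circles$spacerLenRange,
    proximityRange = cfg$circles$proximityRange, seed = seeds[["circles"]])
  writeCircles(circles, pth("circles.fa"), pth("circles_info.tsv"))
  say("[simulate] integration events (seed ", seeds[["events"]], ")")
  sim <- simulateIntegrations(circles, host, cfg$events$nEventsPerCircle,
                              conservativeProb = cfg$events$conservativeProb,
                              orientationProb = cfg$events$orientationProb,
                              seed = seeds[["events"]])
  writeTruthEvents(sim$events, pth("truth.bed"), pth("truth.json"))
  writeXStringSet(sim$integratedSeqs, pth("integrated_host.fa"))
  say("[simulate] reads (seed ", seeds[["reads"]], ")")
  reads <- simulateReads(sim, coverage = cfg$reads$coverage,
                         readLen = cfg$reads$readLen,
                         errorRate = cfg$reads$errorRate,
                         fragMean = cfg$reads$fragMean,
                         fragSd = cfg$reads$fragSd, seed = seeds[["reads"]],
                         minOverhang = cfg$detect$minAlnLen)
  writeReads(reads, pth("reads_R1.fastq.gz"), pth("reads_R2.fastq.gz"))

  ## ---- stage 2: detect ----------------------------------------------------
  say("[detect] aligning ", 2 * length(reads$r1), " reads")
  chim <- extractChimeras(c(pth("reads_R1.fastq.gz"),
                            pth("reads_R2.fastq.gz")),
                          circles, host,
                          minAlnLen = cfg$detect$minAlnLen,
                          evalueMax = cfg$detect$evalueMax,
                          maxOverlap = cfg$detect$maxOverlap,
                          maxGap = cfg$detect$maxGap, k = cfg$detect$k,
                          stride = cfg$detect$stride,
                          xdrop = cfg$detect$xdrop)
  writeChimeras(chim, pth("chimeras.tsv"), pth("chimeras.bedpe"))

  ## ---- stage 3: profile ---------------------------------------------------
  say("[profile] ", nrow(chim), " chimeras")
  profiles <- buildProfiles(chim, circles, cfg$profile$clusterTol)
  bs <- do.call(rbind, lapply(profiles, function(p) {
    up <- p@upCounts; dn <- p@downCounts
    if (!length(up) && !length(dn)) return(NULL)
    data.frame(circle_id = p@circleId,
               side = rep(c("U", "D"), c(length(up), length(dn))),
               position = as.integer(c(names(up), names(dn))),
               count = c(unname(up), unname(dn)))
  }))
  write.table(bs, pth("breaksites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  classification <- classifyCircles(profiles, cfg$profile$cbcThreshold,
                                    cfg$profile$minSupport)
  write.table(classification, pth("classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  randomFractionReport(classification, pth("random_fractions.tsv"))

  ## ---- stage 4: him -------------------------------------------------------
  cbcIds <- classification$circle_id[classification$label == "CBC"]
  say("[him] calling motifs on ", length(cbcIds), " CBC circles")
  himCalls <- setNames(lapply(cbcIds, function(id)
    callHim(chim, circles[id], cfg$profile$clusterTol)), cbcIds)
  ht <- if (length(himCalls)) himTable(himCalls, circles, pth("him_table.tsv"))
        else data.frame()
  okCalls <- himCalls[vapply(himCalls, function(h)
    h@deletion@status == "ok", logical(1))]
  if (length(okCalls) >= 2L) {
    fl <- vapply(okCalls, function(h)
      junctionFlanks(circles[h@deletion@circleId], h@deletion, 20),
      character(2))
    writeXStringSet(DNAStringSet(setNames(fl["upstream", ],
                                          names(okCalls))),
                    pth("flanks_upstream.fa"))
    writeXStringSet(DNAStringSet(setNames(fl["downstream", ],
                                          names(okCalls))),
                    pth("flanks_downstream.fa"))
    writePfm(consensusLogo(fl["upstream", ])$pfm, pth("pfm_upstream.tsv"))
    writePfm(consensusLogo(fl["downstream", ])$pfm, pth("pfm_downstream.tsv"))
  }

  ## ---- stage 5: landscape -------------------------------------------------
  say("[landscape] insertion sites")
  land <- annotateSites(chim, host, cfg$profile$clusterTol)
  writeSitesBed(land$sites, pth("sites.bed"))
  write.table(land$perCircle, pth("landscape.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  track <- windowCounts(land$sites, cfg$landscape$windowSize)
  writeBedGraph(track, pth("windows.bedGraph"))
  motif <- flankMotifScan(land$sites, host, cfg$landscape$flank)
  if (length(motif$icByColumn))
    write.table(data.frame(column = seq_along(motif$icByColumn),
                           ic_bits = motif$icByColumn),
                pth("flank_ic.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

  ## ---- stage 6: index -----------------------------------------------------
  say("[index] qPCR time courses (seed ", seeds[["ct"]], ")")
  idxReport <- data.frame()
  if (nrow(sim$events)) {
    intact <- intactHimIds(circles)
    evCbc <- sim$events[sim$events$circle_id %in% intact, ]
    if (nrow(evCbc)) {
      fr <- waveFractions(evCbc, fMax = cfg$index$fMax)
      ct <- simulateCT(fr, baselineCtHim = cfg$index$baselineCtHim,
                       baselineCtWim = cfg$index$baselineCtWim,
                       efficiency = cfg$index$efficiency,
                       noiseSd = cfg$index$noiseSd,
                       replicates = cfg$index$replicates,
                       seed = seeds[["ct"]])
      series <- lapply(computeIndex(ct), classifyTiming,
                       onsetThresholdPct = cfg$index$onsetThresholdPct)
      idxReport <- indexReport(series, pth("index.tsv"))
    }
  }

  ## ---- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "himseek",
    version = as.character(utils::packageVersion("himseek")),
    config = cfg, stage_seeds = as.list(seeds),
    n_reads = 2L * length(reads$r1), n_chimeras = nrow(chim),
    n_cbc = sum(classification$label == "CBC"),
    n_rbc = sum(classification$label == "RBC"),
    max_flank_ic_bits = motif$maxIC,
    files = as.list(setNames(unname(tools::md5sum(file.path(outdir, files))),
                             files)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  say("[done] ", manifest$n_chimeras, " chimeras; ", manifest$n_cbc,
      " CBC / ", manifest$n_rbc, " RBC")
  invisible(list(circles = circles, host = host, sim = sim, chimeras = chim,
                 profiles = profiles, classification = classification,
                 himCalls = himCalls, himTable = ht, landscape = land,
                 windowTrack = track, flankMotif = motif, index = idxReport,
                 manifest = manifest))
}
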