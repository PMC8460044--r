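#' Default pipeline configuration
#'
#' Returns the full nested parameter list driving [runPipeline()]. The
#' defaults describe the "paper-scale-mini" simulated cohort: 30 circles of
#' which 19 carry an intact HIM (with per-circle conservative-break
#' probabilities set to the published per-CBC conserved fractions), 1500
#' integration events per circle into a 5 Mb two-scaffold host, and paired
#' 150 bp reads at a coverage that yields on the order of 1.4 thousand
#' chimeras per circle — matching the scale of the published chimeric-read
#' yield while keeping a single run to a couple of minutes. Every tunable of
#' the downstream stages is exposed here; stage defaults equal the
#' documented defaults of the corresponding functions.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    host = list(nScaffolds = 2L, scaffoldLength = 2500000L,
                geneDensity = 0.4),
    circles = list(nCircles = 30L, lengthRange = c(800L, 1600L),
                   nWithHim = 19L, spacerLenRange = c(39L, 72L),
                   proximityRange = c(128L, 472L)),
    events = list(nEventsPerCircle = 1500L, conservativeProb = NULL,
                  orientationProb = 0.5),
    reads = list(coverage = 0.85, readLen = 150L, errorRate = 0.002,
                 fragMean = 400, fragSd = 30),
    detect = list(minAlnLen = 28L, evalueMax = 1e-5, maxOverlap = 10L,
                  maxGap = 10L, k = 15L, stride = 5L, xdrop = 20L),
    profile = list(clusterTol = 3L, cbcThreshold = 0.35, minSupport = 20L),
    landscape = list(windowSize = 100000L, flank = 20L),
    index = list(baselineCtHim = 24, baselineCtWim = 22, efficiency = 1.0,
                 noiseSd = 0.15, replicates = 3L, onsetThresholdPct = 25,
                 fMax = 0.7)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at either nesting level) are rejected; missing keys are
#' filled from [defaultConfig()].
#'
#' @param config nested list of overrides (possibly partial).
#' @return completed configuration list.
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  unknownTop <- setdiff(names(config), names(def))
  if (length(unknownTop))
    stop("unknown configuration keys: ", paste(unknownTop, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      if (!is.list(config[[sec]]))
        stop("configuration section '", sec, "' must be a list")
      unknown <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(unknown))
        stop("unknown configuration keys in '", sec, "': ",
             paste(unknown, collapse = ", "))
      def[[sec]] <- modifyList(def[[sec]], config[[sec]])
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  if (is.null(def$seed) || is.na(def$seed))
    stop("configuration must carry an integer seed")
  def$seed <- as.integer(def$seed)
  def
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @export
readConfig <- function(path) {
  validateConfig(yaml::read_yaml(path))
}

#' @rdname readConfig
#' @param config configuration list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
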