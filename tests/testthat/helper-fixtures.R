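# Shared fixtures, built once per test run.

suppressMessages({
  library(Biostrings)
  library(GenomicRanges)
})

.fx <- new.env(parent = emptyenv())

# small cohort: 4 circles (2 with HIMs), one 100 kb scaffold, error-free
# reads — enough for detection/profiling tests in a couple of seconds
smallCohort <- function() {
  if (!is.null(.fx$sc)) return(.fx$sc)
  circles <- generateCircles(nCircles = 4, lengthRange = c(900, 1500),
                             nWithHim = 2, seed = 11)
  host <- generateHostGenome(1, 100000, 0.4, seed = 3)
  sim <- simulateIntegrations(circles, host, nEventsPerCircle = 20,
                              conservativeProb = 1, seed = 5)
  reads <- simulateReads(sim, coverage = 4, errorRate = 0, seed = 7)
  chimeras <- extractChimeras(reads, circles, host)
  .fx$sc <- list(circles = circles, host = host, sim = sim, reads = reads,
                 chimeras = chimeras)
  .fx$sc
}

# a mixed-mode cohort: conservative probability 0.6 on HIM circles, with
# sequencing errors — for classification threshold behaviour
mixedCohort <- function() {
  if (!is.null(.fx$mx)) return(.fx$mx)
  circles <- generateCircles(nCircles = 6, lengthRange = c(900, 1500),
                             nWithHim = 3, seed = 21)
  host <- generateHostGenome(1, 150000, 0.4, seed = 22)
  sim <- simulateIntegrations(circles, host, nEventsPerCircle = 60,
                              conservativeProb = 0.6, seed = 23)
  reads <- simulateReads(sim, coverage = 3, errorRate = 0.002, seed = 24)
  chimeras <- extractChimeras(reads, circles, host)
  .fx$mx <- list(circles = circles, host = host, sim = sim, reads = reads,
                 chimeras = chimeras)
  .fx$mx
}

# junction-flank fixture built from the canonical printed arm sequences with
# {A,C}-alphabet filler, whose reverse complement can share no base with
# itself -> planted arms are provably the only inverted repeats
armFixtureCircle <- function(spacerLen = 50, prox = 200, len = 2000) {
  filler <- function(n) paste(rep(c("A", "C"), length.out = n), collapse = "")
  ds <- prox + 2L
  pre <- filler(ds - 17L)           # up to the base before the upstream block
  block_up <- paste0("TAAATTTC", "ACA", "CTGGT")
  spacer <- filler(spacerLen)
  block_dn <- paste0("ACCAG", "AAA", "GAAATTTA")
  post <- filler(len - nchar(pre) - 16L - spacerLen - 16L)
  seqchr <- paste0(pre, block_up, spacer, block_dn, post)
  substr(seqchr, 2, 5) <- "AGCT"    # WIM content
  list(seq = seqchr, delStart = ds, delEnd = ds + spacerLen - 1L,
       U = ds - 1L, D = ds + spacerLen)
}
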