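test_that("host genome generator hits the requested gene density and is seed-deterministic", {
  hg <- generateHostGenome(2, 100000, geneDensity = 0.4, seed = 42)
  genic <- sum(width(hostGenes(hg)))
  expect_equal(genic / sum(scaffoldLengths(hg)), 0.4, tolerance = 0.05)
  ## genes are non-overlapping: reduce() merges nothing
  expect_equal(length(GenomicRanges::reduce(hostGenes(hg),
                                            min.gapwidth = 0L)),
               length(hostGenes(hg)))
  ## determinism: byte-identical FASTA + GFF3
  d1 <- file.path(tempdir(), "hg1"); d2 <- file.path(tempdir(), "hg2")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  writeHostGenome(hg, file.path(d1, "h.fa"), file.path(d1, "h.gff3"))
  writeHostGenome(generateHostGenome(2, 100000, geneDensity = 0.4, seed = 42),
                  file.path(d2, "h.fa"), file.path(d2, "h.gff3"))
  expect_identical(readLines(file.path(d1, "h.fa")),
                   readLines(file.path(d2, "h.fa")))
  expect_identical(readLines(file.path(d1, "h.gff3")),
                   readLines(file.path(d2, "h.gff3")))
})

test_that("empty host genome is valid and writes valid empty outputs", {
  hg <- generateHostGenome(0, integer(0), seed = 1)
  expect_equal(length(hostSeqs(hg)), 0L)
  expect_equal(length(hostGenes(hg)), 0L)
  expect_error(generateHostGenome(1, 500, seed = 1), ">= 1000")
})

test_that("circle generator plants WIMs and the requested number of intact HIMs", {
  cs <- generateCircles(nCircles = 30, lengthRange = c(800, 1600),
                        nWithHim = 19, seed = 7)
  info <- circleInfo(cs)
  expect_equal(sum(info$has_him), 19L)
  expect_equal(sum(!info$has_him), 11L)
  ## WIM contains AGCT on every circle (validity also enforces this)
  wim <- Biostrings::subseq(circleSeqs(cs), 1, info$wim_end)
  expect_true(all(Biostrings::vcountPattern("AGCT", wim) > 0))
  ## canonical arms: revcomp of upstream 8-nt arm equals downstream arm
  him <- himTruth(cs)
  for (i in seq_len(nrow(him))) {
    s <- as.character(circleSeqs(cs)[[match(him$circle_id[i],
                                            circleIds(cs))]])
    a8u <- substr(s, him$arm8_up_start[i], him$arm8_up_start[i] + 7L)
    a8d <- substr(s, him$arm8_down_start[i], him$arm8_down_start[i] + 7L)
    expect_identical(a8u, "TAAATTTC")
    expect_identical(revcomp(a8u), a8d)
  }
  ## spacer lengths within the simulated truth bounds
  sl <- him$spacer_end - him$spacer_start + 1L
  expect_true(all(sl >= 39 & sl <= 72))
})

test_that("nWithHim = 0 yields no HIM annotation; bad ranges error", {
  cs <- generateCircles(nCircles = 5, lengthRange = c(800, 900),
                        nWithHim = 0, seed = 2)
  expect_false(any(circleInfo(cs)$has_him))
  expect_error(generateCircles(nCircles = 5, lengthRange = c(500, 550),
                               nWithHim = 1, seed = 2),
               "exceed")
  expect_error(generateCircles(nCircles = 2, nWithHim = 3, seed = 2),
               "nWithHim")
})

test_that("HIM mutants delete the expected bases and shift coordinates", {
  cs <- generateCircles(nCircles = 3, lengthRange = c(1000, 1200),
                        nWithHim = 3, seed = 13)
  id <- circleIds(cs)[1]
  L0 <- circleInfo(cs)$length[1]
  m1 <- mutateHim(cs, id, "M1")
  m2 <- mutateHim(cs, id, "M2")
  m3 <- mutateHim(cs, id, "M3")
  expect_equal(circleInfo(m1)$length[1], L0 - 4L)
  expect_equal(circleInfo(m2)$length[1], L0 - 5L)
  expect_equal(circleInfo(m3)$length[1], L0 - 9L)
  expect_equal(circleInfo(m3)$mutation[1], "M3")
  ## spacer still delimited correctly after the shift: the downstream 5-nt
  ## arm sequence is unchanged
  i2 <- circleInfo(m2)
  s2 <- as.character(circleSeqs(m2)[[1]])
  expect_identical(substr(s2, i2$arm5_down_start[1],
                          i2$arm5_down_start[1] + 4L), "ACCAG")
  ## mutating a HIM-less circle is an invalid argument
  csNo <- generateCircles(nCircles = 2, lengthRange = c(800, 900),
                          nWithHim = 0, seed = 3)
  expect_error(mutateHim(csNo, circleIds(csNo)[1], "M1"), "no intact HIM")
})

test_that("conservative events delete exactly the spacer; mutants and HIM-less circles break randomly", {
  cs <- generateCircles(nCircles = 2, lengthRange = c(1000, 1400),
                        nWithHim = 2, seed = 31)
  hg <- generateHostGenome(1, 50000, 0.2, seed = 32)
  id <- circleIds(cs)
  sim <- simulateIntegrations(cs, hg, nEventsPerCircle = 50,
                              conservativeProb = 1, seed = 33)
  him <- circleInfo(cs)
  for (i in 1:2) {
    ev <- sim$events[sim$events$circle_id == id[i], ]
    expect_true(all(ev$mode == "conservative"))
    expect_true(all(ev$deleted_len ==
                      him$spacer_end[i] - him$spacer_start[i] + 1L))
    expect_true(all(ev$up_junction == him$spacer_start[i] - 1L))
    expect_true(all(ev$down_junction == him$spacer_end[i] + 1L))
  }
  ## M3 mutant: zero conservative events regardless of probability
  m3 <- mutateHim(cs, mutation = "M3")
  sim3 <- simulateIntegrations(m3, hg, nEventsPerCircle = 50,
                               conservativeProb = 1, seed = 34)
  expect_true(all(sim3$events$mode == "random"))
  expect_true(all(sim3$events$deleted_len == 0L))
  ## explicitly requesting conservative breaks on a mutant is a contract
  ## violation
  expect_error(simulateIntegrations(m3, hg, 10,
                                    conservativeProb = setNames(1, id[1]),
                                    seed = 35),
               "contract violation")
})

test_that("zero events leave the host untouched; truth records round-trip", {
  sc <- smallCohort()
  sim0 <- simulateIntegrations(sc$circles, sc$host, nEventsPerCircle = 0,
                               seed = 9)
  expect_identical(as.character(sim0$integratedSeqs),
                   as.character(hostSeqs(sc$host)))
  ## BED + JSON round trip
  td <- tempdir()
  bp <- file.path(td, "truth.bed"); jp <- file.path(td, "truth.json")
  writeTruthEvents(sc$sim$events, bp, jp)
  back <- readTruthEvents(jp)
  expect_equal(back$event_id, sc$sim$events$event_id)
  expect_equal(back$host_pos, sc$sim$events$host_pos)
  expect_equal(back$up_junction, sc$sim$events$up_junction)
  expect_equal(back$deleted_len, sc$sim$events$deleted_len)
  bed <- readTruthBed(bp)
  expect_equal(bed$host_pos, sc$sim$events$host_pos)
  expect_equal(bed$circle_id, sc$sim$events$circle_id)
  expect_equal(bed$mode, sc$sim$events$mode)
})

test_that("read counts follow coverage arithmetic and zero-error reads are exact substrings", {
  seqs <- Biostrings::DNAStringSet(setNames(randomSeq(10000), "s1"))
  rs <- simulateReads(seqs, coverage = 30, readLen = 150, errorRate = 0,
                      seed = 17)
  expect_equal(length(rs$r1), round(30 * 10000 / 300))
  ref <- as.character(seqs[[1]])
  idx <- sample(length(rs$r1), 25)
  for (i in idx) {
    expect_true(grepl(as.character(rs$r1[[i]]), ref, fixed = TRUE))
    expect_true(grepl(revcomp(as.character(rs$r2[[i]])), ref, fixed = TRUE))
  }
  expect_error(simulateReads(seqs, coverage = 1, readLen = 20000, seed = 1),
               "readLen")
})

test_that("chimeric truth tags mark junction-spanning reads and round-trip through FASTQ", {
  sc <- smallCohort()
  rs <- sc$reads
  ## every chimeric-tagged read interval spans a junction with >= 28 nt on
  ## both sides, checked against the junction map
  jn <- sc$sim$junctions
  meta <- rs$meta
  chim <- meta[meta$tag == "chimeric", ]
  expect_gt(nrow(chim), 0)
  jpos <- sort(c(jn$int_start - 1L, jn$int_end))
  ok <- vapply(seq_len(nrow(chim)), function(i) {
    any(jpos >= chim$start[i] + 27L & jpos <= chim$end[i] - 28L)
  }, logical(1))
  expect_true(all(ok))
  ## tags survive a FASTQ round trip (plain and gzip parse identically)
  td <- tempdir()
  writeReads(rs, file.path(td, "t_R1.fastq"), file.path(td, "t_R2.fastq.gz"))
  r1 <- Biostrings::readDNAStringSet(file.path(td, "t_R1.fastq"),
                                     format = "fastq")
  tags <- parseReadTags(names(r1))
  expect_equal(tags$tag, meta$tag[meta$mate == 1])
  expect_equal(tags$event_id, meta$event_id[meta$mate == 1])
  rs2 <- simulateReads(sc$sim, coverage = 4, errorRate = 0, seed = 7)
  writeReads(rs2, file.path(td, "u_R1.fastq.gz"), file.path(td, "u_R2.fastq.gz"))
  r1gz <- Biostrings::readDNAStringSet(file.path(td, "u_R1.fastq.gz"),
                                       format = "fastq")
  expect_identical(as.character(r1gz), as.character(r1))
})

test_that("chimeric read yield grows linearly with coverage", {
  sc <- smallCohort()
  n1 <- sum(sc$reads$meta$tag == "chimeric")
  rs2 <- simulateReads(sc$sim, coverage = 8, errorRate = 0, seed = 77)
  n2 <- sum(rs2$meta$tag == "chimeric")
  ## doubling coverage doubles the expectation; allow 3 Poisson sigma
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1))
})

test_that("stochastic operations demand a seed", {
  expect_error(generateCircles(nCircles = 2, nWithHim = 0), "seed")
  expect_error(generateHostGenome(1, 2000, 0.3), "seed")
  sc <- smallCohort()
  expect_error(simulateIntegrations(sc$circles, sc$host, 1), "seed")
  expect_error(simulateReads(sc$sim, coverage = 1), "seed")
})
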