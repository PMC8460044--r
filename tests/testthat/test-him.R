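# Deletion-call arithmetic is anchored on the published junction
# coordinates; motif detection on flanks constructed from the printed arm
# sequences; proximity on both the linear and the wrap-around geometry.

test_that("deletion calls reproduce the published coordinate arithmetic", {
  ## junction pair (4302, 4353) -> deletion 4303-4352, 50 nt
  d <- inferDeletion(c(4302L, 4353L), 4572L)
  expect_equal(d@delStart, 4303L)
  expect_equal(d@delEnd, 4352L)
  expect_equal(d@delLen, 50L)
  ## junction pair (129, 202) -> deletion 130-201, 72 nt
  d2 <- inferDeletion(c(129L, 202L), 5000L)
  expect_equal(d2@delStart, 130L)
  expect_equal(d2@delEnd, 201L)
  expect_equal(d2@delLen, 72L)
  ## degenerate: adjacent junctions delete nothing
  d3 <- inferDeletion(c(100L, 101L), 5000L)
  expect_equal(d3@status, "degenerate")
  expect_equal(d3@delLen, 0L)
  ## a deletion spanning the origin wraps
  d4 <- inferDeletion(c(4990L, 11L), 5000L)
  expect_equal(d4@delStart, 4991L)
  expect_equal(d4@delEnd, 10L)
  expect_equal(d4@delLen, 20L)
})

test_that("profiles without a modal pair give a not-applicable call", {
  ch <- data.frame(circle_id = character(0),
                   viral_junction_pos = integer(0),
                   junction_side = character(0))
  p <- buildProfile(ch, "c1", circleLength = 3000)
  d <- inferDeletion(p, 3000L)
  expect_equal(d@status, "not_applicable")
  hc <- detectInvertedRepeat(randomSeq(3000), d)
  expect_false(hc@intact)
})

test_that("the printed 8-nt and 5-nt arms are detected on a constructed flank", {
  fx <- armFixtureCircle(spacerLen = 50)
  del <- inferDeletion(c(fx$U, fx$D), nchar(fx$seq))
  expect_equal(del@delLen, 50L)
  hc <- detectInvertedRepeat(fx$seq, del)
  expect_true(hc@intact)
  expect_equal(hc@arm8$len, 8L)
  expect_equal(hc@arm5$len, 5L)
  expect_equal(hc@arm8$up_seq, "TAAATTTC")
  expect_equal(hc@arm8$down_seq, "GAAATTTA")
  expect_equal(hc@arm5$up_seq, "CTGGT")
  expect_equal(hc@arm5$down_seq, "ACCAG")
  expect_equal(revcomp(hc@arm8$up_seq), hc@arm8$down_seq)
  expect_equal(revcomp(hc@arm5$up_seq), hc@arm5$down_seq)
})

test_that("random sequence contains no intact motif call", {
  set.seed(81)
  s <- randomSeq(2000)
  hc <- detectInvertedRepeat(s, inferDeletion(c(800L, 861L), 2000L))
  expect_false(hc@intact)
})

test_that("M1 loses the 8-nt pair, M2 the 5-nt pair; both lose intactness", {
  cs <- generateCircles(nCircles = 1, lengthRange = c(1200, 1200),
                        nWithHim = 1, seed = 91)
  info <- circleInfo(cs)
  del0 <- inferDeletion(c(info$spacer_start - 1L, info$spacer_end + 1L),
                        info$length)
  wt <- detectInvertedRepeat(cs, del0)
  expect_true(wt@intact)

  m1 <- mutateHim(cs, mutation = "M1")
  i1 <- circleInfo(m1)
  del1 <- inferDeletion(c(i1$spacer_start - 1L, i1$spacer_end + 1L),
                        i1$length)
  hc1 <- detectInvertedRepeat(m1, del1)
  expect_false(hc1@intact)
  expect_equal(length(hc1@arm8), 0L)             # 8-nt pair gone
  expect_equal(hc1@arm5$up_seq, "CTGGT")         # 5-nt pair still there

  m2 <- mutateHim(cs, mutation = "M2")
  i2 <- circleInfo(m2)
  del2 <- inferDeletion(c(i2$spacer_start - 1L, i2$spacer_end + 1L),
                        i2$length)
  hc2 <- detectInvertedRepeat(m2, del2)
  expect_false(hc2@intact)
  ## deleting the upstream CTGGT removes the 5-nt pair and breaks the
  ## mirrored-offset geometry of the remaining arms
  expect_true(length(hc2@arm5) == 0L ||
                hc2@arm5$up_seq != "CTGGT")
})

test_that("proximity follows the exclusive-gap convention on both geometries", {
  ## linear case: deletion at 407-445 on a long circle -> 405
  d <- inferDeletion(c(406L, 446L), 5000L)
  expect_equal(wimHimProximity(5000L, d), 405L)
  ## wrap-around case: length 4572, deletion 4303-4352 -> gap 220 beats 4301
  d2 <- inferDeletion(c(4302L, 4353L), 4572L)
  expect_equal(wimHimProximity(4572L, d2), 220L)
  ## brute-force check of both circular gaps
  bruteGaps <- function(L, ds, de) {
    fwd <- (1 - de - 1) %% L   # walking forward from del end to WIM base 1
    back <- (ds - 1 - 1) %% L  # walking back from del start
    min(fwd, back)
  }
  expect_equal(wimHimProximity(4572L, d2), bruteGaps(4572, 4303, 4352))
  expect_equal(wimHimProximity(5000L, d), bruteGaps(5000, 407, 445))
  ## deletion immediately after the WIM start -> 0
  d3 <- inferDeletion(c(1L, 40L), 5000L)
  expect_equal(wimHimProximity(5000L, d3), 0L)
})

test_that("detection commutes with reverse complementation of the circle", {
  fx <- armFixtureCircle(spacerLen = 44, prox = 160, len = 1500)
  L <- nchar(fx$seq)
  hc <- detectInvertedRepeat(fx$seq, inferDeletion(c(fx$U, fx$D), L))
  rcSeq <- revcomp(fx$seq)
  ## junctions map to L - x + 1 and swap roles on the reverse complement
  rcU <- L - fx$D + 1L
  rcD <- L - fx$U + 1L
  hcRC <- detectInvertedRepeat(rcSeq, inferDeletion(c(rcU, rcD), L))
  expect_true(hcRC@intact)
  expect_equal(hcRC@arm8$len, hc@arm8$len)
  expect_equal(hcRC@arm5$len, hc@arm5$len)
  ## the arm pairs map to each other under revcomp
  expect_equal(hcRC@arm8$up_seq, revcomp(hc@arm8$down_seq))
  expect_equal(hcRC@arm5$up_seq, revcomp(hc@arm5$down_seq))
})

test_that("deletion-length arithmetic holds over every simulated CBC call", {
  sc <- smallCohort()
  him <- himTruth(sc$circles)
  for (id in him$circle_id) {
    hc <- callHim(sc$chimeras, sc$circles[id])
    d <- hc@deletion
    expect_equal(d@status, "ok")
    L <- d@circleLength
    expect_equal(((d@delEnd - d@delStart) %% L) + 1L, d@delLen)
    ## planted recovery: called deletion within 2 nt of the spacer truth
    i <- match(id, him$circle_id)
    expect_lte(abs(d@delStart - him$spacer_start[i]), 2L)
    expect_lte(abs(d@delEnd - him$spacer_end[i]), 2L)
    expect_true(hc@intact)
    expect_equal(hc@proximity, him$proximity[i])
  }
})

test_that("consensus logos recover planted arms; deleted spacers share no consensus", {
  ## identical flanks -> every column frequency 1
  cl <- consensusLogo(rep("TAAATTTCACACTGGT", 10))
  expect_true(all(apply(cl$pfm, 2, max) == 1))
  expect_equal(cl$consensus, "TAAATTTCACACTGGT")
  expect_error(consensusLogo(c("ACGT", "ACGTA")), "equal lengths")
  expect_error(consensusLogo("ACGT"), "at least 2")
  ## simulated CBC cohort: junction flanks carry the arms, spacers do not
  set.seed(82)
  circles <- generateCircles(nCircles = 24, lengthRange = c(900, 1400),
                             nWithHim = 24, seed = 83)
  info <- circleInfo(circles)
  up <- dn <- sp <- character(0)
  for (i in seq_len(nrow(info))) {
    d <- inferDeletion(c(info$spacer_start[i] - 1L, info$spacer_end[i] + 1L),
                       info$length[i])
    fl <- junctionFlanks(circles[i], d, 20)
    up <- c(up, fl[["upstream"]])
    dn <- c(dn, fl[["downstream"]])
    sp <- c(sp, substr(as.character(circleSeqs(circles)[[i]]),
                       info$spacer_start[i], info$spacer_start[i] + 34L))
  }
  expect_true(grepl("TAAATTTC", consensusLogo(up)$consensus))
  expect_true(grepl("GAAATTTA", consensusLogo(dn)$consensus))
  spacerCl <- consensusLogo(sp)
  expect_lt(spacerCl$maxColFreq, 0.6)
})
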