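# Break-site profiles are exercised both on constructed junction tables and
# on simulated cohorts with known break modes.

.chimTable <- function(pos, side, circle = "c1") {
  data.frame(circle_id = rep_len(circle, length(pos)),
             viral_junction_pos = as.integer(pos),
             junction_side = side, stringsAsFactors = FALSE)
}

test_that("chimeras at a single junction pair give conserved fraction 1", {
  ch <- .chimTable(c(rep(500, 50), rep(561, 50)),
                   rep(c("U", "D"), each = 50))
  p <- buildProfile(ch, "c1", circleLength = 2000)
  expect_equal(nChimeras(p), 100L)
  expect_equal(unname(modalPair(p)), c(500L, 561L))
  expect_equal(conservedFraction(p), 1.0)
})

test_that("well-separated uniform junctions give near-zero conserved fraction", {
  pos <- seq(10, 1990, by = 20)  # 100 distinct positions, 20 nt apart
  ch <- .chimTable(pos, rep(c("U", "D"), 50))
  p <- buildProfile(ch, "c1", clusterTol = 3, circleLength = 2000)
  expect_lte(conservedFraction(p), 0.02)
})

test_that("profiles are invariant under permutation of chimera order", {
  set.seed(71)
  pos <- sample(c(rep(300, 30), sample(1000, 40)))
  side <- sample(rep(c("U", "D"), 35))
  ch <- .chimTable(pos, side)
  p1 <- buildProfile(ch, "c1", circleLength = 1200)
  shuf <- sample(nrow(ch))
  p2 <- buildProfile(ch[shuf, ], "c1", circleLength = 1200)
  expect_equal(conservedFraction(p1), conservedFraction(p2))
  expect_equal(modalPair(p1), modalPair(p2))
})

test_that("raising the cluster tolerance never decreases the conserved fraction", {
  set.seed(72)
  ch <- .chimTable(sample(500, 300, replace = TRUE),
                   sample(c("U", "D"), 300, replace = TRUE))
  fr <- vapply(c(0, 1, 2, 3, 5, 8, 12), function(tol)
    conservedFraction(buildProfile(ch, "c1", clusterTol = tol,
                                   circleLength = 500)), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("empty input yields an empty profile, not an error", {
  p <- buildProfile(.chimTable(integer(0), character(0)), "c1",
                    circleLength = 1000)
  expect_equal(nChimeras(p), 0L)
  expect_true(all(is.na(modalPair(p))))
  expect_equal(conservedFraction(p), 0)
  cls <- classifyCircle(p)
  expect_equal(cls$label, "insufficient_support")
})

test_that("classification thresholds behave at the boundary", {
  mk <- function(frac, n = 100) {
    nCons <- round(frac * n)
    ch <- .chimTable(c(rep(100, nCons), seq(300, by = 25,
                                            length.out = n - nCons)),
                     rep("U", n))
    buildProfile(ch, "c1", circleLength = 5000)
  }
  expect_equal(classifyCircle(mk(1.0))$label, "CBC")
  expect_equal(classifyCircle(mk(0.34))$label, "RBC")
  expect_equal(classifyCircle(mk(0.36))$label, "CBC")
  ## below min support the label is withheld
  expect_equal(classifyCircle(mk(1.0, n = 10))$label, "insufficient_support")
})

test_that("simulated conservative fraction is recovered in the profile", {
  mx <- mixedCohort()
  him <- himTruth(mx$circles)
  profs <- buildProfiles(mx$chimeras, mx$circles)
  ## truth: fraction of chimeric reads that stem from conservative events
  tags <- rbind(parseReadTags(names(mx$reads$r1)),
                parseReadTags(names(mx$reads$r2)))
  tags <- tags[tags$tag == "chimeric", ]
  ev <- mx$sim$events
  consRead <- tapply(ev$mode[match(tags$event_id, ev$event_id)] ==
                       "conservative", ev$circle_id[match(tags$event_id,
                                                          ev$event_id)],
                     mean)
  for (id in him$circle_id) {
    expect_equal(conservedFraction(profs[[id]]), unname(consRead[[id]]),
                 tolerance = 0.1)
    ## and the realised fraction sits near the nominal probability 0.6
    expect_equal(unname(consRead[[id]]), 0.6, tolerance = 0.35)
  }
  ## HIM-less circles are near zero
  noHim <- setdiff(circleIds(mx$circles), him$circle_id)
  for (id in noHim) expect_lte(conservedFraction(profs[[id]]), 0.15)
})

test_that("classification accuracy against truth HIM status is high across replicates", {
  correct <- 0L; total <- 0L
  for (rep in 1:6) {
    circles <- generateCircles(nCircles = 4, lengthRange = c(900, 1400),
                               nWithHim = 2, seed = 400 + rep)
    host <- generateHostGenome(1, 60000, 0.3, seed = 500 + rep)
    sim <- simulateIntegrations(circles, host, nEventsPerCircle = 30,
                                conservativeProb = 0.8, seed = 600 + rep)
    rs <- simulateReads(sim, coverage = 3, errorRate = 0.002,
                        seed = 700 + rep)
    chim <- extractChimeras(rs, circles, host)
    cls <- classifyCircles(buildProfiles(chim, circles))
    truth <- ifelse(hasHim(circles)[cls$circle_id], "CBC", "RBC")
    ok <- cls$support >= 50
    correct <- correct + sum((cls$label == truth)[ok])
    total <- total + sum(ok)
  }
  expect_gte(total, 12)
  expect_gte(correct / total, 0.95)
})

test_that("random-fraction report reproduces per-circle random percentages", {
  sc <- smallCohort()
  cls <- classifyCircles(buildProfiles(sc$chimeras, sc$circles))
  rep <- randomFractionReport(cls)
  expect_equal(rep$circle_id, sort(cls$circle_id))
  expect_equal(rep$random_pct, 100 * (1 - rep$conserved_fraction))
  ## all-conservative circles have random fraction ~0, HIM-less ~1
  him <- hasHim(sc$circles)[rep$circle_id]
  expect_true(all(rep$random_fraction[him] <= 0.1))
  expect_true(all(rep$random_fraction[!him] >= 0.85))
})
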