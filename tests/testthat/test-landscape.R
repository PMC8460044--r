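library(GenomicRanges)

.siteGR <- function(scaffold, pos, sl, circle = "c1", support = 1L,
                    annotation = "genic") {
  gr <- GRanges(rep_len(scaffold, length(pos)), IRanges(pos, width = 1L),
                seqinfo = GenomeInfoDb::Seqinfo(names(sl), unname(sl)))
  mcols(gr)$circle_id <- rep_len(circle, length(gr))
  mcols(gr)$support <- rep_len(support, length(gr))
  mcols(gr)$annotation <- rep_len(annotation, length(gr))
  gr
}

test_that("sites inside gene intervals are genic; fractions follow the binomial expectation", {
  host <- generateHostGenome(2, 200000, 0.4, seed = 201)
  g <- hostGenes(host)
  inGene <- start(g)[1] + 5L
  chim <- data.frame(circle_id = "c1",
                     host_scaffold = as.character(seqnames(g))[1],
                     host_junction_pos = inGene)
  ann <- annotateSites(chim, host)
  expect_equal(as.character(mcols(ann$sites)$annotation), "genic")
  ## uniform sites at gene density 0.4: genic fraction 0.40 +/- 0.05
  set.seed(202)
  sl <- scaffoldLengths(host)
  n <- 1000
  sc <- sample(names(sl), n, replace = TRUE, prob = sl)
  chimU <- data.frame(circle_id = "cU", host_scaffold = sc,
                      host_junction_pos = vapply(sc, function(s)
                        sample.int(sl[[s]], 1), integer(1)))
  annU <- annotateSites(chimU, host, clusterTol = 0)
  expect_equal(annU$perCircle$genic_fraction, 0.4, tolerance = 0.125)
  expect_equal(annU$backgroundGenicFraction, 0.4, tolerance = 0.01)
})

test_that("circles biased towards intergenic space are flagged as intergenic-preferring", {
  host <- generateHostGenome(1, 200000, 0.4, seed = 203)
  g <- GenomicRanges::reduce(hostGenes(host))
  sl <- scaffoldLengths(host)
  allPos <- seq_len(sl[[1]])
  genic <- unlist(lapply(seq_along(g), function(i) start(g)[i]:end(g)[i]))
  inter <- setdiff(allPos, genic)
  set.seed(204)
  mkChim <- function(id, pIntergenic, n = 200) {
    useInter <- runif(n) < pIntergenic
    data.frame(circle_id = id, host_scaffold = names(sl)[1],
               host_junction_pos = ifelse(useInter,
                                          sample(inter, n, replace = TRUE),
                                          sample(genic, n, replace = TRUE)))
  }
  chim <- rbind(mkChim("c_inter1", 0.8), mkChim("c_inter2", 0.8),
                mkChim("c_genic", 0.2))
  ann <- annotateSites(chim, host, clusterTol = 0)
  pc <- ann$perCircle
  expect_equal(pc$preference[pc$circle_id == "c_inter1"], "intergenic")
  expect_equal(pc$preference[pc$circle_id == "c_inter2"], "intergenic")
  expect_equal(pc$preference[pc$circle_id == "c_genic"], "genic")
})

test_that("unknown scaffolds in the chimera table raise a keyed error", {
  host <- generateHostGenome(1, 50000, 0.3, seed = 205)
  chim <- data.frame(circle_id = "c1", host_scaffold = "scaffold_99",
                     host_junction_pos = 10L)
  expect_error(annotateSites(chim, host), "scaffold_99")
})

test_that("window counts conserve sites and keep the last partial window", {
  sl <- c(s1 = 250000L)
  empty <- .siteGR("s1", integer(0), sl)
  t0 <- windowCounts(empty, 100000)
  expect_equal(length(t0), 3L)        # 100k, 100k, 50k
  expect_equal(width(t0)[3], 50000L)
  expect_true(all(mcols(t0)$score == 0))
  ## half-open windows: base 200000 is still in the second window
  ## ([100000, 200000) 0-based), base 200001 starts the partial third
  sites <- .siteGR("s1", c(5L, 50L, 99999L, 150000L, rep(2e5L, 5), 200001L),
                   sl)
  tr <- windowCounts(sites, 100000)
  expect_equal(sum(mcols(tr)$score), length(sites))
  expect_equal(mcols(tr)$score, c(3L, 6L, 1L))
  expect_error(windowCounts(sites, 0), "windowSize")
})

test_that("uniform insertions give Poisson-like window dispersion", {
  sl <- c(s1 = 10000000L, s2 = 10000000L)
  set.seed(206)
  n <- 2000
  sc <- sample(names(sl), n, replace = TRUE)
  sites <- .siteGR(sc, vapply(sc, function(s) sample.int(sl[[s]], 1),
                              integer(1)), sl)
  tr <- windowCounts(sites, 100000)
  counts <- mcols(tr)$score
  expect_equal(sum(counts), n)
  disp <- var(counts) / mean(counts)
  expect_lt(abs(disp - 1), 0.3)
})

test_that("flank information content: identical flanks saturate, uniform flanks stay near zero, planted motifs peak", {
  ## identical flanks: every column is 2 bits
  host <- Biostrings::DNAStringSet(setNames(strrep("ACGT", 2500), "s1"))
  sl <- c(s1 = 10000L)
  pos <- seq(41L, by = 4L, length.out = 100)   # same phase -> identical flanks
  sc1 <- flankMotifScan(.siteGR("s1", pos, sl), host, flank = 20)
  expect_equal(sc1$maxIC, 2, tolerance = 1e-9)
  expect_true(all(abs(sc1$icByColumn - 2) < 1e-9))
  ## uniform random insertion sites on a random genome: max IC < 0.3 bits
  set.seed(207)
  hostR <- Biostrings::DNAStringSet(setNames(randomSeq(300000), "s1"))
  slR <- c(s1 = 300000L)
  posR <- sample(50:299950, 600)
  scR <- flankMotifScan(.siteGR("s1", posR, slR), hostR, flank = 20)
  expect_lt(scR$maxIC, 0.3)
  expect_equal(scR$nUsed, 600L)
  ## planted AGCT at a fixed offset drives those columns to ~2 bits
  hostP <- hostR
  posP <- sample(50:299950, 300)
  for (p in posP) Biostrings::subseq(hostP[[1]], p + 5L, p + 8L) <-
    Biostrings::DNAString("AGCT")
  scP <- flankMotifScan(.siteGR("s1", posP, slR), hostP, flank = 20)
  planted <- scP$icByColumn[(20 + 1 + 5):(20 + 1 + 8)]
  expect_true(all(planted > 1.5))
  ## edge sites are truncated with a flag, not an error
  scE <- flankMotifScan(.siteGR("s1", c(5L, 150000L), slR), hostR, 20)
  expect_equal(scE$nTruncated, 1L)
  expect_equal(scE$nUsed, 1L)
})

test_that("insertion sites round-trip through BED and counts stay conserved end-to-end", {
  sc <- smallCohort()
  ann <- annotateSites(sc$chimeras, sc$host)
  expect_equal(sum(mcols(ann$sites)$support), nrow(sc$chimeras))
  tr <- windowCounts(ann$sites, 10000)
  expect_equal(sum(mcols(tr)$score), length(ann$sites))
  genicN <- sum(mcols(ann$sites)$annotation == "genic")
  interN <- sum(mcols(ann$sites)$annotation == "intergenic")
  expect_equal(genicN + interN, length(ann$sites))
  td <- tempdir()
  writeSitesBed(ann$sites, file.path(td, "sites.bed"))
  back <- readSitesBed(file.path(td, "sites.bed"),
                       scaffoldLengths(sc$host))
  expect_equal(start(back), start(ann$sites))
  expect_equal(as.character(mcols(back)$circle_id),
               mcols(ann$sites)$circle_id)
  expect_equal(mcols(back)$support, mcols(ann$sites)$support)
  expect_equal(as.character(mcols(back)$annotation),
               mcols(ann$sites)$annotation)
})
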