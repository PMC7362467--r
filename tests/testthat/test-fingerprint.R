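test_that("relative quantities are ratios to the reference peak", {
  areas <- rbind(S1 = c(2, 4, 8))
  cpm <- CommonPeakMatrix(makePeakTable(areas), referencePeak = 2L)
  rel <- relativeQuantities(cpm)
  expect_equal(unname(SummarizedExperiment::assay(rel, "relArea")[, "S1"]),
               c(0.5, 1, 2))
  # all-equal areas give all-1 relative areas
  cpm2 <- CommonPeakMatrix(makePeakTable(rbind(S1 = c(3, 3, 3))),
                           referencePeak = 2L)
  expect_equal(unname(SummarizedExperiment::assay(
    relativeQuantities(cpm2), "relArea")[, "S1"]), c(1, 1, 1))
})

test_that("relative quantities match an element-wise division oracle", {
  set.seed(31)
  areas <- matrix(runif(15, 1, 50), 3, 5,
                  dimnames = list(paste0("S", 1:3), NULL))
  cpm <- relativeQuantities(CommonPeakMatrix(makePeakTable(areas),
                                             referencePeak = 3L))
  relA <- SummarizedExperiment::assay(cpm, "relArea")
  for (i in 1:3) {
    for (k in 1:5) {
      expect_equal(unname(relA[k, i]), unname(areas[i, k] / areas[i, 3]))
    }
  }
  # reference entries are exactly 1 in both relative assays
  expect_equal(unname(relA[3, ]), rep(1, 3))
  expect_equal(unname(SummarizedExperiment::assay(cpm, "relRT")[3, ]),
               rep(1, 3))
})

test_that("construction rejects a zero-area reference peak by name", {
  areas <- rbind(S1 = c(2, 4, 8), S2 = c(1, 0, 3))
  expect_error(CommonPeakMatrix(makePeakTable(areas), referencePeak = 2L),
               "S2")
})

test_that("missing common peaks are imputed as zero with a warning", {
  long <- makePeakTable(rbind(S1 = c(2, 4, 8), S2 = c(1, 5, 3)))
  long <- long[-which(long$sample_id == "S2" & long$peak_id == 1L), ]
  expect_warning(cpm <- CommonPeakMatrix(long, referencePeak = 2L),
                 "imputed")
  expect_equal(SummarizedExperiment::assay(cpm, "area")["P1", "S2"], 0)
})

test_that("mean fingerprint is the per-peak arithmetic mean", {
  expect_equal(unname(meanFingerprint(rbind(c(1, 2)))), c(1, 2))
  expect_equal(unname(meanFingerprint(rbind(c(1, 2), c(3, 4)))), c(2, 3))
  set.seed(5)
  v <- matrix(runif(28 * 28), 28, 28)
  m <- meanFingerprint(v)
  loopMean <- vapply(seq_len(ncol(v)), function(k) sum(v[, k]) / nrow(v), 0)
  expect_equal(unname(m), loopMean)
})

test_that("similarity obeys the cosine definition and its identities", {
  expect_equal(fingerprintSimilarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(fingerprintSimilarity(c(1, 0), c(0, 1)), 0)
  set.seed(8)
  x <- runif(10)
  expect_equal(fingerprintSimilarity(x, x), 1)
  expect_equal(fingerprintSimilarity(x, 7 * x), 1)  # scale invariance
  u <- runif(10); v <- runif(10)
  expect_equal(fingerprintSimilarity(u, v), fingerprintSimilarity(v, u))
  expect_error(fingerprintSimilarity(c(0, 0), c(1, 1)), "zero-norm")
  expect_equal(fingerprintSimilarity(u, v, method = "correlation"),
               cor(u, v))
})

test_that("pairwise matrix is symmetric with unit diagonal and valid RSI", {
  set.seed(13)
  areas <- matrix(runif(6 * 9, 5, 100), 6, 9,
                  dimnames = list(paste0("S", 1:6), NULL))
  sim <- similarityMatrix(CommonPeakMatrix(makePeakTable(areas),
                                           referencePeak = 4L))
  P <- pairwiseSimilarity(sim)
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 6))
  expect_true(all(P >= -1 & P <= 1 + 1e-12))
  # identical samples scaled by arbitrary positive constants: cosine 1
  dup <- areas[rep(1, 4), ] * c(1, 2, 0.5, 10)
  rownames(dup) <- paste0("D", 1:4)
  simDup <- similarityMatrix(CommonPeakMatrix(makePeakTable(dup),
                                              referencePeak = 4L))
  expect_equal(unname(pairwiseSimilarity(simDup)),
               matrix(1, 4, 4), tolerance = 1e-12)
  expect_equal(unname(rsi(simDup)), rep(1, 4), tolerance = 1e-12)
})

test_that("cosine on raw areas equals cosine on relative areas", {
  set.seed(17)
  areas <- matrix(runif(5 * 12, 1, 80), 5, 12,
                  dimnames = list(paste0("S", 1:5), NULL))
  cpm <- relativeQuantities(CommonPeakMatrix(makePeakTable(areas),
                                             referencePeak = 6L))
  Praw <- pairwiseSimilarity(similarityMatrix(areas))
  Prel <- pairwiseSimilarity(similarityMatrix(cpm))
  expect_equal(unname(Praw), unname(Prel), tolerance = 1e-12)
})

test_that("a sample identical to the mean fingerprint has RSI 1", {
  set.seed(23)
  v <- matrix(runif(4 * 6, 1, 10), 4, 6)
  m <- meanFingerprint(v)
  expect_equal(fingerprintSimilarity(m, m), 1)
  withMean <- rbind(v, m)
  sim <- similarityMatrix(withMean)
  expect_equal(unname(rsi(sim)[5]),
               fingerprintSimilarity(m, meanFingerprint(withMean)))
})

test_that("RSI thresholds assign the published labels", {
  expect_warning(labels <- classifyByRSI(c(0.933, 0.478, 0.86)),
                 "unassigned")
  expect_equal(unname(labels), c("A", "B", "unassigned"))
  expect_error(classifyByRSI(1.2), "\\[-1, 1\\]")
  expect_error(classifyByRSI(0.5, high = 0.8, low = 0.9), "<=")
})

test_that("RSI grouping tracks the planted chemistry in a synthetic cohort", {
  coh <- simulateCohort(cohortSpec(), seed = 41)
  sim <- similarityMatrix(relativeQuantities(coh$peaks))
  isA <- coh$compounds$group == "A"
  # group carrying the majority chemistry scores the higher RSI
  expect_gt(cor(rsi(sim), as.numeric(isA), method = "spearman"), 0.5)
  expect_gt(median(rsi(sim)[isA]), median(rsi(sim)[!isA]))
})
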