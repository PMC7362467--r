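test_that("PCA reproduces eigenstructure and variance bookkeeping", {
  # rank-1 data: first component carries all variance
  x <- seq(-3, 3, length.out = 10)
  m1 <- pcaModel(cbind(x = x, y = 2 * x), scale = FALSE)
  expect_equal(m1@explainedVariance[1], 1, tolerance = 1e-12)

  set.seed(61)
  X <- matrix(rnorm(24), 6, 4)
  m <- pcaModel(X, center = TRUE, scale = FALSE)
  # eigen oracle: eigenvalues of the covariance = per-component variances
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(unname(apply(modelScores(m), 2, var)), ev[1:ncol(modelScores(m))],
               tolerance = 1e-10)
  # scores uncorrelated; total explained variance = total variance
  cc <- cov(modelScores(m))
  expect_equal(unname(cc[upper.tri(cc)]), rep(0, sum(upper.tri(cc))),
               tolerance = 1e-10)
  expect_equal(sum(apply(modelScores(m), 2, var)), sum(diag(cov(X))),
               tolerance = 1e-10)
  # loadings orthonormal
  expect_equal(crossprod(modelLoadings(m)),
               diag(ncol(modelLoadings(m))), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA drops constant features with a warning when scaling", {
  X <- cbind(a = rnorm(8), b = rep(2, 8), c = rnorm(8))
  expect_warning(m <- pcaModel(X), "constant")
  expect_equal(nrow(modelLoadings(m)), 2L)
})

test_that("OPLS-DA separates planted classes and not permuted ones", {
  set.seed(71)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 8), n, 8)
  X[lab == "b", 1:4] <- X[lab == "b", 1:4] + 3   # effect >> noise
  m <- oplsda(X, lab, seed = 5)
  expect_gt(modelQ2(m), 0.5)
  expect_lte(modelQ2(m), modelR2(m))
  # permutation null: Q2 collapses
  q2perm <- replicate(50, modelQ2(oplsda(X, sample(lab), seed = 5)))
  expect_lte(mean(q2perm), 0.05)
})

test_that("OPLS-DA is deterministic given the fold seed", {
  set.seed(72)
  X <- matrix(rnorm(20 * 5), 20, 5)
  lab <- rep(c("a", "b"), 10)
  m1 <- oplsda(X, lab, seed = 9)
  m2 <- oplsda(X, lab, seed = 9)
  expect_identical(modelQ2(m1), modelQ2(m2))
  expect_identical(m1@details$foldAssignment, m2@details$foldAssignment)
})

test_that("OPLS-DA rejects degenerate inputs", {
  X <- matrix(1, 10, 3)
  expect_error(oplsda(X, rep(c("a", "b"), 5)), "constant")
  expect_error(oplsda(matrix(rnorm(30), 10, 3), rep("a", 10)),
               "two classes")
  expect_warning(oplsda(matrix(rnorm(12 * 3), 12, 3),
                        rep(c("a", "b"), c(3, 9)), folds = 7),
                 "reducing folds")
})

test_that("Ward clustering follows the documented height convention", {
  # two points merge at their Euclidean distance (ward.D2 scale)
  two <- rbind(c(0, 0), c(3, 4))
  cl <- wardCluster(two, k = 2)
  expect_equal(cl$heights, 5)
  # duplicated points merge first at height zero
  X <- rbind(c(0, 0), c(0, 0), c(9, 9))
  cl2 <- wardCluster(X, k = 2)
  expect_equal(cl2$heights[1], 0)
  expect_true(all(diff(cl2$heights) >= 0))
  expect_error(wardCluster(two, k = 5), "exceeds")
})

test_that("Ward recovers well-separated simulated clusters exactly", {
  set.seed(83)
  X <- rbind(matrix(rnorm(10 * 3, 0), ncol = 3),
             matrix(rnorm(10 * 3, 8), ncol = 3))
  truth <- rep(1:2, each = 10)
  cl <- wardCluster(X, k = 2)
  expect_equal(length(unique(cl$labels[truth == 1])), 1L)
  expect_equal(length(unique(cl$labels[truth == 2])), 1L)
  expect_false(cl$labels[1] == cl$labels[20])
})

test_that("two-group t test matches the pooled-variance formula", {
  r <- tTestTwoGroup(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  same <- tTestTwoGroup(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(z <- tTestTwoGroup(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(z$p, 0)
  expect_error(tTestTwoGroup(1, c(1, 2)), ">= 2")
})

test_that("t-test null rejection rate is calibrated", {
  set.seed(91)
  p <- replicate(2000, tTestTwoGroup(rnorm(8), rnorm(8))$p)
  expect_gt(mean(p < 0.05), 0.035)
  expect_lt(mean(p < 0.05), 0.065)
})

test_that("Spearman equals Pearson on mean ranks and is monotone-invariant", {
  expect_equal(spearmanRho(1:5, c(2, 4, 6, 7, 9)), 1)
  expect_equal(spearmanRho(1:5, -(1:5)^3), -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  expect_equal(spearmanRho(x, y), cor(rank(x), rank(y)))
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearmanRho(exp(a), b), spearmanRho(a, b))  # monotone map
  expect_warning(r <- spearmanRho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearmanRho(1:2, 1:2), ">= 3")
})

test_that("correlation strength classes honour the published boundaries", {
  eps <- 1e-9
  expect_equal(rhoStrength(c(0.29, -0.75)), c("none", "strong"))
  expect_equal(rhoStrength(c(0.30 - eps, 0.30, 0.30 + eps)),
               c("none", "none", "weak"))
  expect_equal(rhoStrength(c(0.50 - eps, 0.50, 0.50 + eps)),
               c("weak", "moderate", "moderate"))
  expect_equal(rhoStrength(c(-0.70 + eps, -0.70, -0.70 - eps)),
               c("moderate", "strong", "strong"))
})

test_that("correlation network flags a planted monotone link", {
  set.seed(101)
  n <- 28
  gly <- rlnorm(n, 2, 0.4)
  dl <- data.frame(sample_id = paste0("S", 1:n),
                   I0 = 4000 - 900 * log(gly) + rnorm(n, 0, 80),
                   Tau = 0.55 - 0.12 * log(gly) + rnorm(n, 0, 0.01),
                   Beta = 1.9 - 0.25 * log(gly) + rnorm(n, 0, 0.03))
  dl$T <- decayTime(dl$Beta, dl$Tau)
  comp <- cbind(glycoside_total = gly, noise = rnorm(n))
  rownames(comp) <- dl$sample_id
  net <- correlationNetwork(comp, dl)
  planted <- net[net$compound == "glycoside_total", ]
  expect_true(all(planted$sign == "negative"))
  expect_true(all(planted$linear))
  # edge classification is a pure function of rho
  expect_equal(planted$strength, rhoStrength(planted$rho))
  expect_error(correlationNetwork(comp[-1, , drop = FALSE], dl),
               "mismatch")
})

test_that("edge lists round-trip through the TSV exporter", {
  edges <- data.frame(compound = c("x", "y"), dl_property = c("Tau", "T"),
                      rho = c(-0.8, 0.1), sign = c("negative", "positive"),
                      strength = c("strong", "none"),
                      linear = c(TRUE, FALSE))
  f <- tempfile(fileext = ".tsv")
  writeEdgeList(edges, f, linearOnly = TRUE)
  back <- read.delim(f)
  expect_equal(nrow(back), 1L)
  expect_equal(back$compound, "x")
  unlink(f)
})
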