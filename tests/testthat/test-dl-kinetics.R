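test_that("hyperbolic intensity evaluates the decay law", {
  expect_equal(dlIntensity(0, 1000, 0.5, 1.2), 1000)      # I(0) = I0
  expect_equal(dlIntensity(0.5, 1000, 0.5, 1), 500)       # t = Tau, Beta = 1
  expect_equal(dlIntensity(1.5, 1000, 0.5, 2), 62.5)      # 1000 / 4^2
  t <- seq(0, 30, by = 0.05)
  expect_true(all(diff(dlIntensity(t, 1000, 0.3, 1.2)) < 0))
  expect_error(dlIntensity(1, 1000, -0.5, 1), "must all be > 0")
  expect_error(dlIntensity(1, 1000, 0.5, 0), "must all be > 0")
  expect_error(dlIntensity(-1, 1000, 0.5, 1), ">= 0")
})

test_that("decay time follows the closed form", {
  expect_equal(decayTime(1, 1), exp(1) - 1, tolerance = 1e-12)
  expect_equal(decayTime(0.5, 2), (exp(2) - 1) * 2, tolerance = 1e-12)
  # large-Beta limit: T ~ Tau/Beta
  expect_equal(decayTime(1000, 1), 1.0005e-3, tolerance = 1e-3)
  expect_error(decayTime(0, 1), "> 0")
  expect_error(decayTime(1, -1), "> 0")
})

test_that("noiseless curves are recovered to well under 0.5%", {
  t <- (seq_len(600) - 0.5) * 0.05
  y <- round(dlIntensity(t, 1000, 0.5, 1.2))
  f <- fitHyperbolic(y)
  expect_true(f$converged)
  expect_lt(abs(f$I0 / 1000 - 1), 0.005)
  expect_lt(abs(f$Tau / 0.5 - 1), 0.005)
  expect_lt(abs(f$Beta / 1.2 - 1), 0.005)
})

test_that("degenerate curves are rejected", {
  expect_error(fitHyperbolic(rep(0, 600)), "no signal")
  expect_error(fitHyperbolic(c(5, 1, 0, 2)), ">= 10")
  expect_error(fitHyperbolic(c(rep(3, 5), rep(0, 595))), "positive counts")
})

test_that("fitter matches a coarse-to-fine grid-search minimizer", {
  set.seed(421)
  t <- (seq_len(600) - 0.5) * 0.05
  for (i in 1:5) {
    truth <- c(I0 = runif(1, 800, 3000), Tau = runif(1, 0.1, 0.6),
               Beta = runif(1, 0.7, 1.6))
    y <- rpois(600, dlIntensity(t, truth[1], truth[2], truth[3]))
    f <- fitHyperbolic(y)
    g <- gridSearchRefine(y, t, truth)
    expect_lt(f$objective_value, g$value + 1e-6)
    expect_equal(f$objective_value,
                 oracleDeviance(y, t, f$I0, f$Tau, f$Beta),
                 tolerance = 1e-8)
  }
})

test_that("stored decay time always equals the closed form of the fit", {
  set.seed(7)
  t <- (seq_len(600) - 0.5) * 0.05
  for (i in 1:5) {
    y <- rpois(600, dlIntensity(t, 1500, 0.2, 1.0))
    f <- fitHyperbolic(y)
    expect_identical(f$T, decayTime(f$Beta, f$Tau))
  }
})

test_that("fitted I0 is scale-equivariant, Tau and Beta invariant", {
  t <- (seq_len(600) - 0.5) * 0.05
  y <- round(dlIntensity(t, 800, 0.4, 1.1))
  f1 <- fitHyperbolic(y)
  f2 <- fitHyperbolic(round(dlIntensity(t, 4 * 800, 0.4, 1.1)))
  expect_equal(f2$I0 / f1$I0, 4, tolerance = 0.01)
  expect_equal(f2$Tau, f1$Tau, tolerance = 0.01)
  expect_equal(f2$Beta, f1$Beta, tolerance = 0.01)
})

test_that("parameter recovery under Poisson noise stays within bounds", {
  set.seed(99)
  t <- (seq_len(600) - 0.5) * 0.05
  relerr <- replicate(25, {
    I0 <- runif(1, 500, 5000); Tau <- runif(1, 0.05, 1)
    Beta <- runif(1, 0.5, 2)
    y <- rpois(600, dlIntensity(t, I0, Tau, Beta) + 0.5)
    f <- fitHyperbolic(y, background = 0.5)
    c(abs(f$I0 / I0 - 1), abs(f$Tau / Tau - 1), abs(f$Beta / Beta - 1))
  })
  expect_lt(median(relerr[1, ]), 0.03)  # I0
  expect_lt(median(relerr[2, ]), 0.05)  # Tau
  expect_lt(median(relerr[3, ]), 0.05)  # Beta
})

test_that("replicate averaging is the arithmetic mean per sample", {
  one <- data.frame(sample_id = "S1", I0 = 900, Tau = 0.3, Beta = 1.1,
                    T = decayTime(1.1, 0.3), converged = TRUE)
  expect_equal(averageReplicates(one)$Tau, 0.3)
  expect_equal(averageReplicates(one)$n_replicates, 1L)
  two <- rbind(one, transform(one, Tau = 0.4))
  expect_equal(averageReplicates(two)$Tau, 0.35)
  mixed <- rbind(one, transform(one, sample_id = "S2", Tau = 0.7))
  avg <- averageReplicates(mixed)
  expect_equal(avg$sample_id, c("S1", "S2"))
  expect_equal(avg$Tau, c(0.3, 0.7))
  expect_error(averageReplicates(one[0, ]), "nrow")
  none <- transform(one, converged = FALSE)
  expect_error(averageReplicates(none), "no converged fits")
})

test_that("averaged replicate fits approach the simulated truth", {
  set.seed(11)
  cts <- simulateDecay(1200, 0.3, 1.2, background = 0)
  curves <- DLCurveSet(cts, sampleID = "S1")
  props <- averageReplicates(fitCurves(curves))
  expect_equal(props$I0, 1200, tolerance = 0.05)
  expect_equal(props$Tau, 0.3, tolerance = 0.08)
  expect_equal(props$Beta, 1.2, tolerance = 0.08)
})

test_that("DLCurveSet enforces count and layout invariants", {
  expect_error(DLCurveSet(matrix(-1, 600, 1), sampleID = "S1"),
               "non-negative")
  expect_error(DLCurveSet(matrix(1.5, 600, 1), sampleID = "S1"),
               "integral")
  x <- DLCurveSet(matrix(1, 600, 3), sampleID = c("S1", "S1", "S2"))
  expect_equal(SummarizedExperiment::colData(x)$replicate, c(1L, 2L, 1L))
  expect_equal(nrow(x) * binWidth(x), 30)
  expect_equal(SummarizedExperiment::rowData(x)$time_s[2], 0.05)
})

test_that("CSV readers round-trip both supported layouts", {
  set.seed(2)
  y1 <- rpois(60, 40); y2 <- rpois(60, 30)
  long <- rbind(
    data.frame(sample_id = "S1", replicate = 1L,
               time_s = (0:59) * 0.05, counts = y1),
    data.frame(sample_id = "S1", replicate = 2L,
               time_s = (0:59) * 0.05, counts = y2))
  f <- tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  cs <- readDLCurves(f)
  expect_equal(unname(SummarizedExperiment::assay(cs)[, 1]), y1)
  expect_equal(unname(SummarizedExperiment::assay(cs)[, 2]), y2)
  expect_equal(binWidth(cs), 0.05)

  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(counts = y1), f2, row.names = FALSE)
  cs2 <- readDLCurves(f2, binWidth = 0.05, sampleID = "X")
  expect_equal(unname(SummarizedExperiment::assay(cs2)[, 1]), y1)
  unlink(c(f, f2))
})
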