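# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Poisson deviance of the hyperbolic model on a count vector, direct form.
oracleDeviance <- function(y, t, I0, Tau, Beta, background = 0) {
  mu <- pmax(I0 / (1 + t / Tau)^Beta + background, 1e-12)
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

# Grid search over (I0, Tau, Beta) for the background-0 Poisson deviance.
# For fixed (Tau, Beta) the I0-dependence of the deviance is
#   C - 2 (N log I0 + a) + 2 I0 b,  a = sum(y log s), b = sum(s),
# with s the unit-I0 shape, so each I0 evaluation is O(1).
gridSearchDeviance <- function(y, t, I0grid, TauGrid, BetaGrid) {
  N <- sum(y)
  C <- 2 * sum(ifelse(y > 0, y * log(y), 0)) - 2 * N
  best <- Inf
  bestPar <- c(NA, NA, NA)
  for (Tau in TauGrid) {
    lt <- log1p(t / Tau)
    for (Beta in BetaGrid) {
      logs <- -Beta * lt
      a <- sum(y * logs)
      b <- sum(exp(logs))
      dev <- C - 2 * (N * log(I0grid) + a) + 2 * I0grid * b
      i <- which.min(dev)
      if (dev[i] < best) {
        best <- dev[i]
        bestPar <- c(I0grid[i], Tau, Beta)
      }
    }
  }
  list(value = best, par = bestPar)
}

# Coarse-to-fine refinement of the grid search around the running optimum.
gridSearchRefine <- function(y, t, truth, span = 0.5, n = 20, stages = 4) {
  ctr <- truth
  width <- span
  out <- NULL
  for (s in seq_len(stages)) {
    g <- lapply(ctr, function(v) seq(v * (1 - width), v * (1 + width),
                                     length.out = n))
    out <- gridSearchDeviance(y, t, g[[1]], g[[2]], g[[3]])
    ctr <- out$par
    width <- width * 2.5 / n   # keep the next stage bracketing the best cell
  }
  out
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (probability-mass definition).
fisherEnumerate <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Small deterministic peak table fixture: nSamples x peaks long data.frame.
makePeakTable <- function(areas, rts = NULL, ids = seq_len(ncol(areas))) {
  if (is.null(rts)) {
    rts <- matrix(rep(5 * seq_len(ncol(areas)), each = nrow(areas)),
                  nrow(areas))
  }
  samples <- rownames(areas)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(areas)))
  do.call(rbind, lapply(seq_len(nrow(areas)), function(i) {
    data.frame(sample_id = samples[i], peak_id = ids,
               rt_min = rts[i, ], area = areas[i, ])
  }))
}
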