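#' Names and classes of the quantified compounds
#'
#' The fifteen quantified constituents in three chemical classes: five free
#' anthraquinones, eight glycoside-containing compounds (seven anthraquinone
#' O-glucosides plus sennoside A, the class carrying the cathartic
#' activity), and two polyphenols.
#'
#' @return named character vector mapping compound name to class
#'   ("free_anthraquinone", "glycoside", "polyphenol").
#' @export
compoundClasses <- function() {
  c(aloe_emodin = "free_anthraquinone",
    rhein = "free_anthraquinone",
    emodin = "free_anthraquinone",
    chrysophanol = "free_anthraquinone",
    physcion = "free_anthraquinone",
    aloe_emodin_8_O_glucoside = "glycoside",
    rhein_8_O_glucoside = "glycoside",
    emodin_1_O_glucoside = "glycoside",
    emodin_8_O_glucoside = "glycoside",
    chrysophanol_1_O_glucoside = "glycoside",
    chrysophanol_8_O_glucoside = "glycoside",
    physcion_8_O_glucoside = "glycoside",
    sennoside_A = "glycoside",
    gallic_acid = "polyphenol",
    catechin = "polyphenol")
}

#' Specification of a synthetic rhubarb cohort
#'
#' Default values emulate the 28-sample commercial panel: two sub-groups
#' (A : B roughly 17 : 11) that differ two-fold in the mean content of the
#' glycoside-containing compounds, lognormal concentrations with CV 0.4,
#' DL properties decreasing linearly in log glycoside total, Poisson photon
#' counts around the hyperbolic decay (3 replicates of 600 x 0.05-s bins,
#' 0.5 counts/bin dark background), a 28-common-peak chromatogram template
#' with reference peak 13, and a 7-group mouse bioassay design (control +
#' two samples x three doses, n = 8-9) with endpoint distributions matching
#' the published group summaries. The species factor carries no chemical
#' effect.
#'
#' @param nSamples number of herb batches (default 28).
#' @param groupFractionA proportion assigned to group A (default 17/28).
#' @param glycosideFold group-B/group-A fold change of glycoside means
#'   (default 2).
#' @param compoundCV lognormal coefficient of variation of concentrations
#'   (default 0.4).
#' @param classMeans mean concentrations (mg/g) per class in group A.
#' @param dlLink per-property c(intercept, slope, noise sd) of the linear
#'   link property = intercept - slope * log(glycoside total) + noise.
#' @param nBins,binWidth,nReplicates,background DL acquisition settings.
#' @param referencePeak reference common-peak id (default 13).
#' @param calibrationSlope peak area units per mg/g (default 100).
#' @param peakNoiseSD lognormal sd of peak-area noise (default 0.1).
#' @param rtJitterSD retention-time jitter sd, minutes (default 0.1).
#' @param groupBHeterogeneity half-width (log scale) of the bounded
#'   per-peak batch-heterogeneity distortion applied to group-B
#'   chromatograms (default 1.2). Group B batches of the commercial panel
#'   had markedly divergent profiles (reference similarity indices down to
#'   0.3); a log-uniform per-peak gain in [exp(-h), exp(h)] reproduces that
#'   contrast without the extreme outliers a lognormal tail would inject
#'   into the mean fingerprint.
#' @param species species labels sampled with equal probability, no effect.
#' @param bioassay list of per-group bioassay settings (see defaults).
#' @return a list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(nSamples = 28L,
                       groupFractionA = 17 / 28,
                       glycosideFold = 2,
                       compoundCV = 0.4,
                       classMeans = c(free_anthraquinone = 2,
                                      glycoside = 1,
                                      polyphenol = 1.5),
                       dlLink = list(I0 = c(4000, 900, 100),
                                     Tau = c(0.55, 0.12, 0.012),
                                     Beta = c(1.9, 0.25, 0.035)),
                       nBins = 600L, binWidth = 0.05, nReplicates = 3L,
                       background = 0.5,
                       referencePeak = 13L,
                       calibrationSlope = 100,
                       peakNoiseSD = 0.1,
                       rtJitterSD = 0.1,
                       groupBHeterogeneity = 1.2,
                       species = c("R_palmatum", "R_tanguticum",
                                   "R_officinale"),
                       bioassay = NULL) {
  if (is.null(bioassay)) {
    groups <- c("Control", "S10-Low", "S10-Medium", "S10-High",
                "S22-Low", "S22-Medium", "S22-High")
    bioassay <- list(
      groups = groups,
      dose = c(0, 1, 2.5, 5, 1, 2.5, 5),
      n_defecation = c(8L, 8L, 8L, 9L, 8L, 8L, 9L),
      n_propulsion = c(8L, 8L, 9L, 9L, 8L, 9L, 9L),
      diarrhea_prob = c(0, 0, 1 / 8, 3 / 9, 0, 5 / 8, 8 / 9),
      incubation_mean = c(280.5, 255.4, 148.4, 105.5, 133.7, 129.8, 88.9),
      incubation_sd = c(36.1, 62.4, 65.5, 44.3, 60.7, 40.3, 21.0),
      incubation_cap = 300,
      feces_count_mean = c(0.4, 1.1, 5.3, 8.0, 5.1, 6.9, 6.9),
      feces_weight_mean = c(2.0, 5.8, 25.5, 65.7, 59.0, 86.6, 62.3),
      feces_weight_sd = c(3.7, 8.9, 16.3, 25.0, 30.9, 50.6, 22.3),
      propulsion_mean = c(0.606, 0.756, 0.813, 0.811, 0.792, 0.824, 0.801),
      propulsion_phi = 60,
      intestine_mean = 43.9, intestine_sd = 2.5)
  }
  stopifnot(nSamples >= 2L, groupFractionA >= 0, groupFractionA <= 1,
            compoundCV >= 0, glycosideFold > 0,
            all(classMeans > 0), binWidth > 0, nBins >= 10L)
  spec <- list(nSamples = as.integer(nSamples),
               groupFractionA = groupFractionA,
               glycosideFold = glycosideFold, compoundCV = compoundCV,
               classMeans = classMeans, dlLink = dlLink,
               nBins = as.integer(nBins), binWidth = binWidth,
               nReplicates = as.integer(nReplicates),
               background = background,
               referencePeak = as.integer(referencePeak),
               calibrationSlope = calibrationSlope,
               peakNoiseSD = peakNoiseSD, rtJitterSD = rtJitterSD,
               groupBHeterogeneity = groupBHeterogeneity,
               species = species, bioassay = bioassay)
  class(spec) <- "CohortSpec"
  spec
}

## compound -> common-peak id map; reference peak 13 stays a baseline peak
.peakMap <- function() {
  stats::setNames(
    c(26L, 24L, 27L, 28L, 25L,      # free anthraquinones elute late
      10L, 8L, 11L, 12L, 15L, 16L, 17L, 6L,  # glucosides mid-run
      1L, 3L),                      # polyphenols early
    names(compoundClasses()))
}

## deterministic chromatogram template for the 28 common peaks
.peakTemplate <- function() {
  ids <- 1:28
  rt <- 4 + 3.2 * ids                       # minutes, strictly increasing
  base_area <- 40 + 25 * (ids %% 7)         # baseline (unmapped) peak areas
  base_area[13] <- 160                      # stable, well-separated reference
  list(ids = ids, rt = rt, base_area = base_area)
}

.genCompounds <- function(spec) {
  cls <- compoundClasses()
  nA <- round(spec$nSamples * spec$groupFractionA)
  group <- rep(c("A", "B"), c(nA, spec$nSamples - nA))
  sdlog <- sqrt(log(1 + spec$compoundCV^2))
  X <- matrix(0, spec$nSamples, length(cls),
              dimnames = list(sprintf("S%02d", seq_len(spec$nSamples)),
                              names(cls)))
  for (k in seq_along(cls)) {
    m <- spec$classMeans[[cls[k]]]
    mg <- ifelse(group == "B" & cls[k] == "glycoside",
                 m * spec$glycosideFold, m)
    X[, k] <- stats::rlnorm(spec$nSamples,
                            meanlog = log(mg) - sdlog^2 / 2, sdlog = sdlog)
  }
  species <- sample(spec$species, spec$nSamples, replace = TRUE)
  totals <- vapply(unique(cls), function(cc) {
    rowSums(X[, cls == cc, drop = FALSE])
  }, numeric(spec$nSamples))
  list(concentrations = X, group = group, species = species,
       classTotals = totals)
}

.genDL <- function(spec, compounds) {
  logG <- log(compounds$classTotals[, "glycoside"])
  n <- length(logG)
  truth <- data.frame(sample_id = rownames(compounds$concentrations))
  floors <- c(I0 = 50, Tau = 0.02, Beta = 0.1)
  for (pr in c("I0", "Tau", "Beta")) {
    co <- spec$dlLink[[pr]]
    v <- co[1L] - co[2L] * logG + stats::rnorm(n, 0, co[3L])
    if (any(v <= floors[[pr]])) {
      warning("clipping non-positive ", pr, " truth values")
      v <- pmax(v, floors[[pr]])
    }
    truth[[pr]] <- v
  }
  truth$T <- decayTime(truth$Beta, truth$Tau)
  counts <- do.call(cbind, lapply(seq_len(n), function(i) {
    simulateDecay(truth$I0[i], truth$Tau[i], truth$Beta[i],
                  nBins = spec$nBins, binWidth = spec$binWidth,
                  background = spec$background,
                  nReplicates = spec$nReplicates)
  }))
  curves <- DLCurveSet(counts,
                       sampleID = rep(truth$sample_id,
                                      each = spec$nReplicates),
                       replicate = rep(seq_len(spec$nReplicates), n),
                       binWidth = spec$binWidth)
  list(truth = truth, curves = curves)
}

.genPeaks <- function(spec, compounds) {
  tmpl <- .peakTemplate()
  pmap <- .peakMap()
  X <- compounds$concentrations
  n <- nrow(X)
  rows <- list()
  for (i in seq_len(n)) {
    area <- tmpl$base_area *
      stats::rlnorm(28, -spec$peakNoiseSD^2 / 2, spec$peakNoiseSD)
    area[pmap] <- spec$calibrationSlope * X[i, names(pmap)] *
      stats::rlnorm(length(pmap), -spec$peakNoiseSD^2 / 2, spec$peakNoiseSD)
    if (compounds$group[i] == "B" && spec$groupBHeterogeneity > 0) {
      h <- spec$groupBHeterogeneity
      area <- area * exp(stats::runif(28, -h, h))
    }
    rt <- tmpl$rt + stats::rnorm(28, 0, spec$rtJitterSD)
    rows[[i]] <- data.frame(sample_id = rownames(X)[i], peak_id = tmpl$ids,
                            rt_min = rt, area = area)
  }
  long <- do.call(rbind, rows)
  CommonPeakMatrix(long, referencePeak = spec$referencePeak,
                   peakIDs = tmpl$ids)
}

.rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  v <- stats::rnorm(n, mean, sd)
  while (any(bad <- v <= lower | v > upper)) {
    v[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  v
}

.genBioassay <- function(spec) {
  b <- spec$bioassay
  k <- length(b$groups)
  defecation <- do.call(rbind, lapply(seq_len(k), function(g) {
    n <- b$n_defecation[g]
    loose <- stats::runif(n) < b$diarrhea_prob[g]
    inc <- .rtruncnorm(n, b$incubation_mean[g], b$incubation_sd[g],
                       upper = b$incubation_cap)
    nf <- stats::rpois(n, b$feces_count_mean[g])
    inc[nf == 0] <- NA  # never passed charcoal feces within 5 h -> missing
    wt <- pmax(.rtruncnorm(n, b$feces_weight_mean[g], b$feces_weight_sd[g],
                           lower = -Inf), 0)
    data.frame(mouse_id = sprintf("%s_m%02d", b$groups[g], seq_len(n)),
               group = b$groups[g], dose_g_per_kg = b$dose[g],
               incubation_min = inc, n_feces = nf, feces_mg = wt,
               loose = loose)
  }))
  propulsion <- do.call(rbind, lapply(seq_len(k), function(g) {
    n <- b$n_propulsion[g]
    len <- .rtruncnorm(n, b$intestine_mean, b$intestine_sd, lower = 20)
    mu <- b$propulsion_mean[g]; phi <- b$propulsion_phi
    ratio <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    data.frame(mouse_id = sprintf("%s_m%02d", b$groups[g], seq_len(n)),
               group = b$groups[g], dose_g_per_kg = b$dose[g],
               distance_cm = ratio * len, length_cm = len)
  }))
  rownames(defecation) <- rownames(propulsion) <- NULL
  list(defecation = defecation, propulsion = propulsion)
}

#' Generate a complete synthetic cohort
#'
#' Draws, in a fixed order under one seed, (1) lognormal compound
#' concentrations with the planted group effect on the glycoside class,
#' (2) DL truth parameters linked negatively to log glycoside total plus
#' replicate Poisson decay curves, (3) common-peak chromatogram tables, and
#' (4) per-mouse bioassay records. Identical spec + seed give identical
#' output.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param seed integer seed determining all randomness.
#' @return list of class \code{"SyntheticCohort"}: \code{compounds}
#'   (data.frame with sample_id, group, species and 15 concentration
#'   columns, mg/g), \code{classTotals}, \code{dlTruth}, \code{dlCurves}
#'   (a \code{\link{DLCurveSet}}), \code{peaks} (a
#'   \code{\link{CommonPeakMatrix}}), \code{bioassay}
#'   (defecation + propulsion data.frames), \code{spec}, \code{seed}.
#' @examples
#' coh <- simulateCohort(cohortSpec(nSamples = 6), seed = 7)
#' dim(coh$compounds)
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  withLocalSeed(seed, {
    comp <- .genCompounds(spec)
    dl <- .genDL(spec, comp)
    peaks <- .genPeaks(spec, comp)
    bio <- .genBioassay(spec)
    out <- list(
      compounds = data.frame(sample_id = rownames(comp$concentrations),
                             group = comp$group, species = comp$species,
                             comp$concentrations),
      classTotals = data.frame(sample_id = rownames(comp$concentrations),
                               group = comp$group, comp$classTotals),
      dlTruth = dl$truth, dlCurves = dl$curves, peaks = peaks,
      bioassay = bio, spec = spec, seed = seed)
    class(out) <- "SyntheticCohort"
    out
  })
}

#' @describeIn simulateCohort compound table + class totals only.
#' @export
generateCompounds <- function(spec = cohortSpec(), seed = 1L) {
  withLocalSeed(seed, .genCompounds(spec))
}

#' @describeIn simulateCohort DL truth + simulated curves for a given
#'   compound draw (as returned by \code{generateCompounds}).
#' @param compounds result of \code{generateCompounds}.
#' @export
generateDL <- function(spec, compounds, seed = 1L) {
  withLocalSeed(seed, .genDL(spec, compounds))
}

#' @describeIn simulateCohort common-peak tables for a given compound draw.
#' @export
generatePeaks <- function(spec, compounds, seed = 1L) {
  withLocalSeed(seed, .genPeaks(spec, compounds))
}

#' @describeIn simulateCohort per-mouse bioassay records only.
#' @export
generateBioassay <- function(spec = cohortSpec(), seed = 1L) {
  withLocalSeed(seed, .genBioassay(spec))
}
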