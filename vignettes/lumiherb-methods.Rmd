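---
title: "Delayed luminescence, fingerprint similarity and bioassay statistics: models and design choices"
author: "lumiherb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed luminescence, fingerprint similarity and bioassay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`lumiherb` implements an integrated quality-assessment pipeline for
medicinal herb batches (developed around rhubarb, *Rheum* spp.) that
combines three measurement modalities:

1. **Delayed luminescence (DL)**: long-lived ultraweak photon re-emission
   after white-light excitation, recorded as photon counts in 600
   consecutive 0.05-s bins (30 s), three replicate measurements per batch.
2. **HPLC chromatographic fingerprints**: a panel of 28 common peaks per
   batch, expressed relative to a reference peak, compared through cosine
   similarity indices.
3. **A mouse cathartic bioassay**: defecation and charcoal-meal intestinal
   propulsion endpoints across a control group and two herb samples at
   three doses each.

The package also ships a deterministic synthetic-cohort generator so the
entire pipeline can be exercised and tested without instrument data.

# The DL decay model

The decay phase is modelled by the hyperbolic law

$$ I(t) = \frac{I_0}{\left(1 + t/\tau\right)^{\beta}}, \qquad
   T = \left(e^{1/\beta} - 1\right)\tau , $$

where $I_0$ (counts/bin) is the initial intensity, $\tau$ (s) a
characteristic time scale, $\beta$ (dimensionless) an index of the decay
rate, and $T$ (s) a derived decay-time summary. `dlIntensity()`,
`decayTime()` and `fitHyperbolic()` implement the law, the closed form
and the fit.

## Fitting choices

Counts are integrals over bins, so the model is evaluated at bin midpoints
$t_k = (k + 1/2)\,\Delta t$ — a second-order accurate approximation at the
default $\Delta t = 0.05$ s.

Photon counts are Poisson distributed, so the default objective is the
Poisson deviance
$2\sum_k \left[ y_k \log(y_k/\mu_k) - (y_k - \mu_k) \right]$; a weighted
least-squares objective (weights $1/\max(y_k, 1)$) is available for
comparison. The fitting criterion behind the original analyses of this
kind is generally unstated, which is why both are exposed.

The dark count of a cooled photomultiplier is of the order of 10 counts/s,
i.e. 0.5 counts/bin. The fitter therefore accepts a constant background
term, fixed at 0 by default, fixable at any value, or estimable
(`estimateBackground = TRUE`).

Initialisation takes $I_0$ from the first bin, $\beta$ from the slope of
$\log y$ against $\log(1 + t/\tau_0)$ with $\tau_0 = 10\,\Delta t$, and a
small multistart over $\tau_0 \in \{0.5, 0.1, 0.5, 2\}$ s guards against
poor starts. Refinement uses bounded L-BFGS-B with
$I_0 \in (0, 10\max y]$, $\tau \in (10^{-4}, 30]$,
$\beta \in (0.01, 20]$, terminating at a relative objective change near
$10^{-10}$ or 500 iterations; non-convergence is reported via the
`converged` flag and a warning, and such fits are excluded from replicate
averaging. Tests verify the optimum against an independent coarse-to-fine
grid search, exploiting that for fixed $(\tau, \beta)$ the deviance is
analytic in $I_0$.

## Replicate aggregation

Acquisition protocols of this kind describe both summing the three
replicate measurements and averaging their properties. The package fits
each replicate separately and averages the fitted properties
(`averageReplicates()`), the statistically explicit reading; summing
counts before one fit can be emulated by adding the count matrices. The
identity $T = (e^{1/\beta}-1)\tau$ is applied to each fit by the same code
path, so the stored $T$ is exactly consistent.

# Fingerprint similarity and RSI grouping

Fingerprints are represented as common-peak vectors, not full
chromatogram traces: peak tables are the reproducible, exchangeable
representation, and the similarity index used on them (the included-angle
cosine) is insensitive to the per-sample scale factors that dominate raw
traces. Relative retention times and relative peak areas are ratios to the
reference peak (peak 13 by default — mid-run, well separated); cosine
similarity is identical on raw and relative areas, and the relative form
is used for reporting.

The *standard fingerprint* is the per-peak arithmetic mean of the relative
areas over all samples; each sample's **reference similarity index (RSI)**
is its cosine similarity to that mean. Grouping uses two thresholds: RSI
$\ge 0.885$ assigns group A, RSI $\le 0.84$ group B, and the gap stays
`unassigned` with a warning rather than forcing a label. These defaults
reproduce the published 17 : 11 split of the 28-batch commercial panel
from its printed RSI values; both are configurable. Published pairwise
similarity indices computed by proprietary software on full chromatograms
(e.g. values such as 0.173 between two divergent batches) are only
approximately reproducible from peak vectors, so no exact reproduction of
the pairwise table is claimed.

# Multivariate analysis

* **PCA** (`pcaModel()`) wraps `stats::prcomp` with autoscaling as the
  default preprocessing for mixed-unit blocks; constant features are
  dropped with a warning when scaling.
* **OPLS-DA** (`oplsda()`) is implemented directly (no CRAN/Bioconductor
  implementation is used): features are autoscaled, the 0/1 class variable
  centred, `nOrtho` orthogonal components (default 1) are extracted and
  deflated, then one predictive component is fitted. $R^2$ is the in-fit
  fraction of class variance explained; $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$
  under stratified 7-fold cross-validation, with centring/scaling
  re-estimated inside each training fold and the fold assignment a
  deterministic function of the `seed` argument. The fold scheme behind
  published $Q^2$ values of this kind is typically unspecified, so exact
  reproduction of printed $Q^2/R^2$ is out of scope; the package instead
  verifies the qualitative behaviour (planted separation gives high $Q^2$,
  permuted labels collapse it to $\le 0$ on average).
* **Ward clustering** (`wardCluster()`) uses Euclidean distances with
  `hclust(method = "ward.D2")`: the Lance–Williams update on
  squared-Euclidean merge costs with heights reported on the distance
  scale, so two singletons merge at their Euclidean distance.
* **Correlation network** (`correlationNetwork()`): Spearman's $\rho$
  between every compound (or class total) and each DL property. A *linear
  relationship* is $|\rho| > 0.30$ (strict inequality at the boundary);
  strength classes are weak $(0.30, 0.50)$, moderate $[0.50, 0.70)$ and
  strong $[0.70, 1]$ — the 0.50 and 0.70 boundaries are assigned to the
  upper class, a documented convention since published class definitions
  leave the boundary values ambiguous.

# Bioassay statistics

Diarrhea incidence is $100\,n_\text{loose}/n_\text{total}$ and the
charcoal propelling ratio $100\,d/L$; published tables print one decimal,
and the package keeps full precision internally. One-way ANOVA uses the
classical equal-variance decomposition. Post hoc comparisons follow the
homogeneity-gated convention: a Brown–Forsythe test (median-centred
Levene, `car::leveneTest`) at $\alpha = 0.05$ selects **LSD** (unadjusted
pooled-variance t tests) under homogeneity and **Tamhane's T2**
(Welch-type pairwise statistics with Šidák-adjusted per-comparison levels)
otherwise; the gate, like everything else, is overridable. Diarrhea counts
are tested with an overall Pearson chi-square (no continuity correction)
and pairwise two-sided Fisher exact tests under the probability-mass
definition, which the test suite verifies against exhaustive
hypergeometric enumeration for every $2\times2$ table with $n \le 20$.
Incubation periods of mice that never passed charcoal-containing feces
within the 5-h observation window are treated as missing and excluded
from group means with their count reported.

# The synthetic cohort generator

`cohortSpec()`/`simulateCohort()` generate cohorts with the statistical
structure the analysis assumes. Default values are the study conditions of
the commercial panel; the main ones, with rationale:

* $n = 28$ batches, group fraction A $= 17/28$, matching the published
  split; a wild-panel design is `cohortSpec(nSamples = 118)`.
* Concentrations of the 15 compounds (5 free anthraquinones, 7
  anthraquinone O-glucosides + sennoside A, 2 polyphenols) are lognormal
  with CV 0.4 — strictly positive and right-skewed, as natural-product
  assays are. Group B's glycoside-class means are two-fold higher
  (`glycosideFold = 2`), which gives near-certain detection of the class
  difference at $n = 28$ while keeping single compounds overlapping.
* DL truth follows the planted link
  $\text{property} = a - b \log(\text{glycoside total}) + \varepsilon$,
  clipped positive, with defaults $a, b, \mathrm{sd}(\varepsilon)$ of
  $(4000, 900, 100)$ for $I_0$, $(0.55, 0.12, 0.012)$ for $\tau$ and
  $(1.9, 0.25, 0.035)$ for $\beta$; $T$ is derived from $\tau$ and
  $\beta$. The noise levels are chosen so that *all four* properties —
  including the derived $T$, whose signal partially cancels between
  $\tau$ and $\beta$ — carry a strong negative link
  ($|\rho| \gtrsim 0.5$ after curve fitting), the pattern the pipeline is
  meant to reproduce. Parameter magnitudes ($I_0$ of order $10^3$
  counts/bin, $\tau$ of order $10^{-1}$ s, $\beta$ of order 1) give
  log–log decay shapes resembling real DL curves. Three Poisson replicate
  curves per batch are sampled around the hyperbolic mean plus a 0.5
  counts/bin dark background.
* Chromatograms: compound peaks are calibration slope × concentration
  with lognormal noise (sd 0.1); 13 baseline peaks, including the
  reference peak, come from a fixed template. Group-B batches additionally
  receive a bounded per-peak gain $e^{U(-h,h)}$ with $h = 1.2$
  (`groupBHeterogeneity`): the published group-B batches have strongly
  divergent profiles (RSI down to 0.3), and a uniform fold change on one
  compound class cannot move a cosine index below about 0.94, so batch
  heterogeneity is the realistic mechanism. The bounded form avoids the
  lognormal's heavy tail, which would let single outlier peaks dominate
  the mean fingerprint.
* Bioassay records use the published design (7 groups, $n$ = 8–9) with
  endpoint distributions anchored at the published group summaries:
  Bernoulli loose-stool flags, Poisson charcoal-feces counts, truncated
  normal incubation times and feces weights, and Beta-distributed
  propulsion fractions (so distance never exceeds intestine length).
* The species factor is generated but carries no chemical effect,
  mirroring the finding that species do not separate.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: full chromatogram traces and peak-shape
artefacts; retention-time drift across instruments; inter-compound
correlation beyond the class structure; environmental/altitude covariates
(present in wild material) beyond generic noise; any DL spectral
(wavelength-resolved) structure. One visible consequence: cross-validated
$Q^2$ on the *relative-area* block is unstable under the planted group-B
heterogeneity (heterogeneity is not a reproducible direction), so only the
compound-block OPLS-DA is used for quantitative checks.

# Problem sizes and numerical tolerances

The test suite and the acceptance script use problem sizes chosen as a
balance of statistical resolution and runtime: 100 Poisson curves for
parameter-recovery medians, a $50^3$ grid oracle on 5 curves, 5,000
replicates for type-I-error calibration of the t test and ANOVA, 100
label permutations for the OPLS-DA null, and single cohorts of $n = 28$
and $n = 118$ for the end-to-end workflows. Exact identities (decay-time
closed form, cosine scale invariance, Fisher-vs-enumeration) are asserted
at $10^{-9}$–$10^{-12}$; stochastic checks use the margins stated in the
tests.

# Worked example

```{r}
library(lumiherb)
coh <- simulateCohort(cohortSpec(), seed = 1)
res <- runCommercialWorkflow(coh, seed = 1)
res$similarity
subset(res$network, compound == "glycoside")
```

# Known limitations

* The pairwise similarity indices of the original proprietary software
  are reproduced only in kind (cosine on peak vectors), not value.
* Printed $Q^2/R^2$ values depend on an unknown cross-validation scheme
  and are not reproduced numerically.
* The OPLS-DA implementation supports a single two-level response; VIP
  scores and multi-class models are out of scope.
* The DL model covers only the 30-s decay phase; the excitation phase and
  spectral structure are not modelled.
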