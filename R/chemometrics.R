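#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around \code{\link[stats]{prcomp}} returning a
#' \code{\link{LatentModel}}. Constant features are dropped with a warning
#' when unit-variance scaling is requested.
#'
#' @param X samples x features numeric matrix (or data.frame).
#' @param center,scale preprocessing flags (defaults TRUE/TRUE, the usual
#'   autoscaling for mixed-unit chemometric blocks).
#' @param nComponents number of components to keep (default
#'   \code{min(nrow - 1, ncol)}).
#' @return a \code{\link{LatentModel}} of type "pca".
#' @export
pcaModel <- function(X, center = TRUE, scale = TRUE, nComponents = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two samples")
  if (scale) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant feature(s): ",
              paste(colnames(X)[sds == 0], collapse = ", "))
      X <- X[, sds > 0, drop = FALSE]
    }
  }
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (is.null(nComponents)) nComponents <- kmax
  if (nComponents > kmax) stop("nComponents exceeds min(samples - 1, features)")
  p <- stats::prcomp(X, center = center, scale. = scale)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(nComponents)
  new("LatentModel", type = "pca",
      scores = p$x[, k, drop = FALSE],
      loadings = p$rotation[, k, drop = FALSE],
      explainedVariance = ev[k], R2 = NA_real_, Q2 = NA_real_,
      details = list(center = p$center, scale = p$scale,
                     sdev = p$sdev))
}

## Orthogonal projections to latent structures for a single response:
## on column-preprocessed X and centred y, extract nOrtho y-orthogonal
## components, deflate, and fit one predictive component.
.oplsFit <- function(X, yc, nOrtho) {
  wOrth <- list(); pOrth <- list(); tOrth <- list()
  for (h in seq_len(nOrtho)) {
    w <- crossprod(X, yc)[, 1L] / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    tt <- X %*% w
    p <- crossprod(X, tt)[, 1L] / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to)[, 1L] / sum(to^2)
    X <- X - to %*% t(po)
    wOrth[[h]] <- wo; pOrth[[h]] <- po; tOrth[[h]] <- to[, 1L]
  }
  w <- crossprod(X, yc)[, 1L] / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  tt <- (X %*% w)[, 1L]
  p <- crossprod(X, tt)[, 1L] / sum(tt^2)
  q <- sum(yc * tt) / sum(tt^2)
  list(w = w, p = p, q = q, t = tt, Xres = X,
       wOrth = wOrth, pOrth = pOrth, tOrth = tOrth)
}

## Apply a fitted OPLS filter + predictive weight vector to new
## (already preprocessed) data; returns predictive scores.
.oplsPredictScores <- function(fit, Xnew) {
  for (h in seq_along(fit$wOrth)) {
    to <- Xnew %*% fit$wOrth[[h]]
    Xnew <- Xnew - to %*% t(fit$pOrth[[h]])
  }
  (Xnew %*% fit$w)[, 1L]
}

#' OPLS-DA with cross-validated R2/Q2
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' two-class response. Features are autoscaled (mean-centred, unit
#' variance); the class variable is coded 0/1 and centred. One predictive
#' component plus \code{nOrtho} orthogonal components are fitted. R2 is the
#' in-fit fraction of class-variable variance explained; Q2 = 1 - PRESS/TSS
#' under stratified k-fold cross-validation, with preprocessing re-estimated
#' inside each training fold and the fold assignment reproducible from
#' \code{seed}.
#'
#' @param X samples x features numeric matrix.
#' @param labels two-level factor (or coercible) of class membership.
#' @param nOrtho number of orthogonal components (default 1).
#' @param folds number of CV folds (default 7); reduced with a warning if a
#'   class has fewer members.
#' @param seed integer seed for the fold assignment (default 1).
#' @return a \code{\link{LatentModel}} of type "oplsda": score column 1 is
#'   the predictive component, remaining columns orthogonal.
#' @export
oplsda <- function(X, labels, nOrtho = 1L, folds = 7L, seed = 1L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  if (nrow(X) != length(labels)) stop("X rows and labels must match")
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) stop("all features constant: no signal to model")
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  y <- as.numeric(labels) - 1
  nmin <- min(table(labels))
  if (folds > nmin) {
    warning("reducing folds from ", folds, " to ", nmin,
            " (smallest class size)")
    folds <- nmin
  }
  if (folds < 2L) stop("need at least 2 cross-validation folds")

  ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd)
  Xs <- scale(X, center = ctr, scale = scl)
  yc <- y - mean(y)
  fit <- .oplsFit(Xs, yc, nOrtho)
  yhat <- fit$t * fit$q
  R2 <- 1 - sum((yc - yhat)^2) / sum(yc^2)

  assign_f <- stratifiedFolds(labels, folds, seed)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- assign_f != f; te <- !tr
    ctr_f <- colMeans(X[tr, , drop = FALSE])
    scl_f <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    scl_f[scl_f == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], ctr_f, scl_f)
    Xte <- scale(X[te, , drop = FALSE], ctr_f, scl_f)
    ybar <- mean(y[tr])
    ftr <- .oplsFit(Xtr, y[tr] - ybar, nOrtho)
    yhat_te <- .oplsPredictScores(ftr, Xte) * ftr$q + ybar
    press <- press + sum((y[te] - yhat_te)^2)
  }
  Q2 <- 1 - press / sum((y - mean(y))^2)

  scores <- cbind(pred = fit$t,
                  if (length(fit$tOrth)) do.call(cbind, fit$tOrth))
  loads <- cbind(pred = fit$p,
                 if (length(fit$pOrth)) do.call(cbind, fit$pOrth))
  if (ncol(scores) > 1L) {
    colnames(scores)[-1L] <- colnames(loads)[-1L] <-
      paste0("ortho", seq_len(ncol(scores) - 1L))
  }
  rownames(scores) <- rownames(X)
  totvar <- sum(Xs^2)
  ev <- apply(scores, 2L, function(s) sum(s^2)) / totvar
  new("LatentModel", type = "oplsda", scores = scores, loadings = loads,
      explainedVariance = ev, R2 = R2, Q2 = Q2,
      details = list(weights = fit$w, q = fit$q, center = ctr, scale = scl,
                     folds = folds, foldAssignment = assign_f, seed = seed,
                     labels = labels))
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Euclidean distances and the Ward minimum-
#' variance criterion (\code{hclust} method \code{"ward.D2"}, i.e. the
#' Lance-Williams update on squared-Euclidean merge costs with heights on
#' the distance scale, so two singletons merge at their Euclidean distance).
#'
#' @param X samples x features numeric matrix.
#' @param k number of clusters to cut (default 2).
#' @param scale autoscale features first (default FALSE).
#' @return list with \code{labels} (integer cluster per sample),
#'   \code{heights} (non-decreasing merge heights) and \code{hclust}
#'   (the full tree).
#' @export
wardCluster <- function(X, k = 2L, scale = FALSE) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of samples")
  if (scale) X <- base::scale(X)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  list(labels = stats::cutree(hc, k = k), heights = hc$height, hclust = hc)
}

#' Two-group t test
#'
#' Student variant (default) uses the pooled variance with df = n1 + n2 - 2;
#' Welch uses unequal variances. Degenerate zero-variance inputs are handled
#' explicitly: identical means give t = 0, p = 1; different means with zero
#' variance give p = 0 with a warning.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param variant "student" (default) or "welch".
#' @return list with \code{t}, \code{df}, \code{p} (two-sided).
#' @export
tTestTwoGroup <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    warning("zero variance with different means: p -> 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "student")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked data (ties get mean ranks).
#' Returns \code{NA} with a warning when either vector is constant.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return rho in [-1, 1], or NA when not computable.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation not computable")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Classify a correlation coefficient by strength
#'
#' Linear relationship is defined as |rho| > 0.30; the strength classes are
#' none (|rho| <= 0.30), weak (0.30 < |rho| < 0.50), moderate
#' (0.50 <= |rho| < 0.70) and strong (|rho| >= 0.70). The 0.30 boundary is
#' exclusive (strict ">"); 0.50 and 0.70 belong to the upper class.
#'
#' @param rho numeric vector of correlation coefficients.
#' @return character vector of strength classes.
#' @export
rhoStrength <- function(rho) {
  a <- abs(rho)
  ifelse(a <= 0.30, "none",
         ifelse(a < 0.50, "weak",
                ifelse(a < 0.70, "moderate", "strong")))
}

#' Spearman correlation network between compounds and DL properties
#'
#' One edge per (feature, DL property) pair, with Spearman rho, sign and
#' strength class; pairs with strength >= weak are flagged as linear
#' relationships. Samples are matched by id between the two tables.
#'
#' @param compounds samples x features numeric matrix or data.frame with
#'   sample ids as rownames (or a \code{sample_id} column).
#' @param dlProperties data.frame with \code{sample_id} and the DL property
#'   columns \code{I0}, \code{Tau}, \code{Beta}, \code{T} (as produced by
#'   \code{\link{averageReplicates}}).
#' @param properties DL property columns to correlate (default all four).
#' @return data.frame with columns \code{compound}, \code{dl_property},
#'   \code{rho}, \code{sign}, \code{strength}, \code{linear}.
#' @export
correlationNetwork <- function(compounds, dlProperties,
                               properties = c("I0", "Tau", "Beta", "T")) {
  if (is.data.frame(compounds) && "sample_id" %in% colnames(compounds)) {
    rownames(compounds) <- compounds$sample_id
    compounds$sample_id <- NULL
  }
  X <- as.matrix(compounds)
  ids <- rownames(X)
  if (is.null(ids)) stop("compound table needs sample ids")
  missing <- setdiff(ids, dlProperties$sample_id)
  extra <- setdiff(dlProperties$sample_id, ids)
  if (length(missing) || length(extra)) {
    stop("sample mismatch between tables; missing from DL table: ",
         paste(missing, collapse = ", "), "; missing from compounds: ",
         paste(extra, collapse = ", "))
  }
  dl <- dlProperties[match(ids, dlProperties$sample_id), , drop = FALSE]
  grid <- expand.grid(compound = colnames(X), dl_property = properties,
                      stringsAsFactors = FALSE)
  grid$rho <- mapply(function(cp, pr) spearmanRho(X[, cp], dl[[pr]]),
                     grid$compound, grid$dl_property)
  grid$sign <- ifelse(is.na(grid$rho), NA_character_,
                      ifelse(grid$rho >= 0, "positive", "negative"))
  grid$strength <- ifelse(is.na(grid$rho), NA_character_,
                          rhoStrength(grid$rho))
  grid$linear <- !is.na(grid$strength) & grid$strength != "none"
  grid
}

#' Write a correlation network as an edge-list TSV
#'
#' Tab-separated \code{compound dl_property rho sign strength} table
#' importable into network-visualisation tools.
#'
#' @param edges data.frame from \code{\link{correlationNetwork}}.
#' @param path output file.
#' @param linearOnly keep only edges flagged as linear (default FALSE).
#' @return invisibly, the written data.frame.
#' @export
writeEdgeList <- function(edges, path, linearOnly = FALSE) {
  if (linearOnly) edges <- edges[edges$linear, , drop = FALSE]
  utils::write.table(
    edges[c("compound", "dl_property", "rho", "sign", "strength")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
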