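#' Relative retention times and relative peak areas
#'
#' Divides each sample's peak areas and retention times by its reference-peak
#' values, adding assays \code{"relArea"} and \code{"relRT"}. The entry at
#' the reference peak is exactly 1 in both.
#'
#' @param object a \code{\link{CommonPeakMatrix}}.
#' @return the object with relative assays added.
#' @export
relativeQuantities <- function(object) {
  stopifnot(is(object, "CommonPeakMatrix"))
  a <- assay(object, "area")
  r <- assay(object, "rt")
  ref <- match(referencePeak(object), peakIDs(object))
  refA <- a[ref, ]
  if (any(refA <= 0)) {
    stop("zero reference-peak area in sample(s): ",
         paste(colnames(a)[refA <= 0], collapse = ", "))
  }
  assays(object)$relArea <- sweep(a, 2L, refA, "/")
  assays(object)$relRT <- sweep(r, 2L, r[ref, ], "/")
  object
}

## samples x peaks matrix of relative areas, computing them if absent
.relAreaMatrix <- function(object) {
  if (!"relArea" %in% assayNames(object)) object <- relativeQuantities(object)
  t(assay(object, "relArea"))
}

#' Mean-reference ("standard") fingerprint
#'
#' The per-peak arithmetic mean of the relative peak areas over all samples:
#' the standard fingerprint against which each sample's RSI is computed.
#'
#' @param object a \code{\link{CommonPeakMatrix}} or a samples x peaks
#'   numeric matrix of relative areas.
#' @return named numeric vector, one mean relative area per peak.
#' @export
meanFingerprint <- function(object) {
  v <- if (is(object, "CommonPeakMatrix")) .relAreaMatrix(object)
       else as.matrix(object)
  if (nrow(v) < 1L) stop("need at least one fingerprint vector")
  colMeans(v)
}

#' Similarity of two fingerprint vectors
#'
#' Cosine: sum(u*v) / (||u|| ||v||) — the included-angle cosine index
#' conventional in chromatographic similarity evaluation. Correlation:
#' Pearson correlation of the two vectors.
#'
#' @param u,v numeric vectors over the same peak set.
#' @param method "cosine" (default) or "correlation".
#' @return similarity in [-1, 1].
#' @examples
#' fingerprintSimilarity(c(1, 2, 2), c(2, 1, 2))  # 8/9
#' @export
fingerprintSimilarity <- function(u, v, method = c("cosine", "correlation")) {
  method <- match.arg(method)
  if (length(u) != length(v)) stop("vectors must share one peak set")
  if (method == "cosine") {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) stop("zero-norm fingerprint vector")
    sum(u * v) / (nu * nv)
  } else {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      stop("constant fingerprint vector: correlation undefined")
    }
    stats::cor(u, v)
  }
}

#' Pairwise similarity matrix and reference similarity index
#'
#' Computes all pairwise similarities between sample fingerprints and each
#' sample's RSI — its similarity to the mean-reference fingerprint of the
#' whole panel. Group labels are "unassigned" until
#' \code{\link{classifyByRSI}} is applied.
#'
#' @param object a \code{\link{CommonPeakMatrix}} or samples x peaks matrix
#'   of (relative) areas.
#' @param method "cosine" (default) or "correlation".
#' @return a \code{\link{SimilarityResult}}.
#' @export
similarityMatrix <- function(object, method = c("cosine", "correlation")) {
  method <- match.arg(method)
  v <- if (is(object, "CommonPeakMatrix")) .relAreaMatrix(object)
       else as.matrix(object)
  if (nrow(v) < 2L) stop("need at least two samples")
  ids <- rownames(v)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(v)))
  n <- nrow(v)
  P <- diag(1, n)
  dimnames(P) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- tryCatch(fingerprintSimilarity(v[i, ], v[j, ], method),
                    error = function(e) {
                      stop("similarity failed for samples ", ids[i], "/",
                           ids[j], ": ", conditionMessage(e))
                    })
      P[i, j] <- P[j, i] <- s
    }
  }
  m <- meanFingerprint(v)
  r <- vapply(seq_len(n),
              function(i) fingerprintSimilarity(v[i, ], m, method), 0)
  names(r) <- ids
  g <- stats::setNames(rep("unassigned", n), ids)
  new("SimilarityResult", pairwise = P, rsi = r, groups = g,
      method = method, thresholds = c(high = NA_real_, low = NA_real_))
}

#' Two-group classification by reference similarity index
#'
#' Samples with RSI >= \code{high} are labelled "A", samples with
#' RSI <= \code{low} are labelled "B"; anything in the gap stays
#' "unassigned" with a warning. The default thresholds (0.885 / 0.84)
#' reproduce the published two-group split of the 28-sample commercial
#' panel.
#'
#' @param object a \code{\link{SimilarityResult}} or numeric RSI vector.
#' @param high lower RSI bound for group A (default 0.885).
#' @param low upper RSI bound for group B (default 0.84).
#' @return for a numeric input, a character vector of labels; for a
#'   \code{SimilarityResult}, the object with \code{groups} and
#'   \code{thresholds} filled in.
#' @examples
#' classifyByRSI(c(0.933, 0.478, 0.86))
#' @export
classifyByRSI <- function(object, high = 0.885, low = 0.84) {
  if (low > high) stop("low threshold must be <= high threshold")
  r <- if (is(object, "SimilarityResult")) rsi(object) else
    stats::setNames(as.numeric(object), names(object))
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) {
    stop("RSI values must lie in [-1, 1]")
  }
  labels <- ifelse(r >= high, "A", ifelse(r <= low, "B", "unassigned"))
  names(labels) <- names(r)
  if (any(labels == "unassigned")) {
    warning(sum(labels == "unassigned"),
            " sample(s) fall between the RSI thresholds and stay unassigned")
  }
  if (is(object, "SimilarityResult")) {
    object@groups <- labels
    object@thresholds <- c(high = high, low = low)
    validObject(object)
    object
  } else {
    labels
  }
}
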