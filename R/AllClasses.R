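#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   "assays<-" assayNames colData rowData
NULL

#' Container for delayed-luminescence decay curves
#'
#' A \code{DLCurveSet} holds one or more photon-count decay records on a
#' shared time grid: the \code{"counts"} assay is a bins x curves integer
#' matrix, \code{colData} carries \code{sample_id} and \code{replicate},
#' and \code{rowData$time_s} gives the left edge of each counting bin.
#' The conventional acquisition is 600 bins of 0.05 s (30 s total), three
#' consecutive replicates per sample.
#'
#' @slot binWidth width of one counting bin in seconds.
#' @export
setClass("DLCurveSet",
  contains = "SummarizedExperiment",
  representation(binWidth = "numeric")
)

setValidity("DLCurveSet", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0) {
    msg <- c(msg, "binWidth must be a single positive number")
  }
  if (!"counts" %in% assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0)) {
      msg <- c(msg, "counts must be finite and non-negative")
    } else if (any(abs(cts - round(cts)) > 1e-8)) {
      msg <- c(msg, "counts must be integral (photon counts)")
    }
  }
  cd <- colData(object)
  if (!all(c("sample_id", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'sample_id' and 'replicate'")
  } else if (any(cd$replicate < 1)) {
    msg <- c(msg, "replicate indices must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DLCurveSet
#'
#' @param counts numeric matrix of photon counts, bins in rows and curves
#'   in columns, or a numeric vector for a single curve.
#' @param sampleID character vector, one id per curve (recycled if length 1).
#' @param replicate integer replicate index per curve (default: consecutive
#'   within each sample).
#' @param binWidth bin width in seconds (default 0.05).
#' @return a \code{DLCurveSet}.
#' @examples
#' y <- rpois(600, dlIntensity((seq_len(600) - 0.5) * 0.05, 1000, 0.3, 1.2))
#' DLCurveSet(y, sampleID = "S1")
#' @export
DLCurveSet <- function(counts, sampleID, replicate = NULL, binWidth = 0.05) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- ncol(counts)
  sampleID <- rep_len(as.character(sampleID), n)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n), sampleID, FUN = seq_along)
  }
  replicate <- as.integer(rep_len(replicate, n))
  colnames(counts) <- paste(sampleID, replicate, sep = ".")
  time_s <- (seq_len(nrow(counts)) - 1L) * binWidth
  se <- SummarizedExperiment(
    assays  = list(counts = counts),
    rowData = DataFrame(time_s = time_s),
    colData = DataFrame(sample_id = sampleID, replicate = replicate,
                        row.names = colnames(counts))
  )
  new("DLCurveSet", se, binWidth = binWidth)
}

#' @describeIn DLCurveSet bin width in seconds.
#' @param object a \code{DLCurveSet}.
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @export
setMethod("binWidth", "DLCurveSet", function(object) object@binWidth)

setMethod("show", "DLCurveSet", function(object) {
  cat("DLCurveSet:", ncol(object), "curve(s) x", nrow(object), "bins of",
      object@binWidth, "s (", nrow(object) * object@binWidth, "s total )\n")
  cat("  samples:", paste(unique(colData(object)$sample_id)[
    seq_len(min(6L, length(unique(colData(object)$sample_id))))],
    collapse = ", "),
    if (length(unique(colData(object)$sample_id)) > 6L) "..." else "", "\n")
})

#' Common-peak matrix for chromatographic fingerprints
#'
#' Peaks in rows, samples in columns; assays \code{"area"} and \code{"rt"}
#' (retention time, minutes). After \code{\link{relativeQuantities}} the
#' assays \code{"relArea"} and \code{"relRT"} hold per-sample ratios to the
#' reference peak.
#'
#' @slot referencePeak integer id of the reference peak (default 13).
#' @export
setClass("CommonPeakMatrix",
  contains = "SummarizedExperiment",
  representation(referencePeak = "integer")
)

setValidity("CommonPeakMatrix", function(object) {
  msg <- character()
  if (!all(c("area", "rt") %in% assayNames(object))) {
    msg <- c(msg, "assays 'area' and 'rt' are required")
  } else {
    a <- assay(object, "area"); r <- assay(object, "rt")
    if (anyNA(a) || anyNA(r)) {
      msg <- c(msg, "no missing cells allowed; impute absent peaks as 0 area")
    } else {
      if (any(a < 0)) msg <- c(msg, "peak areas must be >= 0")
      if (any(r <= 0)) msg <- c(msg, "retention times must be > 0")
      ref <- match(object@referencePeak, peakIDs(object))
      if (is.na(ref)) {
        msg <- c(msg, "reference peak id not among peak ids")
      } else if (any(a[ref, ] <= 0)) {
        msg <- c(msg, "reference peak area must be > 0 in every sample")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Build a CommonPeakMatrix from a long peak table
#'
#' @param peaks data.frame with columns \code{sample_id}, \code{peak_id},
#'   \code{rt_min}, \code{area}; one row per observed peak.
#' @param referencePeak integer reference peak id (default 13).
#' @param peakIDs optional full set of common-peak ids; defaults to the ids
#'   present in \code{peaks}. A common peak missing from a sample is imputed
#'   as area 0 (with a warning) at the peak's median retention time.
#' @return a \code{CommonPeakMatrix}.
#' @export
CommonPeakMatrix <- function(peaks, referencePeak = 13L, peakIDs = NULL) {
  stopifnot(all(c("sample_id", "peak_id", "rt_min", "area") %in%
                  colnames(peaks)))
  if (is.null(peakIDs)) peakIDs <- sort(unique(peaks$peak_id))
  peakIDs <- as.integer(peakIDs)
  samples <- unique(as.character(peaks$sample_id))
  area <- matrix(NA_real_, length(peakIDs), length(samples),
                 dimnames = list(paste0("P", peakIDs), samples))
  rt <- area
  i <- cbind(match(peaks$peak_id, peakIDs),
             match(as.character(peaks$sample_id), samples))
  if (anyNA(i)) stop("peak ids outside the declared common-peak set")
  area[i] <- peaks$area
  rt[i] <- peaks$rt_min
  if (anyNA(area)) {
    miss <- which(is.na(area), arr.ind = TRUE)
    warning(sum(is.na(area)), " missing common-peak cell(s) imputed as area 0")
    med_rt <- apply(rt, 1L, stats::median, na.rm = TRUE)
    area[is.na(area)] <- 0
    rt[miss] <- med_rt[miss[, 1L]]
  }
  refrow <- match(referencePeak, peakIDs)
  if (is.na(refrow)) stop("reference peak ", referencePeak, " not in peak set")
  bad <- colnames(area)[area[refrow, ] <= 0]
  if (length(bad)) {
    stop("reference peak ", referencePeak, " has zero area in sample(s): ",
         paste(bad, collapse = ", "))
  }
  se <- SummarizedExperiment(
    assays  = list(area = area, rt = rt),
    rowData = DataFrame(peak_id = peakIDs, row.names = rownames(area))
  )
  new("CommonPeakMatrix", se, referencePeak = as.integer(referencePeak))
}

#' @describeIn CommonPeakMatrix integer peak ids, in row order.
#' @param object a \code{CommonPeakMatrix}.
#' @export
setGeneric("peakIDs", function(object) standardGeneric("peakIDs"))

#' @export
setMethod("peakIDs", "CommonPeakMatrix",
          function(object) rowData(object)$peak_id)

#' @describeIn CommonPeakMatrix id of the reference peak.
#' @export
setGeneric("referencePeak", function(object) standardGeneric("referencePeak"))

#' @export
setMethod("referencePeak", "CommonPeakMatrix",
          function(object) object@referencePeak)

setMethod("show", "CommonPeakMatrix", function(object) {
  cat("CommonPeakMatrix:", nrow(object), "common peaks x", ncol(object),
      "samples; reference peak", object@referencePeak, "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Fingerprint similarity result
#'
#' Pairwise similarity matrix of fingerprint vectors plus each sample's
#' reference similarity index (RSI, similarity to the mean-reference
#' fingerprint) and threshold-based group labels.
#'
#' @slot pairwise symmetric samples x samples similarity matrix in [-1, 1].
#' @slot rsi named per-sample RSI.
#' @slot groups named per-sample label in \{"A", "B", "unassigned"\}.
#' @slot method "cosine" or "correlation".
#' @slot thresholds numeric c(high, low) used for grouping (NA before
#'   \code{\link{classifyByRSI}} is applied).
#' @export
setClass("SimilarityResult",
  representation(pairwise = "matrix", rsi = "numeric", groups = "character",
                 method = "character", thresholds = "numeric")
)

setValidity("SimilarityResult", function(object) {
  msg <- character()
  p <- object@pairwise
  if (nrow(p) != ncol(p)) msg <- c(msg, "pairwise matrix must be square")
  if (max(abs(p - t(p))) > 1e-12) {
    msg <- c(msg, "pairwise matrix must be symmetric within 1e-12")
  }
  if (any(abs(diag(p) - 1) > 1e-12)) {
    msg <- c(msg, "pairwise diagonal must equal 1")
  }
  if (any(p < -1 - 1e-12 | p > 1 + 1e-12)) {
    msg <- c(msg, "similarities must lie in [-1, 1]")
  }
  if (length(object@rsi) != nrow(p)) {
    msg <- c(msg, "one RSI value per sample required")
  }
  if (length(object@groups) != nrow(p)) {
    msg <- c(msg, "one group label per sample required")
  }
  if (!all(object@groups %in% c("A", "B", "unassigned"))) {
    msg <- c(msg, "groups must be 'A', 'B' or 'unassigned'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult (", object@method, "): ", nrow(object@pairwise),
      " samples\n", sep = "")
  cat("  RSI range: [", round(min(object@rsi), 3), ", ",
      round(max(object@rsi), 3), "]\n", sep = "")
  cat("  groups: ", sum(object@groups == "A"), " A, ",
      sum(object@groups == "B"), " B, ",
      sum(object@groups == "unassigned"), " unassigned\n", sep = "")
})

#' @describeIn SimilarityResult per-sample reference similarity index.
#' @param object a \code{SimilarityResult}.
#' @export
setGeneric("rsi", function(object) standardGeneric("rsi"))

#' @export
setMethod("rsi", "SimilarityResult", function(object) object@rsi)

#' @describeIn SimilarityResult pairwise similarity matrix.
#' @export
setGeneric("pairwiseSimilarity",
           function(object) standardGeneric("pairwiseSimilarity"))

#' @export
setMethod("pairwiseSimilarity", "SimilarityResult",
          function(object) object@pairwise)

#' @describeIn SimilarityResult per-sample group labels.
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @export
setMethod("sampleGroups", "SimilarityResult", function(object) object@groups)

#' Latent-variable model (PCA or OPLS-DA)
#'
#' @slot type "pca" or "oplsda".
#' @slot scores samples x components score matrix (for OPLS-DA the first
#'   column is the predictive component, the rest orthogonal).
#' @slot loadings features x components loading matrix.
#' @slot explainedVariance per-component fraction of (preprocessed) variance
#'   explained (PCA) or of X variance captured (OPLS-DA).
#' @slot R2 in-fit explained class variance (OPLS-DA; NA for PCA).
#' @slot Q2 cross-validated predictive accuracy (OPLS-DA; NA for PCA).
#' @slot details list of fit internals (weights, preprocessing, folds, ...).
#' @export
setClass("LatentModel",
  representation(type = "character", scores = "matrix", loadings = "matrix",
                 explainedVariance = "numeric", R2 = "numeric",
                 Q2 = "numeric", details = "list")
)

setValidity("LatentModel", function(object) {
  msg <- character()
  if (!object@type %in% c("pca", "oplsda")) {
    msg <- c(msg, "type must be 'pca' or 'oplsda'")
  }
  if (ncol(object@scores) != ncol(object@loadings)) {
    msg <- c(msg, "scores and loadings must have matching component counts")
  }
  if (object@type == "oplsda" && is.finite(object@R2) &&
      is.finite(object@Q2) && object@Q2 > object@R2 + 1e-8) {
    msg <- c(msg, "Q2 cannot exceed R2 for the same model and data")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "LatentModel", function(object) {
  if (object@type == "pca") {
    cat("LatentModel (PCA): ", nrow(object@scores), " samples, ",
        ncol(object@scores), " components\n", sep = "")
    ev <- round(100 * object@explainedVariance, 1)
    cat("  explained variance (%):", paste(ev, collapse = ", "), "\n")
  } else {
    cat("LatentModel (OPLS-DA): 1 predictive + ",
        ncol(object@scores) - 1L, " orthogonal component(s)\n", sep = "")
    cat("  R2 =", round(object@R2, 3), " Q2 =", round(object@Q2, 3), "\n")
  }
})

#' @describeIn LatentModel score matrix.
#' @param object a \code{LatentModel}.
#' @export
setGeneric("modelScores", function(object) standardGeneric("modelScores"))

#' @export
setMethod("modelScores", "LatentModel", function(object) object@scores)

#' @describeIn LatentModel loading matrix.
#' @export
setGeneric("modelLoadings", function(object) standardGeneric("modelLoadings"))

#' @export
setMethod("modelLoadings", "LatentModel", function(object) object@loadings)

#' @describeIn LatentModel cross-validated Q2 (OPLS-DA).
#' @export
setGeneric("modelQ2", function(object) standardGeneric("modelQ2"))

#' @export
setMethod("modelQ2", "LatentModel", function(object) object@Q2)

#' @describeIn LatentModel in-fit R2 (OPLS-DA).
#' @export
setGeneric("modelR2", function(object) standardGeneric("modelR2"))

#' @export
setMethod("modelR2", "LatentModel", function(object) object@R2)
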