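## numeric matrix of compound concentrations from the cohort-style
## data.frame (sample_id/group/species + concentration columns)
.compoundMatrix <- function(compounds) {
  X <- as.matrix(compounds[, setdiff(colnames(compounds),
                                     c("sample_id", "group", "species")),
                           drop = FALSE])
  rownames(X) <- compounds$sample_id
  X
}

.groupTTests <- function(X, labels, alpha = 0.05) {
  keep <- labels %in% c("A", "B")
  rows <- lapply(colnames(X), function(cn) {
    ht <- tTestTwoGroup(X[keep & labels == "A", cn],
                        X[keep & labels == "B", cn])
    data.frame(feature = cn, mean_A = mean(X[keep & labels == "A", cn]),
               mean_B = mean(X[keep & labels == "B", cn]),
               t = ht$t, df = ht$df, p = ht$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}

#' Commercial-panel workflow
#'
#' Runs the full commercial analysis: fingerprint construction and RSI
#' grouping, per-compound and class-total two-group t tests, DL curve
#' fitting and replicate averaging, OPLS-DA of the compound, relative-area
#' and DL blocks against the RSI grouping, and the compound-DL Spearman
#' correlation network. Operates on a \code{\link{simulateCohort}} result
#' or on equivalently shaped inputs.
#'
#' @param cohort a \code{"SyntheticCohort"}, or NULL if the individual
#'   blocks are supplied.
#' @param peaks a \code{\link{CommonPeakMatrix}}.
#' @param compounds compound concentration data.frame (sample_id + 15
#'   columns; optional group/species columns are ignored for fitting).
#' @param classTotals class-totals data.frame (sample_id + 3 columns).
#' @param dlCurves a \code{\link{DLCurveSet}}.
#' @param outDir optional output directory; when given, stage CSVs, an
#'   edge-list TSV, a JSON summary and a manifest are written.
#' @param seed seed for the OPLS-DA fold assignment (default 1).
#' @param similarityMethod "cosine" or "correlation".
#' @param rsiHigh,rsiLow RSI grouping thresholds (defaults 0.885 / 0.84).
#' @param nOrtho,folds OPLS-DA settings.
#' @param alpha significance level for t tests (default 0.05).
#' @return list with elements \code{similarity} (a
#'   \code{\link{SimilarityResult}}), \code{groups}, \code{compoundTests},
#'   \code{classTests}, \code{dlFits}, \code{dlProperties},
#'   \code{dlTests}, \code{oplsCompounds}, \code{oplsRelArea},
#'   \code{oplsDL}, \code{network}, \code{summary}.
#' @export
runCommercialWorkflow <- function(cohort = NULL, peaks = NULL,
                                  compounds = NULL, classTotals = NULL,
                                  dlCurves = NULL, outDir = NULL,
                                  seed = 1L,
                                  similarityMethod = "cosine",
                                  rsiHigh = 0.885, rsiLow = 0.84,
                                  nOrtho = 1L, folds = 7L, alpha = 0.05) {
  if (!is.null(cohort)) {
    peaks <- cohort$peaks
    compounds <- cohort$compounds
    classTotals <- cohort$classTotals
    dlCurves <- cohort$dlCurves
  }
  if (is.null(peaks) || is.null(compounds) || is.null(dlCurves)) {
    stop("commercial workflow needs peaks, compounds and DL curves")
  }

  ## fingerprint stage
  peaks <- relativeQuantities(peaks)
  sim <- similarityMatrix(peaks, method = similarityMethod)
  sim <- suppressWarnings(classifyByRSI(sim, high = rsiHigh, low = rsiLow))
  groups <- sampleGroups(sim)

  ## chemistry stage
  X <- .compoundMatrix(compounds)
  labels <- groups[rownames(X)]
  if (length(unique(labels[labels != "unassigned"])) < 2L) {
    stop("fingerprint stage produced fewer than two groups")
  }
  compoundTests <- .groupTTests(X, labels, alpha)
  CT <- .compoundMatrix(classTotals)
  classTests <- .groupTTests(CT, labels, alpha)

  ## DL stage
  dlFits <- fitCurves(dlCurves)
  dlProps <- averageReplicates(dlFits)
  DLm <- as.matrix(dlProps[, c("I0", "Tau", "Beta", "T")])
  rownames(DLm) <- dlProps$sample_id
  dlTests <- .groupTTests(DLm, groups[rownames(DLm)], alpha)

  ## discriminant stage (samples with an assigned group only)
  keep <- labels != "unassigned"
  oplsCompounds <- oplsda(X[keep, , drop = FALSE], labels[keep],
                          nOrtho = nOrtho, folds = folds, seed = seed)
  relA <- t(assay(peaks, "relArea"))[rownames(X)[keep], , drop = FALSE]
  oplsRelArea <- oplsda(relA, labels[keep], nOrtho = nOrtho,
                        folds = folds, seed = seed)
  oplsDL <- oplsda(DLm[rownames(X)[keep], , drop = FALSE], labels[keep],
                   nOrtho = nOrtho, folds = folds, seed = seed)

  ## correlation network: compounds + class totals vs DL properties
  feat <- cbind(X, CT[rownames(X), , drop = FALSE])
  network <- correlationNetwork(feat, dlProps)

  summary <- list(
    seed = seed,
    n_samples = nrow(X),
    groups = as.list(table(groups)),
    significant_compounds =
      compoundTests$feature[compoundTests$significant],
    significant_class_totals = classTests$feature[classTests$significant],
    oplsda = list(compounds = list(R2 = modelR2(oplsCompounds),
                                   Q2 = modelQ2(oplsCompounds)),
                  relative_areas = list(R2 = modelR2(oplsRelArea),
                                        Q2 = modelQ2(oplsRelArea)),
                  dl_properties = list(R2 = modelR2(oplsDL),
                                       Q2 = modelQ2(oplsDL))),
    linear_edges = sum(network$linear),
    negative_glycoside_edges = with(
      network, sum(linear & compound == "glycoside" & sign == "negative"))
  )

  result <- list(similarity = sim, groups = groups,
                 compoundTests = compoundTests, classTests = classTests,
                 dlFits = dlFits, dlProperties = dlProps,
                 dlTests = dlTests, oplsCompounds = oplsCompounds,
                 oplsRelArea = oplsRelArea, oplsDL = oplsDL,
                 network = network, summary = summary)
  if (!is.null(outDir)) .writeReport(result, outDir, "commercial", seed)
  result
}

#' Wild-panel workflow
#'
#' PCA of the compound and DL blocks, Ward/Euclidean clustering of the
#' (autoscaled) DL properties into two groups, relabelling so that group 1
#' has the higher DL values, and two-group t tests of the DL properties and
#' chemical class totals.
#'
#' @param cohort a \code{"SyntheticCohort"}, or NULL.
#' @param compounds compound concentration data.frame.
#' @param classTotals class-totals data.frame.
#' @param dlProperties per-sample DL property data.frame (fitted from
#'   \code{cohort$dlCurves} when a cohort is given and this is NULL).
#' @param k number of clusters (default 2).
#' @param alpha significance level (default 0.05).
#' @param outDir optional output directory (CSVs + JSON summary).
#' @param seed recorded in the report manifest (the workflow itself is
#'   deterministic).
#' @return list with \code{pcaCompounds}, \code{pcaDL}, \code{clustering},
#'   \code{clusters} (named 1 = higher DL), \code{dlTests},
#'   \code{classTests}, \code{dlProperties}, \code{summary}.
#' @export
runWildWorkflow <- function(cohort = NULL, compounds = NULL,
                            classTotals = NULL, dlProperties = NULL,
                            k = 2L, alpha = 0.05, outDir = NULL,
                            seed = 1L) {
  if (!is.null(cohort)) {
    compounds <- cohort$compounds
    classTotals <- cohort$classTotals
    if (is.null(dlProperties)) {
      dlProperties <- averageReplicates(fitCurves(cohort$dlCurves))
    }
  }
  if (is.null(compounds) || is.null(dlProperties)) {
    stop("wild workflow needs compounds and DL properties (or curves)")
  }
  X <- .compoundMatrix(compounds)
  DLm <- as.matrix(dlProperties[, c("I0", "Tau", "Beta", "T")])
  rownames(DLm) <- dlProperties$sample_id

  pcaCompounds <- pcaModel(X)
  pcaDL <- suppressWarnings(pcaModel(DLm))

  if (anyDuplicated(DLm)) {
    warning("duplicated DL profiles: clustering partially degenerate ",
            "(tied zero-height merges)")
  }
  sds <- apply(DLm, 2L, stats::sd)
  sc <- scale(DLm, scale = ifelse(sds > 0, sds, 1))
  cl <- wardCluster(sc, k = k, scale = FALSE)
  ## group 1 = cluster with the higher mean autoscaled DL properties
  msc <- tapply(rowMeans(sc), cl$labels, mean)
  ord <- order(msc, decreasing = TRUE)
  relabel <- match(cl$labels, ord)
  clusters <- stats::setNames(relabel, rownames(DLm))

  lab <- ifelse(clusters == 1L, "A", "B")  # 1 = high-DL, reuse A/B machinery
  dlTests <- .groupTTests(DLm, lab, alpha)
  CT <- .compoundMatrix(classTotals)
  classTests <- .groupTTests(CT, lab[rownames(CT)], alpha)

  summary <- list(
    seed = seed, n_samples = nrow(DLm), k = k,
    cluster_sizes = as.list(table(clusters)),
    dl_higher_in_group1 = all(
      dlTests$mean_A > dlTests$mean_B),
    significant_dl_properties = dlTests$feature[dlTests$significant],
    significant_class_totals = classTests$feature[classTests$significant])

  result <- list(pcaCompounds = pcaCompounds, pcaDL = pcaDL,
                 clustering = cl, clusters = clusters, dlTests = dlTests,
                 classTests = classTests, dlProperties = dlProperties,
                 summary = summary)
  if (!is.null(outDir)) .writeReport(result, outDir, "wild", seed)
  result
}

.writeReport <- function(result, outDir, workflow, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wpath <- function(f) file.path(outDir, f)
  if (workflow == "commercial") {
    utils::write.csv(data.frame(sample_id = names(result$groups),
                                rsi = rsi(result$similarity),
                                group = result$groups),
                     wpath("rsi_groups.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pairwiseSimilarity(result$similarity)),
                     wpath("similarity_matrix.csv"))
    utils::write.csv(result$dlFits, wpath("dl_fits.csv"), row.names = FALSE)
    utils::write.csv(result$dlProperties, wpath("dl_properties.csv"),
                     row.names = FALSE)
    utils::write.csv(result$compoundTests, wpath("compound_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(result$classTests, wpath("class_total_tests.csv"),
                     row.names = FALSE)
    writeEdgeList(result$network, wpath("network_edges.tsv"))
  } else {
    utils::write.csv(data.frame(sample_id = names(result$clusters),
                                cluster = result$clusters),
                     wpath("clusters.csv"), row.names = FALSE)
    utils::write.csv(result$dlTests, wpath("dl_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(result$classTests, wpath("class_total_tests.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$summary, wpath("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(workflow = workflow, seed = seed,
                   package = "lumiherb",
                   version = as.character(utils::packageVersion("lumiherb")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}
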