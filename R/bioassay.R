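#' Diarrhea incidence
#'
#' Incidence of diarrhea (%) = number of mice with loose stools / total
#' number of mice x 100. Reported tables round to 1 decimal; the value
#' returned here keeps full precision.
#'
#' @param nLoose number of mice with loose stools (vectorised).
#' @param nTotal total number of mice per group.
#' @return incidence in percent.
#' @examples
#' round(diarrheaRate(8, 9), 1)  # 88.9
#' @export
diarrheaRate <- function(nLoose, nTotal) {
  if (any(nTotal < 1)) stop("nTotal must be >= 1")
  if (any(nLoose < 0) || any(nLoose > nTotal)) {
    stop("nLoose must satisfy 0 <= nLoose <= nTotal")
  }
  100 * nLoose / nTotal
}

#' Charcoal propelling ratio
#'
#' Propelling ratio (%) = distance from pylorus to the charcoal front (cm) /
#' total small-intestine length (cm) x 100.
#'
#' @param distance charcoal travel distance, cm (> 0, vectorised).
#' @param total total small-intestine length, cm.
#' @return ratio in percent.
#' @export
propellingRatio <- function(distance, total) {
  if (any(distance <= 0) || any(total <= 0)) {
    stop("distance and total length must be > 0")
  }
  if (any(distance > total)) stop("distance cannot exceed intestine length")
  100 * distance / total
}

## split values by group label with the shared >= 2-per-group check
.splitGroups <- function(values, groups) {
  g <- split(as.numeric(values), factor(groups, levels = unique(groups)))
  if (length(g) < 2L) stop("need at least two groups")
  if (any(vapply(g, length, 1L) < 2L)) {
    stop("every group needs at least two values")
  }
  g
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition (equal-variance F test).
#'
#' @param values numeric outcome vector, or a list of per-group vectors
#'   (then \code{groups} is ignored).
#' @param groups group labels matching \code{values}.
#' @return list with \code{F}, \code{df_between}, \code{df_within}, \code{p}.
#' @export
anovaOneway <- function(values, groups = NULL) {
  g <- if (is.list(values)) {
    if (length(values) < 2L) stop("need at least two groups")
    if (any(vapply(values, length, 1L) < 2L)) {
      stop("every group needs at least two values")
    }
    values
  } else .splitGroups(values, groups)
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(seq_along(g), vapply(g, length, 1L)))
  ht <- stats::oneway.test(y ~ f, var.equal = TRUE)
  Fv <- unname(ht$statistic)
  if (!is.finite(Fv)) {  # zero within-group variance everywhere
    means <- vapply(g, mean, 0)
    Fv <- if (max(means) - min(means) == 0) 0 else Inf
  }
  list(F = Fv, df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]),
       p = if (Fv == 0) 1 else if (is.infinite(Fv)) 0 else ht$p.value)
}

#' Pairwise post hoc comparisons after one-way ANOVA
#'
#' \code{method = "auto"} applies a homogeneity-of-variance gate: the
#' Brown-Forsythe test (median-centred Levene) at level \code{alpha}
#' selects LSD (least significant difference: unadjusted t tests on the
#' pooled within-group variance) when variances are homogeneous, and
#' Tamhane's T2 (Welch-type pairwise statistics with Sidak-adjusted
#' per-comparison levels) otherwise.
#'
#' @param values numeric outcome vector or list of per-group vectors.
#' @param groups group labels (ignored for list input).
#' @param method "auto" (default), "lsd" or "tamhane_t2".
#' @param alpha significance level for the gate and flags (default 0.05).
#' @return data.frame of pairwise rows: \code{group1}, \code{group2},
#'   \code{mean_diff}, \code{p}, \code{significant}; attributes
#'   \code{method} (the method applied) and \code{levene_p}.
#' @export
postHoc <- function(values, groups = NULL,
                    method = c("auto", "lsd", "tamhane_t2"), alpha = 0.05) {
  method <- match.arg(method)
  g <- if (is.list(values)) values else .splitGroups(values, groups)
  if (is.null(names(g)) || any(names(g) == "")) {
    names(g) <- paste0("G", seq_along(g))
  }
  if (length(g) < 2L || any(vapply(g, length, 1L) < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g), vapply(g, length, 1L)), levels = names(g))
  lev_p <- NA_real_
  if (method == "auto") {
    lev <- car::leveneTest(y ~ f, center = stats::median)
    lev_p <- lev[["Pr(>F)"]][1L]
    method <- if (!is.na(lev_p) && lev_p < alpha) "tamhane_t2" else "lsd"
  }
  k <- length(g)
  ns <- vapply(g, length, 1L)
  means <- vapply(g, mean, 0)
  vars <- vapply(g, stats::var, 0)
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    diff <- means[i] - means[j]
    if (method == "lsd") {
      msw <- sum((ns - 1) * vars) / (sum(ns) - k)
      se <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
      df <- sum(ns) - k
      p <- if (se == 0) as.numeric(diff != 0) * 0 + (diff == 0) else
        2 * stats::pt(-abs(diff / se), df)
    } else {
      se <- sqrt(vars[i] / ns[i] + vars[j] / ns[j])
      df <- se^4 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                      (vars[j] / ns[j])^2 / (ns[j] - 1))
      p_raw <- if (se == 0) as.numeric(diff == 0) else
        2 * stats::pt(-abs(diff / se), df)
      p <- 1 - (1 - min(p_raw, 1))^m  # Sidak over the m comparisons
    }
    data.frame(group1 = names(g)[i], group2 = names(g)[j],
               mean_diff = unname(diff), p = unname(min(p, 1)))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  attr(out, "method") <- method
  attr(out, "levene_p") <- lev_p
  out
}

#' Chi-square and pairwise Fisher exact tests on diarrhea counts
#'
#' Overall Pearson chi-square across the group x \{loose, not loose\} table,
#' then two-sided Fisher exact tests (probability-mass definition: the sum
#' of probabilities of all tables with the observed margins that are no more
#' probable than the observed one) for every group pair.
#'
#' @param counts matrix with one row per group and two columns
#'   (loose, not loose); rownames label the groups.
#' @return list with \code{chisq_p}, \code{chisq_stat} and \code{pairwise}
#'   (data.frame \code{group1}, \code{group2}, \code{p}).
#' @export
diarrheaTests <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("counts must have two columns")
  if (nrow(counts) < 2L) stop("need at least two groups")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(rowSums(counts) == 0)) stop("empty group in counts table")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  }
  chi <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  pairs <- utils::combn(nrow(counts), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    tab <- counts[c(i, j), , drop = FALSE]
    p <- stats::fisher.test(tab)$p.value
    data.frame(group1 = rownames(counts)[i], group2 = rownames(counts)[j],
               p = p)
  })
  list(chisq_stat = unname(chi$statistic), chisq_p = chi$p.value,
       pairwise = do.call(rbind, pw))
}

#' Group summaries of per-mouse bioassay endpoints
#'
#' Mean and SD of each numeric endpoint by treatment group; incubation
#' periods recorded as NA (mice that never passed charcoal feces) are
#' excluded from the means with their count reported.
#'
#' @param records per-mouse data.frame with a \code{group} column and
#'   numeric endpoint columns.
#' @param endpoints endpoint column names (default: all numeric columns
#'   except \code{dose_g_per_kg}).
#' @return data.frame with one row per group x endpoint: \code{group},
#'   \code{endpoint}, \code{n}, \code{n_missing}, \code{mean}, \code{sd}.
#' @export
bioassaySummary <- function(records, endpoints = NULL) {
  stopifnot("group" %in% colnames(records))
  if (is.null(endpoints)) {
    num <- vapply(records, is.numeric, TRUE)
    endpoints <- setdiff(colnames(records)[num],
                         c("dose_g_per_kg", "mouse_id"))
  }
  grp <- factor(records$group, levels = unique(records$group))
  rows <- lapply(endpoints, function(ep) {
    v <- split(records[[ep]], grp)
    data.frame(group = names(v), endpoint = ep,
               n = vapply(v, function(x) sum(!is.na(x)), 1L),
               n_missing = vapply(v, function(x) sum(is.na(x)), 1L),
               mean = vapply(v, function(x) mean(x, na.rm = TRUE), 0),
               sd = vapply(v, function(x) stats::sd(x, na.rm = TRUE), 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
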