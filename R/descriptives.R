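# Taylor-linearized variance of a proportion under single-stage cluster
# sampling (families as clusters): with cluster totals t_g, sizes n_g and
# overall p = sum(t)/sum(n), var = m/(m-1) * sum((t_g - p n_g)^2) / n^2.
cluster_var_prop <- function(z, cluster) {
  n <- length(z)
  t_g <- tapply(z, cluster, sum)
  n_g <- tapply(z, cluster, length)
  m <- length(t_g)
  if (m < 2) return(NA_real_)
  p <- sum(z) / n
  u <- t_g - p * n_g
  m / (m - 1) * sum(u^2) / n^2
}

#' Prevalence with cluster-robust confidence intervals
#'
#' Per-group proportion of a 0/1 trait, on the percent scale, with a Wald 95%
#' interval built from a Taylor-linearized standard error that treats the
#' family as the sampling cluster. Missing trait values are excluded from the
#' denominator, so intent (coded `NA` for ever-sippers) is automatically
#' computed over never-users only.
#'
#' @param cohort Cohort data.frame containing the trait, a `family_id` column
#'   and (if `by` is given) the grouping column.
#' @param trait Name of a 0/1 trait column.
#' @param by Optional name of a categorical grouping column.
#' @return A data.frame with `group`, `n`, `prevalence`, `ci_lower`,
#'   `ci_upper` (percent, clipped to [0, 100]) and `se` (percent).
#' @export
prevalence <- function(cohort, trait, by = NULL) {
  y <- cohort[[trait]]
  if (is.null(y)) stop("trait column not found: ", trait)
  g <- if (is.null(by)) rep("All", nrow(cohort)) else as.character(cohort[[by]])
  levels <- unique(g[!is.na(g)])
  rows <- lapply(levels, function(lv) {
    sel <- !is.na(g) & g == lv & !is.na(y)
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(group = lv, n = 0L, prevalence = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        se = NA_real_, stringsAsFactors = FALSE))
    }
    p <- mean(y[sel])
    v <- cluster_var_prop(y[sel], cohort$family_id[sel])
    se <- sqrt(v)
    data.frame(group = lv, n = n, prevalence = 100 * p,
               ci_lower = max(0, 100 * (p - 1.96 * se)),
               ci_upper = min(100, 100 * (p + 1.96 * se)),
               se = 100 * se, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' First-order Rao-Scott chi-square test for clustered categorical data
#'
#' Computes the Pearson chi-square on the individual-level contingency table
#' and divides it by the first-order Rao-Scott correction: the mean
#' generalized design effect of the cell proportions, estimated by the trace
#' formula `[sum_rc d_rc (1 - p_rc) - sum_r d_r (1 - p_r) - sum_c d_c (1 -
#' p_c)] / ((R-1)(C-1))` with cell and margin design effects `d` taken as the
#' ratio of the family-clustered Taylor-linearized variance to the same
#' linearized variance computed with every individual as its own cluster.
#' With singleton clusters the correction is exactly 1. The adjusted statistic
#' is referred to a chi-square with (R-1)(C-1) degrees of freedom.
#'
#' @param cohort Cohort data.frame.
#' @param trait Name of the (categorical or 0/1) outcome column.
#' @param group Name of the grouping column.
#' @param cluster Name of the clustering column (default `"family_id"`).
#' @return A `rao_scott` object: Pearson statistic, mean design effect,
#'   adjusted statistic, df, p-value.
#' @export
rao_scott_test <- function(cohort, trait, group, cluster = "family_id") {
  y <- cohort[[trait]]; g <- cohort[[group]]; cl <- cohort[[cluster]]
  keep <- !is.na(y) & !is.na(g)
  y <- factor(y[keep]); g <- factor(g[keep]); cl <- cl[keep]
  if (nlevels(y) < 2 || nlevels(g) < 2) {
    stop("degenerate table: empty margin for ",
         if (nlevels(y) < 2) trait else group)
  }
  tab <- table(g, y)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    empty <- c(rownames(tab)[rowSums(tab) == 0], colnames(tab)[colSums(tab) == 0])
    stop("degenerate table: empty margin for ", paste(empty, collapse = ", "))
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  pearson <- sum((tab - expected)^2 / expected)
  unit <- seq_along(y)
  deff <- function(z) {
    p <- mean(z)
    if (p <= 0 || p >= 1) return(c(d = 1, w = 0))
    c(d = cluster_var_prop(z, cl) / cluster_var_prop(z, unit), w = 1 - p)
  }
  num <- 0
  for (r in levels(g)) for (c in levels(y)) {
    dw <- deff(as.numeric(g == r & y == c))
    num <- num + dw["d"] * dw["w"]
  }
  for (r in levels(g)) {
    dw <- deff(as.numeric(g == r)); num <- num - dw["d"] * dw["w"]
  }
  for (c in levels(y)) {
    dw <- deff(as.numeric(y == c)); num <- num - dw["d"] * dw["w"]
  }
  df <- (nlevels(g) - 1) * (nlevels(y) - 1)
  dbar <- unname(num) / df
  if (!is.finite(dbar) || dbar <= 0) dbar <- 1
  adjusted <- pearson / dbar
  structure(list(pearson = pearson, design_effect = dbar,
                 statistic = adjusted, df = df,
                 p.value = stats::pchisq(adjusted, df, lower.tail = FALSE),
                 table = tab),
            class = "rao_scott")
}

#' @export
print.rao_scott <- function(x, ...) {
  cat("Rao-Scott chi-square (first-order correction)\n")
  cat(sprintf("  Pearson X^2 = %.4f, mean design effect = %.4f\n",
              x$pearson, x$design_effect))
  cat(sprintf("  adjusted X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param items Numeric matrix or data.frame, one column per item, one row per
#'   respondent; rows with any missing item are dropped.
#' @return The reliability coefficient, or `NA` when the total-score variance
#'   is zero.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2 || nrow(items) < 2) stop("need >= 2 items and >= 2 respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}
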