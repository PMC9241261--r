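#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch–Satterthwaite degrees of freedom,
#' the test used for all group comparisons of FP counts, FPRs and
#' deamination scores. Thin wrapper around [stats::t.test] with explicit
#' handling of the degenerate constant-data cases.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param alternative `"two_sided"`, `"greater"` (mean of `x` exceeds mean
#'   of `y`) or `"less"`.
#' @return List with `statistic` (t), `df` and `p_value`.
#' @export
welch_t <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both groups constant with equal means; p = 1")
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    warning("both groups constant with different means; p = 0")
    s <- sign(mean(x) - mean(y))
    p <- switch(alternative, two_sided = 0,
                greater = if (s > 0) 0 else 1,
                less = if (s < 0) 0 else 1)
    return(list(statistic = s * Inf, df = NA_real_, p_value = p))
  }
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  tt <- stats::t.test(x, y, alternative = alt, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Pearson's chi-squared test with Yates' continuity correction
#'
#' For 2x2 tables of pass/fail counts between sample groups. The corrected
#' statistic subtracts 0.5 from each `|O - E|` (floored at zero) before
#' squaring; p-value from the chi-squared distribution with 1 df. Wrapper
#' around [stats::chisq.test].
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic` (chi-squared) and `p_value`.
#' @export
yates_chi2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("table must be 2x2")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Run a plan of group comparisons
#'
#' Takes a per-sample metric table (one row per sample with a `group`
#' column, e.g. built from [fp_report_table] joined to classified
#' metadata) and a comparison plan, and runs one Welch's t-test per plan
#' row. One-tailed directions are explicit in the plan; `"greater"` means
#' the mean of `group_a` exceeds that of `group_b`. No multiple-testing
#' adjustment is applied to `p_value` (raw p-values are reported); a
#' Bonferroni column over the plan's rows is appended for transparency.
#'
#' @param metrics data frame with columns `group` and every metric named in
#'   the plan (e.g. `fp_count`, `fpr_per_million`, `n_gc_to_at`,
#'   `normalized_deamination`).
#' @param plan data frame with columns `metric`, `group_a`, `group_b`,
#'   `alternative`.
#' @return Data frame with one row per comparison: metric, groups, group
#'   sizes and means, t statistic, df, p_value, alternative,
#'   p_bonferroni.
#' @export
compare_groups <- function(metrics, plan) {
  stopifnot(is.data.frame(metrics), is.data.frame(plan))
  if (!"group" %in% names(metrics)) stop("metrics must have a 'group' column")
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    metric <- as.character(plan$metric[i])
    ga <- as.character(plan$group_a[i])
    gb <- as.character(plan$group_b[i])
    alt <- as.character(plan$alternative[i])
    if (!metric %in% names(metrics)) stop("unknown metric: ", metric)
    for (g in c(ga, gb)) {
      if (!g %in% metrics$group) stop("unknown group label: ", g)
    }
    x <- metrics[[metric]][metrics$group == ga]
    y <- metrics[[metric]][metrics$group == gb]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    res <- welch_t(x, y, alternative = alt)
    data.frame(metric = metric, group_a = ga, group_b = gb,
               n_a = length(x), n_b = length(y),
               mean_a = mean(x), mean_b = mean(y),
               statistic = res$statistic, df = res$df,
               p_value = res$p_value, alternative = alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}

#' Append a normalized-deamination column to a metric table
#'
#' Normalizes each sample's G:C>A:T count by the mean count of the baseline
#' group; when the baseline group's mean is zero the fallback group is
#' used (see [normalized_deamination]).
#'
#' @param metrics per-sample metric table with `group` and `n_gc_to_at`.
#' @param baseline_group primary baseline group label.
#' @param fallback_group optional fallback group label.
#' @return `metrics` with a `normalized_deamination` column.
#' @export
add_normalized_deamination <- function(metrics, baseline_group = "PASS_INNER",
                                       fallback_group = NULL) {
  base <- metrics$n_gc_to_at[metrics$group == baseline_group]
  fb <- if (!is.null(fallback_group)) {
    metrics$n_gc_to_at[metrics$group == fallback_group]
  }
  metrics$normalized_deamination <-
    normalized_deamination(metrics$n_gc_to_at, base, fb)
  metrics
}
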