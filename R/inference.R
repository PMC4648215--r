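sem <- function(x) stats::sd(x) / sqrt(length(x))

comparison_row <- function(metric, test, groups, values, statistic, df1, df2,
                           p_value, degenerate = FALSE, alpha = 0.05) {
  tibble(
    metric = metric, test = test,
    comparison = paste(groups, collapse = " vs "),
    groups = list(groups),
    means = list(purrr::map_dbl(values, mean)),
    sems = list(purrr::map_dbl(values, sem)),
    statistic = statistic, df1 = df1, df2 = df2,
    p_value = p_value,
    significant = p_value < alpha,
    degenerate = degenerate
  )
}

#' Unpaired two-sample Student's t-test
#'
#' Pooled-variance (classical Student) two-tailed t-test by default, the
#' textbook "unpaired Student's t-test"; Welch's unequal-variance variant
#' is available via `welch = TRUE`. Group means and standard errors of
#' the mean (SEM) are reported alongside the test. When both groups are
#' constant and equal the comparison is degenerate: the convention is
#' `t = 0`, `p = 1` with `degenerate = TRUE`, so simulated edge cases do
#' not abort pipelines; constant groups with different means give
#' `p = 0` (infinite t).
#'
#' @param x,y Numeric vectors, each with at least 2 observations.
#' @param labels Length-2 character vector naming the two groups.
#' @param metric Name of the quantity being compared (bookkeeping).
#' @param welch Use Welch's unequal-variance t-test.
#' @param alpha Significance threshold (default 0.05).
#' @return A one-row tibble: `metric`, `test`, `comparison`, list-columns
#'   `groups`/`means`/`sems`, `statistic` (t), `df1` (`NA`), `df2`
#'   (degrees of freedom), `p_value`, `significant`, `degenerate`.
#' @export
#' @examples
#' t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
t_test_unpaired <- function(x, y, labels = c("x", "y"), metric = "value",
                            welch = FALSE, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- mean(x) == mean(y)
    return(comparison_row(
      metric, "t_test", labels, list(x, y),
      statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df1 = NA_real_, df2 = length(x) + length(y) - 2,
      p_value = if (same) 1 else 0, degenerate = TRUE, alpha = alpha
    ))
  }
  fit <- stats::t.test(x, y, var.equal = !welch)
  comparison_row(
    metric, "t_test", labels, list(x, y),
    statistic = unname(fit$statistic),
    df1 = NA_real_, df2 = unname(fit$parameter),
    p_value = fit$p.value, alpha = alpha
  )
}

#' One-way ANOVA across groups
#'
#' Standard one-way fixed-effects F test (equal-variance), with `p` from
#' the F distribution on `(k - 1, n - k)` degrees of freedom. When every
#' observation is identical (zero between- and within-group variance) F
#' is undefined; the convention is `p = 1` with `degenerate = TRUE`. With
#' two groups `F = t^2` and the p-value equals the pooled-variance
#' t-test's.
#'
#' @param groups A named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations).
#' @inheritParams t_test_unpaired
#' @return A one-row tibble in the same schema as [t_test_unpaired()],
#'   with `statistic` = F and `df1`/`df2` the numerator/denominator
#'   degrees of freedom.
#' @export
anova_one_way <- function(groups, metric = "value", alpha = 0.05) {
  if (length(groups) < 2L) abort("ANOVA needs at least 2 groups")
  if (any(lengths(groups) < 2L)) {
    abort("every ANOVA group needs at least 2 observations")
  }
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  labels[labels == ""] <- paste0("g", seq_along(groups))[labels == ""]
  values <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  n <- length(values)
  if (stats::var(values) == 0) {
    return(comparison_row(
      metric, "anova", labels, groups,
      statistic = NA_real_, df1 = k - 1, df2 = n - k,
      p_value = 1, degenerate = TRUE, alpha = alpha
    ))
  }
  g <- factor(base::rep(labels, lengths(groups)), levels = labels)
  within_var <- purrr::map_dbl(groups, stats::var)
  if (all(within_var == 0)) {
    # separated constant groups: F diverges
    return(comparison_row(
      metric, "anova", labels, groups,
      statistic = Inf, df1 = k - 1, df2 = n - k,
      p_value = 0, degenerate = TRUE, alpha = alpha
    ))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  comparison_row(
    metric, "anova", labels, groups,
    statistic = unname(fit$statistic),
    df1 = unname(fit$parameter[["num df"]]),
    df2 = unname(fit$parameter[["denom df"]]),
    p_value = fit$p.value, alpha = alpha
  )
}

#' Group comparisons for a cohort metric
#'
#' Applies the study's testing scheme to a cohort-level table:
#' * `unique_count`, `clonality` — the three pairwise unpaired t-tests
#'   between tissue groups on the per-sample diversity table
#'   ([cohort_diversity()]);
#' * `overlap_score` — one one-way ANOVA across the pooled comparison
#'   groups of a [pool_overlaps()] table, followed by all pairwise
#'   t-tests between comparison groups. Records flagged `excluded`
#'   (within-patient NL-LS pairs) never enter.
#'
#' P-values are reported raw, with no multiple-testing correction; the
#' number of tests performed is visible as the number of returned rows.
#'
#' @param data A [cohort_diversity()] table (for `unique_count` /
#'   `clonality`) or a [pool_overlaps()] table (for `overlap_score`).
#' @param metric `"unique_count"`, `"clonality"` or `"overlap_score"`.
#' @inheritParams t_test_unpaired
#' @return A tibble of comparison rows ([t_test_unpaired()] /
#'   [anova_one_way()] schema).
#' @export
compare_metric_across_groups <- function(data,
                                         metric = c(
                                           "unique_count", "clonality",
                                           "overlap_score"
                                         ),
                                         welch = FALSE, alpha = 0.05) {
  metric <- match.arg(metric)
  if (metric %in% c("unique_count", "clonality")) {
    col <- if (metric == "unique_count") "n_unique" else "clonality"
    if (!all(c("group", col) %in% names(data))) {
      abort(sprintf("expected a diversity table with columns group and %s", col))
    }
    groups <- split(data[[col]], factor(data$group, levels = TISSUE_GROUPS))
    present <- TISSUE_GROUPS[lengths(groups)[TISSUE_GROUPS] >= 2L]
    if (length(present) < 2L) abort("need at least two tissue groups")
    pairs <- utils::combn(present, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      t_test_unpaired(groups[[a]], groups[[b]],
        labels = c(a, b), metric = metric, welch = welch, alpha = alpha
      )
    })
  } else {
    if (!all(c("comparison_group", "score", "excluded") %in% names(data))) {
      abort("expected a pooled overlap table (comparison_group, score, excluded)")
    }
    data <- filter(data, !.data$excluded)
    lev <- c("NN", "N-NL", "N-LS", "NL-NL", "NL-LS", "LS-LS")
    groups <- split(
      data$score, factor(data$comparison_group, levels = lev)
    )
    present <- lev[lengths(groups)[lev] >= 2L]
    groups <- groups[present]
    out <- anova_one_way(groups, metric = metric, alpha = alpha)
    if (length(present) >= 2L) {
      pairs <- utils::combn(present, 2L)
      out <- bind_rows(out, purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
        a <- pairs[1, k]
        b <- pairs[2, k]
        t_test_unpaired(groups[[a]], groups[[b]],
          labels = c(a, b), metric = metric, welch = welch, alpha = alpha
        )
      }))
    }
    out
  }
}
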