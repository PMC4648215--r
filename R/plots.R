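group_palette <- c(
  normal = "#4477aa", non_lesional = "#ccbb44", lesional = "#ee6677"
)

#' Plot a diversity metric by tissue group
#'
#' Per-sample points with group mean and SEM error bars, the standard
#' unique-count / clonality group display.
#'
#' @param diversity A [cohort_diversity()] table.
#' @param metric Column to plot, `"n_unique"` or `"clonality"`.
#' @return A ggplot.
#' @export
plot_group_metric <- function(diversity, metric = c("n_unique", "clonality")) {
  metric <- match.arg(metric)
  df <- mutate(diversity, group = factor(.data$group, levels = TISSUE_GROUPS))
  stats_df <- df |>
    group_by(.data$group) |>
    summarise(
      m = mean(.data[[metric]]), s = sem(.data[[metric]]), .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_jitter(
      ggplot2::aes(colour = .data$group),
      width = 0.12, height = 0, size = 2, show.legend = FALSE
    ) +
    ggplot2::geom_errorbar(
      data = stats_df,
      ggplot2::aes(
        x = .data$group, y = .data$m,
        ymin = .data$m - .data$s, ymax = .data$m + .data$s
      ),
      width = 0.25, inherit.aes = FALSE
    ) +
    ggplot2::geom_point(
      data = stats_df,
      ggplot2::aes(x = .data$group, y = .data$m),
      shape = 95, size = 8, inherit.aes = FALSE
    ) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(
      x = NULL,
      y = if (metric == "n_unique") "unique CDR3 sequences" else "clonality"
    ) +
    ggplot2::theme_classic()
}

#' Paired non-lesional vs lesional clone scatter
#'
#' Each point is one clonotype; axes are its percent of total templates
#' in lesional (x) and non-lesional (y) skin on log scales, coloured by
#' whether it is unique to one tissue or shared. Clones absent from a
#' tissue sit on the corresponding axis at a small pseudo-frequency.
#'
#' @param object A [paired_comparison()] result.
#' @param pseudo Pseudo-frequency (percent) for absent clones.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_paired <- function(object, pseudo = NULL, ...) {
  df <- as_tibble(object)
  pos <- c(df$freq_nl[df$freq_nl > 0], df$freq_ls[df$freq_ls > 0])
  pseudo <- pseudo %||% (min(pos) / 3)
  df <- mutate(df,
    x = pmax(.data$freq_ls, pseudo),
    y = pmax(.data$freq_nl, pseudo),
    status = factor(.data$status, levels = c("nl_only", "shared", "ls_only"))
  )
  counts <- table(df$status)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(nl_only = "#d62728", shared = "#1f77b4", ls_only = "#2ca02c"),
      labels = sprintf(
        "%s (n=%d)", c("non-lesional only", "shared", "lesional only"),
        as.integer(counts)
      )
    ) +
    ggplot2::labs(
      x = "% of templates, lesional", y = "% of templates, non-lesional",
      colour = NULL,
      title = sprintf("Patient %s", attr(object, "patient_id"))
    ) +
    ggplot2::theme_classic()
}

#' Plot pooled overlap scores by comparison group
#'
#' Jittered pairwise overlap scores with group mean and SEM bars;
#' excluded within-patient NL-LS records are dropped.
#'
#' @param overlaps A [pool_overlaps()] table.
#' @return A ggplot.
#' @export
plot_overlap_groups <- function(overlaps) {
  lev <- c("NN", "N-NL", "N-LS", "NL-NL", "NL-LS", "LS-LS")
  df <- overlaps |>
    filter(!.data$excluded) |>
    mutate(comparison_group = factor(.data$comparison_group, levels = lev))
  stats_df <- df |>
    group_by(.data$comparison_group) |>
    summarise(m = mean(.data$score), s = sem(.data$score), .groups = "drop")
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$comparison_group, y = .data$score)
  ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 1.5) +
    ggplot2::geom_errorbar(
      data = stats_df,
      ggplot2::aes(
        x = .data$comparison_group, y = .data$m,
        ymin = .data$m - .data$s, ymax = .data$m + .data$s
      ),
      width = 0.3, colour = "red", inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "comparison group", y = "overlap score") +
    ggplot2::theme_classic()
}

#' V/J usage heat-style dot plot across samples
#'
#' @param usage A [cohort_vj_usage()] table (one segment class).
#' @return A ggplot.
#' @export
plot_vj_usage <- function(usage) {
  ggplot2::ggplot(
    usage,
    ggplot2::aes(x = .data$gene, y = .data$usage, colour = .data$group)
  ) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(x = NULL, y = "usage fraction", colour = NULL) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
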