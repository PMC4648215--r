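#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline report's test results
#'
#' One row per statistical test performed (pairwise t-tests on unique
#' counts and clonality, overlap-score ANOVA and pairwise tests), with
#' list columns flattened.
#'
#' @param x A `tcr_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tcr_report <- function(x, ...) {
  flatten_tests(bind_rows(x$diversity_tests, x$overlap_tests))
}

#' One-line summary of a pipeline report
#'
#' @param x A `tcr_report`.
#' @param ... Unused.
#' @return A one-row tibble: sample count, chain, mean unique counts per
#'   group, number of significant tests, public-clone counts.
#' @export
glance.tcr_report <- function(x, ...) {
  by_group <- x$diversity |>
    group_by(.data$group) |>
    summarise(m = mean(.data$n_unique), .groups = "drop")
  m <- setNames(by_group$m, by_group$group)
  tibble(
    n_samples = x$provenance$n_samples,
    chain = x$provenance$chain,
    mean_unique_normal = m[["normal"]],
    mean_unique_non_lesional = m[["non_lesional"]],
    mean_unique_lesional = m[["lesional"]],
    n_significant_tests = sum(
      c(x$diversity_tests$significant, x$overlap_tests$significant)
    ),
    n_public_lesional = dplyr::n_distinct(x$public_lesional$key),
    n_public_psoriatic = dplyr::n_distinct(x$public_psoriatic$key)
  )
}

#' Per-set counts of a paired tissue comparison
#'
#' The numbers conventionally printed under a paired non-lesional vs
#' lesional scatter: clones unique to each tissue and shared, plus the
#' Spearman rank correlation of shared-clone frequencies.
#'
#' @param x A [paired_comparison()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.tcr_paired <- function(x, ...) {
  shared <- filter(as_tibble(x), .data$status == "shared")
  rho <- if (nrow(shared) >= 3L) {
    stats::cor(shared$freq_nl, shared$freq_ls, method = "spearman")
  } else {
    NA_real_
  }
  tibble(
    patient_id = attr(x, "patient_id"),
    chain = attr(x, "chain"),
    n_nl_only = sum(x$status == "nl_only"),
    n_shared = nrow(shared),
    n_ls_only = sum(x$status == "ls_only"),
    shared_freq_spearman = rho
  )
}

#' Diversity summary as a glance row
#'
#' @param x A `tcr_repertoire`.
#' @param ... Passed to [summarize_diversity()].
#' @return A one-row tibble.
#' @export
glance.tcr_repertoire <- function(x, ...) {
  summarize_diversity(x, ...)
}
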