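#' Shannon entropy of a clone-frequency vector
#'
#' `H = -sum_i P_i log2(P_i)` in bits, where `P_i` is the frequency of
#' clone i. Ranges from 0 for a single clone to `log2(N)` for a uniform
#' repertoire of N clones. Zero-count clones must be dropped upstream;
#' zero entries are an error, not treated as a limit.
#'
#' @param frequencies Positive frequencies summing to 1 (within 1e-6).
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
shannon_entropy <- function(frequencies) {
  check_frequencies(frequencies)
  if (length(frequencies) == 1L) return(0)
  -sum(frequencies * log2(frequencies))
}

check_frequencies <- function(p) {
  if (length(p) < 1L) abort("frequency vector must be non-empty")
  if (any(is.na(p)) || any(p <= 0)) {
    abort("frequencies must be strictly positive (drop zero-count clones upstream)")
  }
  if (abs(sum(p) - 1) > 1e-6) abort("frequencies must sum to 1 within 1e-6")
  invisible(p)
}

#' Clonality of a clone-frequency vector
#'
#' `C = 1 - H_N` where `H_N = H / H_max` is Shannon entropy normalized by
#' its maximum `H_max = log2(N)`. Clonality is 0 when all clones are
#' equally abundant (fully polyclonal) and 1 when a single clone makes up
#' the entire sample. For a singleton repertoire (`N = 1`) `H_max = 0`
#' leaves `H_N` undefined; the boundary is defined as clonality 1,
#' maximal concentration.
#'
#' @inheritParams shannon_entropy
#' @return Clonality in `[0, 1]`.
#' @export
#' @examples
#' clonality(rep(1 / 8, 8)) # 0
#' clonality(1) # 1
clonality <- function(frequencies) {
  check_frequencies(frequencies)
  n <- length(frequencies)
  if (n == 1L) return(1)
  1 - shannon_entropy(frequencies) / log2(n)
}

#' Diversity summary of one repertoire
#'
#' Richness (unique clones), total templates, Shannon entropy, maximum
#' entropy, normalized entropy and clonality for one sample, computed on
#' productive clones by default.
#'
#' @param rep A [repertoire()].
#' @param productive_only Drop non-productive clones (and renormalize)
#'   before computing statistics.
#' @return A one-row tibble: `sample_id`, `patient_id`, `group`, `chain`,
#'   `n_unique`, `total_count`, `entropy`, `entropy_max`,
#'   `entropy_normalized`, `clonality`.
#' @export
summarize_diversity <- function(rep, productive_only = TRUE) {
  if (productive_only) rep <- filter_productive(rep)
  m <- rep_metadata(rep)
  p <- rep$count / sum(rep$count)
  h <- shannon_entropy(p)
  n <- nrow(rep)
  hmax <- log2(n)
  cl <- clonality(p)
  tibble(
    sample_id = m$sample_id, patient_id = m$patient_id,
    group = m$group, chain = m$chain,
    n_unique = n, total_count = sum(rep$count),
    entropy = h, entropy_max = hmax,
    entropy_normalized = 1 - cl, clonality = cl
  )
}

#' Diversity table for a whole cohort
#'
#' @param cohort A `tcr_cohort`.
#' @inheritParams summarize_diversity
#' @return A tibble with one [summarize_diversity()] row per sample.
#' @export
cohort_diversity <- function(cohort, productive_only = TRUE) {
  purrr::map_dfr(cohort$repertoires, summarize_diversity,
    productive_only = productive_only
  )
}

#' V or J gene-segment usage of a repertoire
#'
#' Per-gene usage fractions, either weighting every unique clone equally
#' (`by_clone`, each clone contributes 1/N) or by clone abundance
#' (`by_count`, each clone contributes its frequency). Unresolved gene
#' calls are pooled under `"unresolved"`. Usage sums to 1.
#'
#' @param rep A [repertoire()].
#' @param segment_class `"V"` or `"J"`.
#' @param weighting `"by_clone"` or `"by_count"`.
#' @param productive_only Drop non-productive clones first.
#' @return A tibble: `sample_id`, `segment_class`, `gene`, `usage`.
#' @export
vj_usage <- function(rep, segment_class = c("V", "J"),
                     weighting = c("by_clone", "by_count"),
                     productive_only = TRUE) {
  segment_class <- match.arg(segment_class)
  weighting <- match.arg(weighting)
  if (productive_only) rep <- filter_productive(rep)
  m <- rep_metadata(rep)
  gene <- if (segment_class == "V") rep$v_gene else rep$j_gene
  gene <- dplyr::coalesce(gene, "unresolved")
  w <- if (weighting == "by_clone") {
    base::rep(1 / nrow(rep), nrow(rep))
  } else {
    rep$frequency
  }
  tibble(gene = gene, w = w) |>
    group_by(.data$gene) |>
    summarise(usage = sum(.data$w), .groups = "drop") |>
    mutate(usage = .data$usage / sum(.data$usage)) |>
    mutate(
      sample_id = m$sample_id, segment_class = segment_class,
      .before = 1
    )
}

#' V/J usage table for a whole cohort
#'
#' @param cohort A `tcr_cohort`.
#' @inheritParams vj_usage
#' @return A tibble of per-sample [vj_usage()] rows joined with `group`.
#' @export
cohort_vj_usage <- function(cohort, segment_class = c("V", "J"),
                            weighting = c("by_clone", "by_count"),
                            productive_only = TRUE) {
  usage <- purrr::map_dfr(cohort$repertoires, vj_usage,
    segment_class = segment_class, weighting = weighting,
    productive_only = productive_only
  )
  left_join(usage,
    select(cohort$manifest, "sample_id", "patient_id", "group"),
    by = "sample_id"
  )
}
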