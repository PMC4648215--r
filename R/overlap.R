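comparison_group_label <- function(ga, gb) {
  abbr <- c(normal = "N", non_lesional = "NL", lesional = "LS")
  a <- abbr[[ga]]
  b <- abbr[[gb]]
  ord <- c("N", "NL", "LS")
  pair <- c(a, b)[order(match(c(a, b), ord))]
  if (pair[1] == "N" && pair[2] == "N") "NN" else paste(pair, collapse = "-")
}

#' Pairwise repertoire overlap
#'
#' Shared-clonotype count and a normalized overlap score between two
#' repertoires of the same chain. The default score is the Jaccard index
#' on unique clonotype keys, `|A intersect B| / |A union B|` — shared
#' sequences normalized to the total number of sequences. Alternatives:
#' `"min"` (shared / size of the smaller repertoire) and `"morisita"`
#' (Morisita-Horn on clone frequencies, abundance-weighted). All three
#' are symmetric, lie in `[0, 1]`, and are 0 exactly when no clonotype is
#' shared.
#'
#' @param rep_a,rep_b Two [repertoire()]s of the same chain.
#' @param key_mode Clonotype identity, see [identity_key()].
#' @param normalization `"jaccard"` (default), `"min"` or `"morisita"`.
#' @param productive_only Drop non-productive clones first.
#' @return A one-row tibble (`sample_a`, `sample_b`, `n_shared`, `score`,
#'   `comparison_group`, `same_patient`, `excluded`). `excluded` flags
#'   within-patient non-lesional vs lesional comparisons, which are left
#'   out of pooled group summaries to avoid inflating the NL-LS group.
#' @export
overlap_score <- function(rep_a, rep_b, key_mode = c("nt_vj", "aa_only"),
                          normalization = c("jaccard", "min", "morisita"),
                          productive_only = TRUE) {
  key_mode <- match.arg(key_mode)
  normalization <- match.arg(normalization)
  ma <- rep_metadata(rep_a)
  mb <- rep_metadata(rep_b)
  if (ma$chain != mb$chain) {
    abort(sprintf(
      "cannot compare repertoires of different chains (%s vs %s)",
      ma$chain, mb$chain
    ))
  }
  if (productive_only) {
    rep_a <- filter_productive(rep_a)
    rep_b <- filter_productive(rep_b)
  }
  fa <- key_frequencies(rep_a, key_mode)
  fb <- key_frequencies(rep_b, key_mode)
  shared <- intersect(names(fa), names(fb))
  n_shared <- length(shared)
  score <- if (n_shared == 0L) {
    0
  } else {
    switch(normalization,
      jaccard = n_shared / length(union(names(fa), names(fb))),
      min = n_shared / min(length(fa), length(fb)),
      morisita = {
        p <- fa[shared]
        q <- fb[shared]
        2 * sum(p * q) / (sum(fa^2) + sum(fb^2))
      }
    )
  }
  grp <- comparison_group_label(ma$group, mb$group)
  same_patient <- ma$patient_id == mb$patient_id
  tibble(
    sample_a = ma$sample_id, sample_b = mb$sample_id,
    n_shared = n_shared, score = score,
    comparison_group = grp,
    same_patient = same_patient,
    excluded = same_patient && grp == "NL-LS"
  )
}

# per-key frequencies (aa_only collapses synonymous clonotypes)
key_frequencies <- function(rep, key_mode) {
  key <- identity_key(rep, key_mode)
  f <- tapply(rep$frequency, key, sum)
  setNames(as.numeric(f), names(f))
}

#' Pool pairwise overlaps across a cohort
#'
#' Computes one [overlap_score()] record for every unordered pair of
#' samples and labels it by comparison group (NN, N-NL, N-LS, NL-NL,
#' NL-LS, LS-LS). Within-patient non-lesional vs lesional pairs are
#' flagged `excluded`; group summaries and tests should drop them
#' (see `drop_excluded`) so the NL-LS group is not inflated by
#' within-patient sharing.
#'
#' @param cohort A `tcr_cohort` (single chain).
#' @inheritParams overlap_score
#' @param drop_excluded Drop the flagged within-patient NL-LS records
#'   from the returned table (default keeps them, flagged).
#' @return A tibble of overlap records, one per pair.
#' @export
pool_overlaps <- function(cohort, key_mode = c("nt_vj", "aa_only"),
                          normalization = c("jaccard", "min", "morisita"),
                          productive_only = TRUE, drop_excluded = FALSE) {
  key_mode <- match.arg(key_mode)
  normalization <- match.arg(normalization)
  reps <- cohort$repertoires
  if (length(unique(cohort$manifest$chain)) > 1L) {
    abort("pool_overlaps requires a single-chain cohort (statistics never mix TRB and TRG)")
  }
  if (length(reps) < 2L) abort("need at least two samples to pool overlaps")
  if (productive_only) reps <- purrr::map(reps, filter_productive)
  pairs <- utils::combn(length(reps), 2L)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    overlap_score(reps[[pairs[1, k]]], reps[[pairs[2, k]]],
      key_mode = key_mode, normalization = normalization,
      productive_only = FALSE
    )
  })
  if (drop_excluded) out <- filter(out, !.data$excluded)
  out
}

#' Paired non-lesional vs lesional clone comparison
#'
#' Partitions the union of a patient's clonotypes into clones unique to
#' non-lesional skin, unique to lesional skin, and shared, with each
#' clone's frequency as percent of total templates per sample (0 where
#' absent). The per-set counts mirror the numbers reported under paired
#' tissue scatter plots.
#'
#' @param nl,ls The patient's non-lesional and lesional [repertoire()]s
#'   (same `patient_id`, same chain).
#' @inheritParams overlap_score
#' @return A `tcr_paired` tibble: `key`, `status`
#'   (`nl_only`/`shared`/`ls_only`), `freq_nl`, `freq_ls` (percent);
#'   attributes `patient_id` and `chain`. See [glance.tcr_paired()].
#' @export
paired_comparison <- function(nl, ls, key_mode = c("nt_vj", "aa_only"),
                              productive_only = TRUE) {
  key_mode <- match.arg(key_mode)
  mnl <- rep_metadata(nl)
  mls <- rep_metadata(ls)
  if (mnl$patient_id != mls$patient_id) {
    abort(sprintf(
      "paired comparison requires one patient (got %s and %s)",
      mnl$patient_id, mls$patient_id
    ))
  }
  if (mnl$chain != mls$chain) abort("paired comparison requires one chain")
  if (productive_only) {
    nl <- filter_productive(nl)
    ls <- filter_productive(ls)
  }
  fnl <- key_frequencies(nl, key_mode)
  fls <- key_frequencies(ls, key_mode)
  keys <- union(names(fnl), names(fls))
  freq_nl <- unname(fnl[keys]) * 100
  freq_ls <- unname(fls[keys]) * 100
  freq_nl[is.na(freq_nl)] <- 0
  freq_ls[is.na(freq_ls)] <- 0
  out <- tibble(
    key = keys,
    status = dplyr::case_when(
      freq_nl > 0 & freq_ls > 0 ~ "shared",
      freq_nl > 0 ~ "nl_only",
      TRUE ~ "ls_only"
    ),
    freq_nl = freq_nl, freq_ls = freq_ls
  )
  tibble::new_tibble(out,
    class = "tcr_paired",
    patient_id = mnl$patient_id, chain = mnl$chain, key_mode = key_mode
  )
}

#' Clonotypes common to every sample in a scope
#'
#' Intersects clonotype key sets across all given repertoires — e.g. the
#' public clones present in every lesional sample. Cross-patient public
#' clones are conventionally keyed at the amino-acid level (`aa_only`),
#' where convergent recombination can produce sharing that nucleotide
#' keys miss.
#'
#' @param samples A list of [repertoire()]s (or a `tcr_cohort`, optionally
#'   filtered with `groups`).
#' @param key_mode Clonotype identity, default `"aa_only"`.
#' @param groups If `samples` is a cohort, restrict the scope to these
#'   tissue groups.
#' @inheritParams overlap_score
#' @return A tibble in long form: `key`, `sample_id`, `frequency`
#'   (fraction), one row per common clone per sample; zero rows when no
#'   clonotype is shared by all samples. Attribute `scope` lists the
#'   sample ids intersected.
#' @export
common_clones <- function(samples, key_mode = c("aa_only", "nt_vj"),
                          groups = NULL, productive_only = TRUE) {
  key_mode <- match.arg(key_mode)
  if (inherits(samples, "tcr_cohort")) {
    keep <- if (is.null(groups)) {
      samples$manifest$sample_id
    } else {
      samples$manifest$sample_id[samples$manifest$group %in% groups]
    }
    samples <- samples$repertoires[keep]
  }
  if (length(samples) < 1L) abort("common_clones needs at least one sample")
  chains <- purrr::map_chr(samples, ~ rep_metadata(.x)$chain)
  if (length(unique(chains)) > 1L) {
    abort("common_clones requires samples of a single chain")
  }
  if (productive_only) samples <- purrr::map(samples, filter_productive)
  freq_tbl <- purrr::map_dfr(samples, function(r) {
    f <- key_frequencies(r, key_mode)
    tibble(
      key = names(f), sample_id = rep_metadata(r)$sample_id,
      frequency = as.numeric(f)
    )
  })
  common <- freq_tbl |>
    group_by(.data$key) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample_id), .groups = "drop") |>
    filter(.data$n_samples == length(samples))
  out <- freq_tbl |>
    filter(.data$key %in% common$key) |>
    arrange(.data$key, .data$sample_id)
  attr(out, "scope") <- purrr::map_chr(samples, ~ rep_metadata(.x)$sample_id)
  attr(out, "key_mode") <- key_mode
  out
}
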