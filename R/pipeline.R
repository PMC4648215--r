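#' Run the full repertoire analysis pipeline
#'
#' Executes the whole analysis on a cohort deterministically:
#' read and validate clone tables, productive filtering, per-sample
#' diversity, V/J usage, pooled pairwise overlaps with the within-patient
#' NL-LS exclusion, group inference (pairwise t-tests on unique counts
#' and clonality; ANOVA plus pairwise t-tests on pooled overlap scores),
#' paired non-lesional/lesional comparisons for every patient with both
#' tissues, and public-clone detection over the lesional and the combined
#' psoriatic samples. Re-running on identical inputs and configuration
#' yields a byte-identical report.
#'
#' @param manifest A manifest path, manifest tibble, or `tcr_cohort`.
#' @param dialect Clone-table dialect when reading from disk.
#' @param out_dir If non-`NULL`, stage TSVs and `report.json` are written
#'   here.
#' @param key_mode_paired Clonotype identity for within-patient paired
#'   comparisons (default nucleotide-level, `"nt_vj"`).
#' @param key_mode_overlap Clonotype identity for the pooled cross-sample
#'   overlap stage (default amino-acid-level, `"aa_only"`, since those
#'   comparisons are predominantly cross-patient, where convergent
#'   amino-acid sharing is the meaningful unit).
#' @param key_mode_public Clonotype identity for cross-patient public
#'   clones (default amino-acid-level, `"aa_only"`).
#' @param overlap_norm Overlap score normalization, see [overlap_score()].
#' @param productive_only Restrict all statistics to productive clones.
#' @param alpha Significance threshold for all tests.
#' @return A `tcr_report` list: `diversity`, `vj_usage`, `overlaps`
#'   (all pairs, flagged), `overlap_pooled` (exclusions dropped),
#'   `diversity_tests`, `overlap_tests`, `paired` (named list of
#'   [paired_comparison()] results), `public_lesional`,
#'   `public_psoriatic`, `provenance`.
#' @export
run_pipeline <- function(manifest, dialect = c("immunoseq", "airr"),
                         out_dir = NULL,
                         key_mode_paired = c("nt_vj", "aa_only"),
                         key_mode_overlap = c("aa_only", "nt_vj"),
                         key_mode_public = c("aa_only", "nt_vj"),
                         overlap_norm = c("jaccard", "min", "morisita"),
                         productive_only = TRUE, alpha = 0.05) {
  dialect <- match.arg(dialect)
  key_mode_paired <- match.arg(key_mode_paired)
  key_mode_overlap <- match.arg(key_mode_overlap)
  key_mode_public <- match.arg(key_mode_public)
  overlap_norm <- match.arg(overlap_norm)

  input_checksums <- NULL
  if (inherits(manifest, "tcr_cohort")) {
    coh <- manifest
  } else {
    manifest_path <- if (is.character(manifest)) manifest else NULL
    coh <- load_cohort(manifest, dialect)
    if (!is.null(manifest_path)) {
      paths <- file.path(dirname(manifest_path), coh$manifest$path)
      input_checksums <- setNames(
        unname(tools::md5sum(paths)), coh$manifest$sample_id
      )
    }
  }
  if (length(unique(coh$manifest$chain)) > 1L) {
    abort("run_pipeline analyzes one chain at a time (TRB and TRG are never mixed)")
  }

  diversity <- cohort_diversity(coh, productive_only = productive_only)
  usage <- bind_rows(
    cohort_vj_usage(coh, "V", productive_only = productive_only),
    cohort_vj_usage(coh, "J", productive_only = productive_only)
  )
  overlaps <- pool_overlaps(coh,
    key_mode = key_mode_overlap, normalization = overlap_norm,
    productive_only = productive_only
  )
  overlap_pooled <- filter(overlaps, !.data$excluded)

  diversity_tests <- bind_rows(
    compare_metric_across_groups(diversity, "unique_count", alpha = alpha),
    compare_metric_across_groups(diversity, "clonality", alpha = alpha)
  )
  overlap_tests <- compare_metric_across_groups(
    overlaps, "overlap_score",
    alpha = alpha
  )

  man <- coh$manifest
  paired_patients <- intersect(
    man$patient_id[man$group == "non_lesional"],
    man$patient_id[man$group == "lesional"]
  )
  paired <- purrr::map(paired_patients, function(pid) {
    nl_id <- man$sample_id[man$patient_id == pid & man$group == "non_lesional"]
    ls_id <- man$sample_id[man$patient_id == pid & man$group == "lesional"]
    paired_comparison(
      coh$repertoires[[nl_id]], coh$repertoires[[ls_id]],
      key_mode = key_mode_paired, productive_only = productive_only
    )
  })
  names(paired) <- paired_patients

  public_lesional <- common_clones(coh,
    key_mode = key_mode_public,
    groups = "lesional", productive_only = productive_only
  )
  public_psoriatic <- common_clones(coh,
    key_mode = key_mode_public,
    groups = c("non_lesional", "lesional"), productive_only = productive_only
  )

  provenance <- list(
    package_version = as.character(utils::packageVersion("tcrep")),
    dialect = dialect,
    key_mode_paired = key_mode_paired,
    key_mode_overlap = key_mode_overlap,
    key_mode_public = key_mode_public,
    overlap_normalization = overlap_norm,
    productive_only = productive_only,
    alpha = alpha,
    chain = unique(coh$manifest$chain),
    n_samples = nrow(coh$manifest),
    input_checksums = input_checksums
  )

  report <- structure(
    list(
      diversity = diversity, vj_usage = usage,
      overlaps = overlaps, overlap_pooled = overlap_pooled,
      diversity_tests = diversity_tests, overlap_tests = overlap_tests,
      paired = paired,
      public_lesional = public_lesional,
      public_psoriatic = public_psoriatic,
      provenance = provenance
    ),
    class = "tcr_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.tcr_report <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "# TCR analysis report: %d %s samples\n", p$n_samples, p$chain
  ))
  cat(sprintf(
    "# diversity rows: %d; pooled overlap records: %d (%d excluded); paired patients: %d\n",
    nrow(x$diversity), nrow(x$overlap_pooled),
    sum(x$overlaps$excluded), length(x$paired)
  ))
  cat(sprintf(
    "# public clones: %d in all lesional, %d in all psoriatic samples\n",
    dplyr::n_distinct(x$public_lesional$key),
    dplyr::n_distinct(x$public_psoriatic$key)
  ))
  invisible(x)
}

flatten_tests <- function(tests) {
  tests |>
    mutate(
      groups = purrr::map_chr(.data$groups, paste, collapse = ";"),
      means = purrr::map_chr(.data$means, ~ paste(signif(.x, 10), collapse = ";")),
      sems = purrr::map_chr(.data$sems, ~ paste(signif(.x, 10), collapse = ";"))
    )
}

#' Write a pipeline report to disk
#'
#' Writes stage TSVs (`diversity.tsv`, `vj_usage.tsv`, `overlaps.tsv`,
#' `diversity_tests.tsv`, `overlap_tests.tsv`, per-patient
#' `paired_<id>.tsv`, `public_clones.tsv`) and a machine-readable
#' `report.json` with stable key order and no timestamps, so identical
#' inputs give byte-identical output.
#'
#' @param report A `tcr_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  }
  w(report$diversity, "diversity.tsv")
  w(report$vj_usage, "vj_usage.tsv")
  w(report$overlaps, "overlaps.tsv")
  w(flatten_tests(report$diversity_tests), "diversity_tests.tsv")
  w(flatten_tests(report$overlap_tests), "overlap_tests.tsv")
  for (pid in names(report$paired)) {
    w(as_tibble(report$paired[[pid]]), sprintf("paired_%s.tsv", pid))
  }
  pub <- bind_rows(
    mutate(report$public_lesional, scope = "lesional"),
    mutate(report$public_psoriatic, scope = "psoriatic")
  )
  w(pub, "public_clones.tsv")
  payload <- list(
    provenance = report$provenance,
    diversity = report$diversity,
    diversity_tests = flatten_tests(report$diversity_tests),
    overlap_tests = flatten_tests(report$overlap_tests),
    overlap_group_summary = report$overlap_pooled |>
      group_by(.data$comparison_group) |>
      summarise(
        n_pairs = dplyr::n(),
        mean_score = mean(.data$score),
        sem_score = sem(.data$score),
        .groups = "drop"
      ),
    paired_counts = purrr::imap_dfr(report$paired, function(pc, pid) {
      tibble(
        patient_id = pid,
        n_nl_only = sum(pc$status == "nl_only"),
        n_shared = sum(pc$status == "shared"),
        n_ls_only = sum(pc$status == "ls_only")
      )
    }),
    public_clones = pub
  )
  jsonlite::write_json(
    payload, file.path(out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
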