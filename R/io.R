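#' Read a per-sample clone table
#'
#' Reads one sample's clonotype TSV in either the immunoSEQ-export dialect
#' (`nucleotide`, `aminoAcid`, `count`, `frequencyCount`, `vGeneName`,
#' `dGeneName`, `jGeneName`, `sequenceStatus`) or the AIRR Rearrangement
#' dialect (`sequence`/`junction`, `junction_aa`, `duplicate_count`,
#' `v_call`, `d_call`, `j_call`, `productive`). Rows are collapsed by the
#' nucleotide clonotype key (CDR3 nt + V + J) with counts summed, and
#' frequencies are recomputed as `count / total count` — the frequency
#' column of the input file, where present, is ignored.
#'
#' Template counts are preferred over read counts where the dialect
#' distinguishes them: for immunoSEQ files the first of `templates`,
#' `count (template/reads)`, `count`, `reads` present is used and recorded
#' in the `count_column` attribute of the result.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @param metadata A named list or one-row data frame with `sample_id`,
#'   `patient_id`, `group`, `chain` and optionally `source_material`.
#' @return A [repertoire()].
#' @export
read_clone_table <- function(path, dialect = c("immunoseq", "airr"),
                             metadata) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("clone table not found: %s", path))
  metadata <- as.list(metadata)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  parsed <- switch(dialect,
    immunoseq = parse_immunoseq(raw, path),
    airr = parse_airr(raw, path)
  )
  if (nrow(parsed$clones) == 0L) {
    abort(sprintf("empty clone table: %s (a repertoire must have >= 1 clone)", path))
  }
  check_counts(parsed$clones, path)
  rep <- repertoire(parsed$clones,
    sample_id = metadata$sample_id,
    patient_id = metadata$patient_id,
    group = metadata$group,
    chain = metadata$chain,
    source_material = metadata$source_material
  )
  attr(rep, "count_column") <- parsed$count_column
  rep
}

check_counts <- function(clones, path) {
  cnt <- suppressWarnings(as.numeric(clones$count))
  bad <- which(is.na(cnt) | cnt <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-positive or missing count in %s at data row %d", path, bad[1]
    ))
  }
}

require_columns <- function(raw, cols, dialect, path) {
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is not a valid %s clone table: missing column '%s'",
      path, dialect, missing[1]
    ))
  }
}

IMMUNOSEQ_COUNT_COLUMNS <-
  c("templates", "count (template/reads)", "count (templates/reads)", "count", "reads")

parse_immunoseq <- function(raw, path) {
  count_column <- intersect(IMMUNOSEQ_COUNT_COLUMNS, names(raw))[1]
  required <- c(
    "nucleotide", "aminoAcid",
    if (is.na(count_column)) "count",
    "frequencyCount", "vGeneName", "dGeneName", "jGeneName", "sequenceStatus"
  )
  require_columns(raw, required, "immunoseq", path)
  clones <- tibble(
    cdr3_nt = raw$nucleotide,
    cdr3_aa = dplyr::coalesce(raw$aminoAcid, ""),
    v_gene = raw$vGeneName,
    d_gene = raw$dGeneName,
    j_gene = raw$jGeneName,
    count = raw[[count_column]],
    productive = raw$sequenceStatus %in% c("In", "in", "In-frame", "Productive")
  )
  list(clones = clones, count_column = count_column)
}

parse_airr <- function(raw, path) {
  seq_col <- if ("junction" %in% names(raw)) "junction" else "sequence"
  required <- c(
    seq_col, "junction_aa", "duplicate_count",
    "v_call", "d_call", "j_call", "productive"
  )
  require_columns(raw, required, "airr", path)
  clones <- tibble(
    cdr3_nt = raw[[seq_col]],
    cdr3_aa = dplyr::coalesce(raw$junction_aa, ""),
    v_gene = raw$v_call,
    d_gene = raw$d_call,
    j_gene = raw$j_call,
    count = raw$duplicate_count,
    productive = parse_airr_logical(raw$productive)
  )
  list(clones = clones, count_column = "duplicate_count")
}

parse_airr_logical <- function(x) {
  up <- toupper(stringr::str_trim(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "1", "YES", "Y")] <- TRUE
  out[up %in% c("F", "FALSE", "0", "NO", "N")] <- FALSE
  if (anyNA(out)) abort("unrecognized value in AIRR 'productive' column")
  out
}

#' Write a clone table
#'
#' Writes a repertoire back to TSV in either dialect. The writer and
#' [read_clone_table()] round-trip: re-reading a written file reproduces
#' the same clonotype keys and counts. immunoSEQ `frequencyCount` is
#' written as percent of total templates, AIRR frequencies as fractions.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output path.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(rep, path, dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  validate_repertoire(rep)
  text_fields <- c(
    rep$cdr3_nt, rep$cdr3_aa, rep$v_gene, rep$d_gene, rep$j_gene
  )
  if (any(stringr::str_detect(
    text_fields[!is.na(text_fields)], "[\t\n\r]"
  ))) {
    abort("clone fields must not contain tab or newline characters")
  }
  out <- if (dialect == "immunoseq") {
    tibble(
      nucleotide = rep$cdr3_nt,
      aminoAcid = rep$cdr3_aa,
      count = rep$count,
      frequencyCount = rep$frequency * 100,
      vGeneName = dplyr::coalesce(rep$v_gene, "unresolved"),
      dGeneName = dplyr::coalesce(rep$d_gene, "unresolved"),
      jGeneName = dplyr::coalesce(rep$j_gene, "unresolved"),
      sequenceStatus = ifelse(rep$productive, "In", "Out")
    )
  } else {
    tibble(
      junction = rep$cdr3_nt,
      junction_aa = rep$cdr3_aa,
      duplicate_count = rep$count,
      duplicate_frequency = rep$frequency,
      v_call = dplyr::coalesce(rep$v_gene, ""),
      d_call = dplyr::coalesce(rep$d_gene, ""),
      j_call = dplyr::coalesce(rep$j_gene, ""),
      productive = ifelse(rep$productive, "T", "F")
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a TSV binding clone-table files to sample metadata,
#' with columns `sample_id`, `patient_id`, `group`, `chain`,
#' `source_material`, `path`. Validates the study-design invariants:
#' unique sample ids, at most one sample per (patient, group, chain), and
#' normal-group patients disjoint from psoriatic patients.
#'
#' @param path Manifest TSV path.
#' @return A tibble, one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  man <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  require_columns(
    man,
    c("sample_id", "patient_id", "group", "chain", "source_material", "path"),
    "manifest", path
  )
  validate_manifest(man)
  man
}

validate_manifest <- function(man) {
  if (anyDuplicated(man$sample_id) > 0L) abort("duplicate sample_id in manifest")
  if (!all(man$group %in% TISSUE_GROUPS)) {
    abort(sprintf("manifest group must be one of: %s", toString(TISSUE_GROUPS)))
  }
  if (!all(man$chain %in% CHAINS)) {
    abort(sprintf("manifest chain must be one of: %s", toString(CHAINS)))
  }
  if (anyDuplicated(man[c("patient_id", "group", "chain")]) > 0L) {
    abort("each (patient_id, group, chain) may appear at most once in a cohort")
  }
  normal_pat <- man$patient_id[man$group == "normal"]
  psor_pat <- man$patient_id[man$group != "normal"]
  if (length(intersect(normal_pat, psor_pat)) > 0L) {
    abort("normal-group samples must not share patient_id with psoriatic samples")
  }
  invisible(man)
}

#' Load a cohort of repertoires from a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()] or a path to one.
#' @param dialect Clone-table dialect for every file.
#' @param base_dir Directory that relative manifest paths are resolved
#'   against (defaults to the manifest's own directory when `manifest` is
#'   a path).
#' @return A `tcr_cohort`: a list with `repertoires` (named list of
#'   `tcr_repertoire`) and `manifest` (tibble).
#' @export
load_cohort <- function(manifest, dialect = c("immunoseq", "airr"),
                        base_dir = NULL) {
  dialect <- match.arg(dialect)
  if (is.character(manifest) && length(manifest) == 1L) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    validate_manifest(manifest)
    base_dir <- base_dir %||% "."
  }
  paths <- ifelse(
    grepl("^(/|[A-Za-z]:)", manifest$path),
    manifest$path, file.path(base_dir, manifest$path)
  )
  missing <- !file.exists(paths)
  if (any(missing)) {
    abort(sprintf(
      "clone table for sample '%s' not found at %s",
      manifest$sample_id[missing][1], paths[missing][1]
    ))
  }
  reps <- purrr::map(seq_len(nrow(manifest)), function(i) {
    read_clone_table(paths[i], dialect, metadata = manifest[i, ])
  })
  names(reps) <- manifest$sample_id
  new_cohort(reps, manifest)
}

new_cohort <- function(repertoires, manifest) {
  structure(
    list(repertoires = repertoires, manifest = as_tibble(manifest)),
    class = "tcr_cohort"
  )
}

#' Build a cohort object from repertoires in memory
#'
#' @param repertoires A list of `tcr_repertoire` objects.
#' @return A `tcr_cohort` with a manifest derived from the repertoires'
#'   metadata (`path` is `NA` until the cohort is written to disk).
#' @export
cohort <- function(repertoires) {
  man <- purrr::map_dfr(repertoires, function(r) {
    as_tibble(rep_metadata(r))
  })
  man$path <- NA_character_
  names(repertoires) <- man$sample_id
  validate_manifest(man)
  new_cohort(repertoires, man)
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf(
    "# TCR cohort: %d samples (%s)\n",
    length(x$repertoires),
    paste(sprintf(
      "%d %s", table(x$manifest$group)[unique(x$manifest$group)],
      unique(x$manifest$group)
    ), collapse = ", ")
  ))
  print(x$manifest, ...)
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one clone table per sample plus a `manifest.tsv` binding files
#' to metadata, in a layout that [load_cohort()] and [run_pipeline()]
#' accept.
#'
#' @param cohort A `tcr_cohort`.
#' @param dir Output directory (created if needed).
#' @param dialect Dialect for the clone tables.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- paste0(man$sample_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    write_clone_table(
      cohort$repertoires[[man$sample_id[i]]],
      file.path(dir, man$path[i]), dialect
    )
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(man, manifest_path, progress = FALSE)
  invisible(manifest_path)
}
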