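#' Construct a TCR repertoire
#'
#' A repertoire is one sample's clone table: a tibble with one row per
#' clonotype (columns `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`,
#' `count`, `frequency`, `productive`) carrying the sample's metadata
#' (sample id, patient id, tissue group, receptor chain, source material)
#' as attributes. All downstream statistics operate on this object.
#'
#' Clones are collapsed on construction by the nucleotide identity key
#' (CDR3 nucleotide sequence + V + J gene, see [identity_key()]): rows with
#' the same key have their counts summed. Frequencies are always recomputed
#' as `count / sum(count)`, so they sum to 1 within 1e-6 by construction.
#'
#' @param clones A data frame with at least `cdr3_nt`, `count`. Missing
#'   optional columns are filled (`cdr3_aa` by translation where the
#'   sequence length is a multiple of 3, genes with `NA`, `productive`
#'   from the amino-acid sequence).
#' @param sample_id,patient_id Sample and patient identifiers.
#' @param group Tissue group: `"normal"`, `"non_lesional"` or `"lesional"`.
#' @param chain Receptor chain, `"TRB"` or `"TRG"`.
#' @param source_material `"gDNA"` or `"cDNA"`. Defaults to the study
#'   pairing: gDNA for the beta chain, cDNA for the gamma chain.
#' @return A `tcr_repertoire` tibble.
#' @export
#' @examples
#' rep <- repertoire(
#'   tibble::tibble(
#'     cdr3_nt = c("TGTGCCAGCAGC", "TGTGCCTGGAGC"),
#'     cdr3_aa = c("CASS", "CAWS"),
#'     v_gene = "TRBV05-1", j_gene = "TRBJ02-1",
#'     count = c(6L, 4L), productive = TRUE
#'   ),
#'   sample_id = "s1", patient_id = "p1", group = "lesional", chain = "TRB"
#' )
#' rep$frequency # 0.6 0.4
repertoire <- function(clones, sample_id, patient_id, group, chain,
                       source_material = NULL) {
  group <- match.arg(group, TISSUE_GROUPS)
  chain <- match.arg(chain, CHAINS)
  source_material <- source_material %||%
    if (chain == "TRB") "gDNA" else "cDNA"
  source_material <- match.arg(source_material, SOURCE_MATERIALS)
  meta <- list(
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    group = group, chain = chain, source_material = source_material
  )
  clones <- normalize_clone_columns(as_tibble(clones))
  clones <- collapse_clones(clones)
  out <- new_repertoire(clones, meta)
  validate_repertoire(out)
  out
}

new_repertoire <- function(clones, meta) {
  tibble::new_tibble(clones,
    class = "tcr_repertoire",
    tcr_metadata = meta
  )
}

#' Sample metadata of a repertoire
#'
#' @param rep A `tcr_repertoire`.
#' @return A named list with `sample_id`, `patient_id`, `group`, `chain`,
#'   `source_material`.
#' @export
rep_metadata <- function(rep) {
  meta <- attr(rep, "tcr_metadata")
  if (is.null(meta)) abort("not a tcr_repertoire: metadata attribute missing")
  meta
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  m <- rep_metadata(x)
  cat(sprintf(
    "# TCR repertoire: %s (patient %s, %s, %s, %s)\n",
    m$sample_id, m$patient_id, m$group, m$chain, m$source_material
  ))
  cat(sprintf(
    "# %d unique clones, %d total templates\n",
    nrow(x), sum(x$count)
  ))
  NextMethod()
}

CLONE_COLUMNS <- c(
  "cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene",
  "count", "frequency", "productive"
)

normalize_clone_columns <- function(clones) {
  if (!"cdr3_nt" %in% names(clones)) abort("clone table needs a cdr3_nt column")
  if (!"count" %in% names(clones)) abort("clone table needs a count column")
  clones$cdr3_nt <- toupper(as.character(clones$cdr3_nt))
  if (!"cdr3_aa" %in% names(clones)) {
    clones$cdr3_aa <- ifelse(
      nchar(clones$cdr3_nt) %% 3L == 0L,
      translate_nt(clones$cdr3_nt), ""
    )
  }
  clones$cdr3_aa <- dplyr::coalesce(as.character(clones$cdr3_aa), "")
  for (g in c("v_gene", "d_gene", "j_gene")) {
    clones[[g]] <- if (g %in% names(clones)) {
      normalize_gene_call(clones[[g]])
    } else {
      NA_character_
    }
  }
  if (!"productive" %in% names(clones)) {
    clones$productive <- clones$cdr3_aa != "" &
      !stringr::str_detect(clones$cdr3_aa, stringr::fixed("*"))
  }
  clones$productive <- as.logical(clones$productive)
  clones$count <- as.integer(round(as.numeric(clones$count)))
  clones[CLONE_COLUMNS[CLONE_COLUMNS != "frequency"]]
}

#' Normalize a gene-segment call to gene level
#'
#' Takes the first gene of an ambiguous comma-separated call and strips
#' allele suffixes (`*01`), so comparisons are at gene level. Empty or
#' `"unresolved"`/`"unknown"` markers become `NA`.
#'
#' @param x Character vector of gene calls.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_gene_call(c("TRBV05-1*01", "TRBV12-3,TRBV12-4", ""))
normalize_gene_call <- function(x) {
  x <- as.character(x)
  x <- stringr::str_trim(stringr::str_split_i(x, stringr::fixed(","), 1L))
  x <- stringr::str_remove(x, "\\*.*$")
  x[is.na(x) | x == "" | tolower(x) %in% c("unresolved", "unknown", "na")] <-
    NA_character_
  x
}

#' Clonotype identity key
#'
#' Defines when two clone records count as the same clonotype. In
#' `"nt_vj"` mode the key is the CDR3 nucleotide sequence together with the
#' V and J gene (the vendor-style clonotype definition, used for
#' within-cohort counting and paired comparisons; the D gene is excluded).
#' In `"aa_only"` mode the key is the CDR3 amino-acid sequence alone, the
#' convergent unit used for cross-patient public-clone detection.
#'
#' @param clones A repertoire or clone data frame.
#' @param mode `"nt_vj"` (default) or `"aa_only"`.
#' @return A character vector of opaque comparable keys, one per clone.
#' @export
identity_key <- function(clones, mode = c("nt_vj", "aa_only")) {
  mode <- match.arg(mode)
  if (mode == "nt_vj") {
    paste(clones$cdr3_nt,
      dplyr::coalesce(clones$v_gene, "."),
      dplyr::coalesce(clones$j_gene, "."),
      sep = "\x1f"
    )
  } else {
    aa <- clones$cdr3_aa
    if (any(is.na(aa) | aa == "")) {
      abort("aa_only identity is undefined for clones with an empty CDR3 amino-acid sequence")
    }
    aa
  }
}

# Collapse rows sharing an identity key: counts summed, first row's fields
# kept, input order of first occurrence preserved, frequencies recomputed.
collapse_clones <- function(clones, mode = "nt_vj") {
  if (nrow(clones) == 0L) abort("a repertoire must contain at least one clone")
  bad <- which(is.na(clones$count) | clones$count < 1L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "non-positive clone count at row %d (counts must be >= 1)", bad[1]
    ))
  }
  key <- identity_key(clones, mode)
  if (anyDuplicated(key) == 0L) {
    clones$frequency <- clones$count / sum(clones$count)
    return(clones[CLONE_COLUMNS])
  }
  first <- !duplicated(key)
  sums <- rowsum(as.numeric(clones$count), key)
  out <- clones[first, , drop = FALSE]
  out$count <- as.integer(sums[match(key[first], rownames(sums)), 1L])
  out$frequency <- out$count / sum(out$count)
  out[CLONE_COLUMNS]
}

validate_repertoire <- function(rep) {
  if (nrow(rep) == 0L) abort("a repertoire must contain at least one clone")
  if (any(rep$cdr3_nt == "" | is.na(rep$cdr3_nt))) {
    abort("every clone needs a non-empty CDR3 nucleotide sequence")
  }
  if (any(rep$count < 1L)) abort("clone counts must be >= 1")
  if (abs(sum(rep$frequency) - 1) > 1e-6) {
    abort("clone frequencies must sum to 1 within 1e-6")
  }
  stop_in_aa <- stringr::str_detect(rep$cdr3_aa, stringr::fixed("*"))
  bad_prod <- rep$productive & (rep$cdr3_aa == "" | stop_in_aa)
  if (any(bad_prod)) {
    abort("productive clones must have a stop-free, non-empty CDR3 amino-acid sequence")
  }
  if (anyDuplicated(identity_key(rep, "nt_vj")) > 0L) {
    abort("duplicate clonotype identity keys after collapsing")
  }
  invisible(rep)
}

#' Keep only productive clones
#'
#' Drops out-of-frame / stop-containing clones and renormalizes frequencies
#' over the retained clones, leaving the input unchanged. Diversity and
#' overlap statistics are computed on productive clones by default,
#' matching how repertoire studies report "productive unique sequences".
#'
#' @param rep A `tcr_repertoire`.
#' @return A `tcr_repertoire` with only productive clones.
#' @export
filter_productive <- function(rep) {
  keep <- rep$productive
  if (!any(keep)) abort("no productive clones left after filtering")
  clones <- as_tibble(rep)[keep, , drop = FALSE]
  clones$frequency <- clones$count / sum(clones$count)
  out <- new_repertoire(clones, rep_metadata(rep))
  validate_repertoire(out)
  out
}

# CDR3 nucleotide -> amino acid via the standard genetic code,
# vectorized by grouping sequences of equal length
translate_nt <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(nt)
  if (any(n == 0L | n %% 3L != 0L)) {
    abort("cannot translate a sequence whose length is not a multiple of 3")
  }
  out <- character(length(nt))
  for (len in unique(n)) {
    idx <- which(n == len)
    codon_mat <- vapply(
      seq(1L, len, 3L),
      function(s) substr(nt[idx], s, s + 2L),
      character(length(idx))
    )
    aa <- gc[codon_mat]
    aa[is.na(aa)] <- "X"
    aa_mat <- matrix(aa, nrow = length(idx))
    out[idx] <- do.call(paste0, asplit(aa_mat, 2L))
  }
  out
}
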