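# In-code fixtures shared by the suite. Everything is generated, nothing
# is read from stored data files.

# a fixed, hand-checkable four-clone table (one non-productive)
fixture_clones <- function() {
  tibble::tibble(
    cdr3_nt = c(
      "TGTGCCAGCAGCTTGGGG", "TGTGCCTGGAGTCGGGGG",
      "TGTGCCAGCTCCCTTTTT", "TGTGCCAGCAGCTAAGGG"
    ),
    cdr3_aa = c("CASSLG", "CAWSRG", "CASSLF", ""),
    v_gene = c("TRBV05-1", "TRBV07-2", "TRBV05-1", "TRBV12-1"),
    d_gene = c("TRBD01-1", NA, "TRBD02-1", NA),
    j_gene = c("TRBJ02-1", "TRBJ01-2", "TRBJ02-3", "TRBJ02-1"),
    count = c(5L, 3L, 1L, 1L),
    productive = c(TRUE, TRUE, TRUE, FALSE)
  )
}

fixture_repertoire <- function(sample_id = "s1", patient_id = "p1",
                               group = "lesional", chain = "TRB",
                               clones = fixture_clones()) {
  repertoire(clones,
    sample_id = sample_id, patient_id = patient_id,
    group = group, chain = chain
  )
}

# repertoire whose nt_vj keys are exactly the given single-letter tags
keyed_repertoire <- function(keys, counts = NULL, sample_id = "s1",
                             patient_id = sample_id, group = "normal",
                             chain = "TRG") {
  counts <- counts %||% base::rep(2L, length(keys))
  repertoire(
    tibble::tibble(
      # one codon per tag, each encoding a different amino acid, so both
      # nt_vj and aa_only keys are distinct across tags
      cdr3_nt = vapply(keys, function(k) {
        paste0(c(a = "GCA", b = "TGC", c = "GAC", d = "GAA",
                 e = "TTC", f = "GGA", g = "CAC", h = "ATC")[[k]],
               "TGTGCAAGC", collapse = "")
      }, character(1)),
      count = counts,
      v_gene = "TRGV01-1", j_gene = "TRGJ01-1", productive = TRUE
    ),
    sample_id = sample_id, patient_id = patient_id,
    group = group, chain = chain
  )
}

# random valid repertoire for property-style tests (uses ambient RNG)
random_repertoire <- function(n = 20, sample_id = "r1", group = "normal",
                              chain = "TRG", patient_id = sample_id) {
  skel <- generate_rearrangement(n, default_gene_segments(chain))
  skel$count <- as.integer(sample(1:50, n, replace = TRUE))
  repertoire(skel,
    sample_id = sample_id, patient_id = patient_id,
    group = group, chain = chain
  )
}

write_immunoseq_fixture <- function(path, rows) {
  readr::write_tsv(rows, path, progress = FALSE)
}

immunoseq_rows <- function() {
  tibble::tibble(
    nucleotide = c("TGTGCCAGCAGCTTGGGG", "TGTGCCTGGAGTCGGGGG", "TGTGCCAGCTCCCTTTTT"),
    aminoAcid = c("CASSLG", "CAWSRG", "CASSLF"),
    count = c(6L, 3L, 1L),
    frequencyCount = c(60, 30, 10),
    vGeneName = c("TCRBV05-01*01", "TCRBV07-02", "TCRBV05-01"),
    dGeneName = c("TCRBD01-01", "unresolved", "TCRBD02-01"),
    jGeneName = c("TCRBJ02-01", "TCRBJ01-02", "TCRBJ02-03"),
    sequenceStatus = c("In", "In", "In")
  )
}

airr_rows <- function() {
  tibble::tibble(
    junction = c("TGTGCCAGCAGCTTGGGG", "TGTGCCTGGAGTCGGGGG", "TGTGCCAGCAGCTAAGGG"),
    junction_aa = c("CASSLG", "CAWSRG", ""),
    duplicate_count = c(4L, 2L, 2L),
    v_call = c("TRBV5-1*01", "TRBV7-2*02,TRBV7-2*03", "TRBV12-1"),
    d_call = c("TRBD1", "", "TRBD2"),
    j_call = c("TRBJ2-1*01", "TRBJ1-2", "TRBJ2-1"),
    productive = c("T", "T", "F")
  )
}

test_metadata <- function(sample_id = "s1", patient_id = "p1",
                          group = "lesional", chain = "TRB") {
  list(
    sample_id = sample_id, patient_id = patient_id,
    group = group, chain = chain
  )
}

# rebuild a repertoire object around modified clone rows, bypassing
# constructor validation (for exercising writer/validator errors)
new_repertoire_for_test <- function(clones, like) {
  tcrep:::new_repertoire(clones, rep_metadata(like))
}

# small, fast cohort configuration for unit tests (not the study scale)
small_config <- function(seed = 1, chain = "TRG", n_public = 0L, ...) {
  cohort_config(
    chain = chain,
    groups = list(
      group_spec("normal", 3L, 60L),
      group_spec("non_lesional", 2L, 80L),
      group_spec("lesional", 3L, 120L)
    ),
    n_public_clones = n_public,
    seed = seed,
    ...
  )
}
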