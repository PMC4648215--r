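test_that("immunoseq clone tables are read with frequencies recomputed from counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_immunoseq_fixture(path, immunoseq_rows())
  rep <- read_clone_table(path, "immunoseq", test_metadata())
  expect_s3_class(rep, "tcr_repertoire")
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$frequency, c(0.6, 0.3, 0.1))
  expect_equal(rep$count, c(6L, 3L, 1L))
  expect_equal(attr(rep, "count_column"), "count")
  # allele suffixes stripped, gene-level calls retained
  expect_equal(rep$v_gene[1], "TCRBV05-01")
  expect_equal(rep_metadata(rep)$group, "lesional")
})

test_that("rows sharing a nucleotide clonotype key are collapsed with counts summed", {
  rows <- immunoseq_rows()[c(1, 1), ]
  rows$count <- c(2L, 3L)
  rows$dGeneName <- c("TCRBD01-01", "TCRBD02-01") # D never enters the key
  path <- withr::local_tempfile(fileext = ".tsv")
  write_immunoseq_fixture(path, rows)
  rep <- read_clone_table(path, "immunoseq", test_metadata())
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$count, 5L)
  expect_equal(rep$frequency, 1.0)
})

test_that("AIRR dialect maps T/F productivity and multi-gene calls as documented", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(airr_rows(), path, progress = FALSE)
  rep <- read_clone_table(path, "airr", test_metadata())
  # expected repertoire built independently of the reader
  expected <- repertoire(
    tibble::tibble(
      cdr3_nt = airr_rows()$junction,
      cdr3_aa = airr_rows()$junction_aa,
      v_gene = c("TRBV5-1", "TRBV7-2", "TRBV12-1"),
      d_gene = c("TRBD1", NA, "TRBD2"),
      j_gene = c("TRBJ2-1", "TRBJ1-2", "TRBJ2-1"),
      count = c(4L, 2L, 2L),
      productive = c(TRUE, TRUE, FALSE)
    ),
    sample_id = "s1", patient_id = "p1", group = "lesional", chain = "TRB"
  )
  expect_equal(rep$productive, c(TRUE, TRUE, FALSE))
  expect_equal(identity_key(rep, "nt_vj"), identity_key(expected, "nt_vj"))
  expect_equal(rep$count, expected$count)
  expect_equal(rep$v_gene, expected$v_gene)
})

test_that("reader errors are specific: missing column, bad count, empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- immunoseq_rows()
  write_immunoseq_fixture(path, rows[, names(rows) != "vGeneName"])
  expect_error(
    read_clone_table(path, "immunoseq", test_metadata()),
    "vGeneName"
  )

  rows2 <- immunoseq_rows()
  rows2$count[2] <- 0L
  write_immunoseq_fixture(path, rows2)
  expect_error(
    read_clone_table(path, "immunoseq", test_metadata()),
    "row 2"
  )

  write_immunoseq_fixture(path, immunoseq_rows()[0, ])
  expect_error(read_clone_table(path, "immunoseq", test_metadata()), "empty")

  expect_error(
    read_clone_table(tempfile(), "immunoseq", test_metadata()),
    "not found"
  )
})

test_that("identity keys ignore D genes, distinguish synonymous nucleotides, and reject empty aa", {
  clones <- tibble::tibble(
    cdr3_nt = c("TGTGCAAGC", "TGTGCAAGC", "TGCGCAAGC"),
    cdr3_aa = c("CAS", "CAS", "CAS"),
    v_gene = "TRBV05-1",
    d_gene = c("TRBD01-1", "TRBD02-1", NA),
    j_gene = "TRBJ02-1",
    count = 1L, frequency = 1 / 3, productive = TRUE
  )
  k <- identity_key(clones, "nt_vj")
  expect_equal(k[1], k[2]) # d_gene excluded by definition
  expect_false(k[1] == k[3]) # synonymous nt differ at nt level
  ka <- identity_key(clones, "aa_only")
  expect_equal(ka[1], ka[3]) # but converge at aa level

  clones$cdr3_aa[1] <- ""
  expect_error(identity_key(clones, "aa_only"), "amino-acid")
})

test_that("productive filtering renormalizes retained frequencies and leaves input intact", {
  rep <- fixture_repertoire() # counts 5/3/1 productive + 1 non-productive
  filt <- filter_productive(rep)
  expect_equal(nrow(filt), 3L)
  expect_equal(filt$frequency, rep$frequency[1:3] / 0.9)
  expect_equal(sum(filt$frequency), 1, tolerance = 1e-12)
  expect_equal(nrow(rep), 4L) # input unmodified

  # identity case: all clones productive
  all_prod <- fixture_repertoire(clones = fixture_clones()[1:3, ])
  filt2 <- filter_productive(all_prod)
  expect_equal(as.data.frame(filt2), as.data.frame(all_prod))

  none <- fixture_clones()[4, ]
  expect_error(
    filter_productive(fixture_repertoire(clones = none)),
    "no productive"
  )
})

test_that("write/read round-trips preserve clonotype keys and counts in both dialects", {
  withr::local_seed(421)
  path <- withr::local_tempfile(fileext = ".tsv")
  for (i in 1:50) {
    dialect <- if (i %% 2 == 0) "immunoseq" else "airr"
    rep <- random_repertoire(n = sample(3:40, 1), chain = "TRB")
    write_clone_table(rep, path, dialect)
    back <- read_clone_table(path, dialect, rep_metadata(rep))
    orig <- sort(paste(identity_key(rep, "nt_vj"), rep$count))
    got <- sort(paste(identity_key(back, "nt_vj"), back$count))
    expect_equal(got, orig)
    expect_equal(sum(back$frequency), 1, tolerance = 1e-6)
  }
})

test_that("reading is idempotent: re-collapsing a collapsed repertoire changes nothing", {
  withr::local_seed(7)
  rep <- random_repertoire(30)
  again <- repertoire(
    tibble::as_tibble(rep),
    sample_id = "r1", patient_id = "r1", group = "normal", chain = "TRG"
  )
  expect_equal(as.data.frame(again), as.data.frame(rep))
})

test_that("writer rejects tab characters inside fields and empty repertoires", {
  rep <- fixture_repertoire()
  bad <- tibble::as_tibble(rep)
  bad$v_gene[1] <- "TRB\tV05"
  bad_rep <- new_repertoire_for_test(bad, rep)
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_clone_table(bad_rep, path, "immunoseq"), "tab")
  expect_error(
    repertoire(fixture_clones()[0, ],
      sample_id = "s", patient_id = "p", group = "normal", chain = "TRB"
    ),
    "at least one clone"
  )
})

test_that("manifest validation enforces the cohort design invariants", {
  man <- tibble::tibble(
    sample_id = c("a", "b"), patient_id = c("p1", "p1"),
    group = c("normal", "lesional"), chain = "TRB",
    source_material = "gDNA", path = "x.tsv"
  )
  expect_error(tcrep:::validate_manifest(man), "share patient_id")

  man2 <- man
  man2$patient_id <- c("p1", "p2")
  expect_silent(tcrep:::validate_manifest(man2))

  man3 <- man2
  man3$sample_id <- c("a", "a")
  expect_error(tcrep:::validate_manifest(man3), "duplicate sample_id")

  man4 <- man2
  man4$group <- c("lesional", "lesional")
  man4$patient_id <- c("p1", "p1")
  expect_error(tcrep:::validate_manifest(man4), "at most once")
})
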