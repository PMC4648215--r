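test_that("overlap scores follow the Jaccard definition on clonotype keys", {
  a <- keyed_repertoire(c("a", "b", "c"), sample_id = "sa")
  b <- keyed_repertoire(c("b", "c", "d"), sample_id = "sb")
  ov <- overlap_score(a, b)
  expect_equal(ov$n_shared, 2L)
  expect_equal(ov$score, 0.5) # 2 shared / 4 in the union

  ident <- overlap_score(a, a)
  expect_equal(ident$score, 1)

  disjoint <- overlap_score(
    keyed_repertoire(c("a", "b"), sample_id = "s1"),
    keyed_repertoire(c("c", "d"), sample_id = "s2")
  )
  expect_equal(disjoint$n_shared, 0L)
  expect_identical(disjoint$score, 0)
})

test_that("alternative normalizations stay bounded and agree at the extremes", {
  a <- keyed_repertoire(c("a", "b", "c"), counts = c(8L, 1L, 1L), sample_id = "sa")
  b <- keyed_repertoire(c("b", "c", "d", "e"), sample_id = "sb")
  for (norm in c("jaccard", "min", "morisita")) {
    s <- overlap_score(a, b, normalization = norm)$score
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(overlap_score(a, a, normalization = norm)$score, 1,
      tolerance = 1e-12
    )
  }
  expect_equal(overlap_score(a, b, normalization = "min")$score, 2 / 3)
})

test_that("overlap is symmetric and rejects chain mismatches", {
  withr::local_seed(55)
  for (i in 1:10) {
    a <- random_repertoire(sample(5:30, 1), sample_id = "x")
    b <- random_repertoire(sample(5:30, 1), sample_id = "y")
    sab <- overlap_score(a, b)
    sba <- overlap_score(b, a)
    expect_equal(sab$score, sba$score)
    expect_equal(sab$n_shared, sba$n_shared)
  }
  trb <- random_repertoire(5, chain = "TRB")
  trg <- random_repertoire(5, chain = "TRG")
  expect_error(overlap_score(trb, trg), "chain")
})

test_that("adding shared clones never lowers the score; private clones never raise it", {
  base_keys <- c("a", "b", "c")
  a <- keyed_repertoire(base_keys, sample_id = "sa")
  b <- keyed_repertoire(c("b", "c", "d"), sample_id = "sb")
  s0 <- overlap_score(a, b)$score
  a_shared <- keyed_repertoire(c(base_keys, "e"), sample_id = "sa")
  b_shared <- keyed_repertoire(c("b", "c", "d", "e"), sample_id = "sb")
  expect_gte(overlap_score(a_shared, b_shared)$score, s0)
  a_priv <- keyed_repertoire(c(base_keys, "f"), sample_id = "sa")
  expect_lte(overlap_score(a_priv, b)$score, s0)
})

test_that("pooled overlaps label comparison groups and exclude within-patient NL-LS pairs", {
  coh <- simulate_cohort(small_config(seed = 2))
  ov <- pool_overlaps(coh, key_mode = "nt_vj")
  n <- nrow(coh$manifest)
  expect_equal(nrow(ov), choose(n, 2))
  # 2 paired patients in the small design
  expect_equal(sum(ov$excluded), 2L)
  expect_true(all(ov$comparison_group[ov$excluded] == "NL-LS"))
  expect_true(all(ov$same_patient[ov$excluded]))
  n_nl <- sum(coh$manifest$group == "non_lesional")
  n_ls <- sum(coh$manifest$group == "lesional")
  pooled <- ov[!ov$excluded, ]
  expect_equal(
    sum(pooled$comparison_group == "NL-LS"), n_nl * n_ls - 2L
  )

  two <- tcrep:::new_cohort(
    coh$repertoires[1:2], coh$manifest[1:2, ]
  )
  expect_equal(nrow(pool_overlaps(two)), 1L)

  normals <- coh$manifest$sample_id[coh$manifest$group == "normal"]
  all_norm <- tcrep:::new_cohort(
    coh$repertoires[normals],
    coh$manifest[coh$manifest$sample_id %in% normals, ]
  )
  ovn <- pool_overlaps(all_norm)
  expect_true(all(ovn$comparison_group == "NN"))
})

test_that("paired comparison partitions the key union into disjoint sets with percent frequencies", {
  nl <- keyed_repertoire(c("a", "b", "c"),
    counts = c(6L, 3L, 1L),
    sample_id = "p1_NL", patient_id = "p1", group = "non_lesional"
  )
  ls <- keyed_repertoire(c("b", "c", "d"),
    counts = c(5L, 4L, 1L),
    sample_id = "p1_LS", patient_id = "p1", group = "lesional"
  )
  pc <- paired_comparison(nl, ls)
  expect_equal(sort(table(pc$status)[c("nl_only", "shared", "ls_only")]),
    sort(c(nl_only = 1L, shared = 2L, ls_only = 1L)),
    ignore_attr = TRUE
  )
  g <- glance(pc)
  expect_equal(g$n_nl_only + g$n_shared, nrow(nl))
  expect_equal(g$n_ls_only + g$n_shared, nrow(ls))
  # frequencies are percent of each sample's templates
  shared <- pc[pc$status == "shared", ]
  expect_equal(sum(pc$freq_nl), 100, tolerance = 1e-9)
  expect_equal(sum(pc$freq_ls), 100, tolerance = 1e-9)
  expect_true(all(shared$freq_nl > 0 & shared$freq_ls > 0))

  disj <- paired_comparison(
    keyed_repertoire(c("a", "b"),
      sample_id = "p2_NL", patient_id = "p2", group = "non_lesional"
    ),
    keyed_repertoire(c("c", "d"),
      sample_id = "p2_LS", patient_id = "p2", group = "lesional"
    )
  )
  expect_equal(sum(disj$status == "shared"), 0L)
  expect_equal(sum(disj$status == "nl_only"), 2L)

  same <- paired_comparison(
    keyed_repertoire(c("a", "b"),
      sample_id = "p3_NL", patient_id = "p3", group = "non_lesional"
    ),
    keyed_repertoire(c("a", "b"),
      sample_id = "p3_LS", patient_id = "p3", group = "lesional"
    )
  )
  expect_true(all(same$status == "shared"))

  expect_error(
    paired_comparison(
      keyed_repertoire("a", sample_id = "x", patient_id = "px"),
      keyed_repertoire("a", sample_id = "y", patient_id = "py")
    ),
    "one patient"
  )
})

test_that("shared clones inherit correlated frequencies in simulated pairs", {
  cfg <- small_config(paired_freq_correlation = 0.9, paired_sharing_rate = 0.5)
  rho_real <- c()
  rho_null <- c()
  for (s in 1:10) {
    pair <- simulate_paired(
      "p",
      group_spec("non_lesional", 1L, 150L, richness_dispersion = 0.1),
      group_spec("lesional", 1L, 200L, richness_dispersion = 0.1),
      cfg,
      seed = 500 + s
    )
    pc <- paired_comparison(pair$nl, pair$ls)
    shared <- pc[pc$status == "shared", ]
    rho_real <- c(
      rho_real, stats::cor(shared$freq_nl, shared$freq_ls, method = "spearman")
    )
    rho_null <- c(
      rho_null,
      stats::cor(shared$freq_nl, sample(shared$freq_ls), method = "spearman")
    )
  }
  expect_gt(mean(rho_real), mean(rho_null) + 0.2)
})

test_that("common clones are the exact multi-sample intersection", {
  one <- keyed_repertoire(c("a", "b", "c"), sample_id = "s1")
  cc1 <- common_clones(list(one), "nt_vj")
  expect_equal(sort(unique(cc1$key)), sort(identity_key(one, "nt_vj")))

  s1 <- keyed_repertoire(c("a", "b"), sample_id = "s1")
  s2 <- keyed_repertoire(c("b", "c"), sample_id = "s2")
  s3 <- keyed_repertoire(c("b", "d"), sample_id = "s3")
  cc <- common_clones(list(s1, s2, s3), "nt_vj")
  expect_equal(dplyr::n_distinct(cc$key), 1L)
  expect_equal(nrow(cc), 3L) # one frequency row per sample

  disj <- common_clones(
    list(
      keyed_repertoire(c("a", "b"), sample_id = "s1"),
      keyed_repertoire(c("c", "d"), sample_id = "s2")
    ), "nt_vj"
  )
  expect_equal(nrow(disj), 0L)

  expect_error(
    common_clones(list(
      random_repertoire(5, chain = "TRB"), random_repertoire(5, chain = "TRG")
    )),
    "single chain"
  )
})
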