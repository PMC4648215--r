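#' Group specification for the cohort generator
#'
#' @param group Tissue group.
#' @param n_samples Number of samples in the group.
#' @param richness_mean Expected number of unique clones per sample
#'   (latent richness before depth subsampling).
#' @param richness_dispersion Lognormal dispersion (sdlog) of per-sample
#'   richness around `richness_mean`.
#' @param depth Total templates drawn per sample. Defaults to ten times
#'   the mean richness, which observes ~99% of latent clones under the
#'   default abundance model.
#' @return A `tcr_group_spec` list.
#' @export
group_spec <- function(group, n_samples, richness_mean,
                       richness_dispersion = 0.3,
                       depth = 10L * richness_mean) {
  group <- match.arg(group, TISSUE_GROUPS)
  stopifnot(
    n_samples >= 1, richness_mean >= 2, richness_dispersion > 0,
    depth >= richness_mean
  )
  structure(
    list(
      group = group, n_samples = as.integer(n_samples),
      richness_mean = as.integer(richness_mean),
      richness_dispersion = richness_dispersion,
      depth = as.integer(depth)
    ),
    class = "tcr_group_spec"
  )
}

#' Default V/J gene-segment alphabets with usage weights
#'
#' Fixed label alphabets per chain with mildly skewed usage weights
#' (proportional to 1/rank), emulating uneven but broad V/J usage.
#'
#' @param chain `"TRB"` or `"TRG"`.
#' @return A list with `v` and `j`, each a named numeric vector of
#'   usage weights summing to 1.
#' @export
default_gene_segments <- function(chain = c("TRB", "TRG")) {
  chain <- match.arg(chain)
  lbl <- function(prefix, n) sprintf("%s%02d-1", prefix, seq_len(n))
  segs <- if (chain == "TRB") {
    list(v = lbl("TRBV", 15L), j = lbl("TRBJ", 10L))
  } else {
    list(v = lbl("TRGV", 9L), j = lbl("TRGJ", 4L))
  }
  lapply(segs, function(labels) {
    w <- 1 / seq_along(labels)
    setNames(w / sum(w), labels)
  })
}

#' Full parameterization of the synthetic cohort generator
#'
#' The defaults reproduce the design and observed statistical structure of
#' a three-group psoriasis skin study: 7 normal, 5 non-lesional and 8
#' lesional samples with 5 patients contributing paired non-lesional and
#' lesional biopsies; group mean richness 2700/3200/10900 unique clones
#' for the beta chain and 397/558/1570 for the gamma chain (an
#' approximately three-fold lesional increase); heavy-tailed clone
#' abundances giving low, group-similar clonality; within-patient clone
#' sharing with rank-correlated frequencies; and, for the gamma chain,
#' three public amino-acid-level clones present in every psoriatic sample.
#'
#' @param chain Receptor chain; picks the chain-specific richness defaults.
#' @param groups List of three [group_spec()] objects, one per tissue group.
#' @param freq_shape Pareto tail exponent of the latent clone-abundance
#'   distribution (smaller = heavier tail = higher clonality).
#' @param paired_sharing_rate Fraction of the smaller paired repertoire's
#'   clones shared between a patient's non-lesional and lesional samples.
#' @param paired_freq_correlation Gaussian-copula correlation of shared
#'   clones' latent frequencies across the paired tissues.
#' @param n_public_clones Number of identical amino-acid-level clones
#'   injected into every psoriatic (non-lesional and lesional) sample.
#' @param public_frequency Injection frequency per public clone.
#' @param gene_segments V/J alphabets with usage weights
#'   ([default_gene_segments()]).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A `tcr_cohort_config` list.
#' @export
cohort_config <- function(chain = c("TRG", "TRB"),
                          groups = NULL,
                          freq_shape = 1.5,
                          paired_sharing_rate = 0.25,
                          paired_freq_correlation = 0.8,
                          n_public_clones = if (chain == "TRG") 3L else 0L,
                          public_frequency = 1e-3,
                          gene_segments = default_gene_segments(chain),
                          seed = NULL) {
  chain <- match.arg(chain)
  if (is.null(groups)) {
    rich <- if (chain == "TRB") {
      c(normal = 2700L, non_lesional = 3200L, lesional = 10900L)
    } else {
      c(normal = 397L, non_lesional = 558L, lesional = 1570L)
    }
    groups <- list(
      group_spec("normal", 7L, rich[["normal"]]),
      group_spec("non_lesional", 5L, rich[["non_lesional"]]),
      group_spec("lesional", 8L, rich[["lesional"]])
    )
  }
  names(groups) <- purrr::map_chr(groups, "group")
  if (!setequal(names(groups), TISSUE_GROUPS) || length(groups) != 3L) {
    abort("cohort_config needs exactly one group_spec per tissue group")
  }
  if (freq_shape <= 0) abort("freq_shape must be positive")
  if (paired_sharing_rate < 0 || paired_sharing_rate > 1) {
    abort("paired_sharing_rate must lie in [0, 1]")
  }
  if (paired_freq_correlation < 0 || paired_freq_correlation > 1) {
    abort("paired_freq_correlation must lie in [0, 1]")
  }
  stopifnot(n_public_clones >= 0, public_frequency > 0)
  structure(
    list(
      chain = chain, groups = groups[TISSUE_GROUPS],
      freq_shape = freq_shape,
      paired_sharing_rate = paired_sharing_rate,
      paired_freq_correlation = paired_freq_correlation,
      n_public_clones = as.integer(n_public_clones),
      public_frequency = public_frequency,
      gene_segments = gene_segments,
      seed = seed
    ),
    class = "tcr_cohort_config"
  )
}

#' Draw a heavy-tailed clone-frequency vector
#'
#' Latent clone abundances are i.i.d. Pareto(1, shape) weights normalized
#' to sum to 1. Small `shape` gives an oligoclonal sample dominated by a
#' few clones; as `shape` grows the vector approaches uniform (clonality
#' near 0).
#'
#' @param n_clones Number of clones.
#' @param shape Pareto tail exponent (> 0).
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @return A numeric vector of `n_clones` positive frequencies summing to 1.
#' @export
sample_clone_frequencies <- function(n_clones, shape, seed = NULL) {
  if (shape <= 0) abort("shape must be positive")
  if (n_clones < 1) abort("n_clones must be >= 1")
  draw <- function() {
    w <- runif(n_clones)^(-1 / shape)
    w / sum(w)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# quantile of Pareto(1, shape) -- used to couple paired frequencies
pareto_quantile <- function(u, shape) (1 - u)^(-1 / shape)

#' Generate random in-frame CDR3 rearrangements
#'
#' Emits unique CDR3 nucleotide sequences built from stop-free codons
#' (lengths uniform over multiples of 3 in 27-54 nt), their translations,
#' and V/J labels sampled by the configured usage weights. A bounded
#' retry loop guarantees nucleotide-key uniqueness within the batch.
#'
#' @param n Number of rearrangements.
#' @param gene_segments V/J alphabets with weights
#'   ([default_gene_segments()]).
#' @param exclude Character vector of CDR3 nucleotide sequences that must
#'   not be emitted (e.g. already present in the sample).
#' @return A tibble with `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`,
#'   `j_gene`, `productive`.
#' @export
generate_rearrangement <- function(n, gene_segments, exclude = character()) {
  stopifnot(n >= 1)
  if (length(gene_segments$v) == 0L || length(gene_segments$j) == 0L ||
    any(gene_segments$v <= 0) || any(gene_segments$j <= 0)) {
    abort("gene-segment alphabets must be non-empty with positive weights")
  }
  gc <- Biostrings::GENETIC_CODE
  sense_codons <- names(gc)[gc != "*"]
  draw_nt <- function(m) {
    n_codons <- sample(9:18, m, replace = TRUE) # 27-54 nt
    out <- character(m)
    for (k in unique(n_codons)) {
      idx <- which(n_codons == k)
      mat <- matrix(
        sample(sense_codons, length(idx) * k, replace = TRUE),
        nrow = length(idx)
      )
      out[idx] <- do.call(paste0, asplit(mat, 2L))
    }
    out
  }
  nt <- character(0)
  for (attempt in 1:25) {
    need <- n - length(nt)
    if (need == 0L) break
    cand <- draw_nt(need)
    cand <- setdiff(unique(cand), c(nt, exclude))
    nt <- c(nt, cand)
  }
  if (length(nt) < n) {
    abort("could not generate enough unique CDR3 sequences (alphabet exhausted)")
  }
  tibble(
    cdr3_nt = nt,
    cdr3_aa = translate_nt(nt),
    v_gene = sample(names(gene_segments$v), n,
      replace = TRUE, prob = gene_segments$v
    ),
    d_gene = NA_character_,
    j_gene = sample(names(gene_segments$j), n,
      replace = TRUE, prob = gene_segments$j
    ),
    productive = TRUE
  )
}

draw_richness <- function(spec) {
  sdlog <- spec$richness_dispersion
  max(2L, as.integer(round(rlnorm(
    1,
    meanlog = log(spec$richness_mean) - sdlog^2 / 2, sdlog = sdlog
  ))))
}

# multinomial depth subsampling of latent frequencies; zero-draw clones drop
observe_counts <- function(skeleton, latent, depth) {
  counts <- rmultinom(1, depth, latent)[, 1]
  keep <- counts > 0L
  clones <- skeleton[keep, , drop = FALSE]
  clones$count <- counts[keep]
  clones
}

#' Simulate one repertoire
#'
#' Draws a latent richness around the group mean, heavy-tailed latent
#' frequencies, and an observed clone table by multinomial sampling of
#' `depth` templates; clones receiving zero draws are dropped, so observed
#' richness is depth-dependent, as in real sequencing.
#'
#' @param spec A [group_spec()].
#' @param config A [cohort_config()].
#' @param sample_id,patient_id Identifiers for the resulting repertoire.
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @return A [repertoire()].
#' @export
simulate_sample <- function(spec, config, sample_id = "sim",
                            patient_id = "sim", seed = NULL) {
  if (spec$depth < 1) abort("depth must be >= 1")
  draw <- function() {
    richness <- draw_richness(spec)
    skeleton <- generate_rearrangement(richness, config$gene_segments)
    latent <- sample_clone_frequencies(richness, config$freq_shape)
    clones <- observe_counts(skeleton, latent, spec$depth)
    repertoire(clones,
      sample_id = sample_id, patient_id = patient_id,
      group = spec$group, chain = config$chain
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a patient's paired non-lesional / lesional repertoires
#'
#' A shared clone pool of size `paired_sharing_rate` times the smaller of
#' the two latent richnesses is given rank-correlated latent frequencies
#' in the two tissues (Gaussian copula with correlation
#' `paired_freq_correlation`, Pareto marginals); remaining clones are
#' private per tissue. Both observed repertoires carry the same
#' `patient_id`, emulating abundant lesional clones that are also abundant
#' in the patient's non-lesional skin.
#'
#' @param patient_id Patient identifier shared by the two outputs.
#' @param nl_spec,ls_spec [group_spec()] for the non-lesional and lesional
#'   samples.
#' @param config A [cohort_config()].
#' @param seed Optional seed.
#' @param sample_depth If `FALSE`, skip multinomial subsampling and return
#'   the latent repertoires (counts proportional to latent frequencies);
#'   used to inspect the generator's latent structure.
#' @return A list with elements `nl` and `ls`, both [repertoire()]s, plus
#'   attribute `shared_keys` (the latent shared clonotype keys).
#' @export
simulate_paired <- function(patient_id, nl_spec, ls_spec, config,
                            seed = NULL, sample_depth = TRUE) {
  draw <- function() {
    nl_rich <- draw_richness(nl_spec)
    ls_rich <- draw_richness(ls_spec)
    n_shared <- round(config$paired_sharing_rate * min(nl_rich, ls_rich))
    if (n_shared > min(nl_rich, ls_rich)) {
      abort("sharing rate demands more shared clones than the smaller repertoire holds")
    }
    pool <- generate_rearrangement(nl_rich + ls_rich - n_shared,
      config$gene_segments
    )
    shared <- pool[seq_len(n_shared), , drop = FALSE]
    nl_priv <- pool[n_shared + seq_len(nl_rich - n_shared), , drop = FALSE]
    ls_priv <- pool[nl_rich + seq_len(ls_rich - n_shared), , drop = FALSE]

    # copula-coupled Pareto weights for the shared pool
    rho <- config$paired_freq_correlation
    z1 <- rnorm(n_shared)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_shared)
    w_nl <- c(
      pareto_quantile(stats::pnorm(z1), config$freq_shape),
      runif(nrow(nl_priv))^(-1 / config$freq_shape)
    )
    w_ls <- c(
      pareto_quantile(stats::pnorm(z2), config$freq_shape),
      runif(nrow(ls_priv))^(-1 / config$freq_shape)
    )
    nl_skel <- bind_rows(shared, nl_priv)
    ls_skel <- bind_rows(shared, ls_priv)
    build <- function(skel, w, spec, suffix) {
      latent <- w / sum(w)
      clones <- if (sample_depth) {
        observe_counts(skel, latent, spec$depth)
      } else {
        skel$count <- pmax(1L, as.integer(round(latent * spec$depth)))
        skel
      }
      repertoire(clones,
        sample_id = paste0(patient_id, suffix), patient_id = patient_id,
        group = spec$group, chain = config$chain
      )
    }
    out <- list(
      nl = build(nl_skel, w_nl, nl_spec, "_NL"),
      ls = build(ls_skel, w_ls, ls_spec, "_LS")
    )
    attr(out, "shared_keys") <- identity_key(shared, "nt_vj")
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# one public clone: fixed aa, per-sample independent synonymous nt
synonymous_nt <- function(aa, exclude = character()) {
  gc <- Biostrings::GENETIC_CODE
  codons_for <- split(names(gc), gc)
  for (attempt in 1:25) {
    nt <- paste(vapply(
      strsplit(aa, "")[[1]],
      function(a) sample(codons_for[[a]], 1L)[[1]],
      character(1)
    ), collapse = "")
    if (!nt %in% exclude) return(nt)
  }
  abort("could not draw a fresh synonymous nucleotide sequence")
}

inject_public <- function(rep, public, config) {
  depth <- sum(rep$count)
  add_count <- max(1L, as.integer(round(config$public_frequency * depth)))
  rows <- purrr::map_dfr(seq_len(nrow(public)), function(i) {
    tibble(
      cdr3_nt = synonymous_nt(public$cdr3_aa[i], exclude = rep$cdr3_nt),
      cdr3_aa = public$cdr3_aa[i],
      v_gene = public$v_gene[i],
      d_gene = NA_character_,
      j_gene = public$j_gene[i],
      count = add_count,
      productive = TRUE
    )
  })
  clones <- bind_rows(as_tibble(rep)[names(rep) != "frequency"], rows)
  clones$frequency <- clones$count / sum(clones$count)
  out <- new_repertoire(clones, rep_metadata(rep))
  validate_repertoire(out)
  out
}

#' Simulate a whole study cohort
#'
#' Generates normal samples from unpaired healthy-control patients,
#' paired non-lesional/lesional samples via [simulate_paired()] for the
#' first `min(n_NL, n_LS)` psoriatic patients, unpaired lesional samples
#' for the remainder, and injects `n_public_clones` amino-acid-level
#' public clones (independently drawn synonymous nucleotide sequences per
#' sample, at low frequency with counts renormalized) into every
#' psoriatic sample and no normal sample. Bit-reproducible given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `tcr_cohort` (see [cohort()]); the generator's public-clone
#'   amino-acid sequences are attached as attribute `public_clones`.
#' @export
simulate_cohort <- function(config) {
  draw <- function() {
    gs <- config$groups
    n_paired <- min(gs$non_lesional$n_samples, gs$lesional$n_samples)
    reps <- list()
    for (i in seq_len(gs$normal$n_samples)) {
      pid <- sprintf("HC%d", i)
      sid <- sprintf("%s_N_%s", pid, config$chain)
      reps[[sid]] <- simulate_sample(gs$normal, config,
        sample_id = sid, patient_id = pid
      )
    }
    for (i in seq_len(n_paired)) {
      pid <- sprintf("PS%d", i)
      pair <- simulate_paired(pid, gs$non_lesional, gs$lesional, config)
      reps[[rep_metadata(pair$nl)$sample_id]] <- pair$nl
      reps[[rep_metadata(pair$ls)$sample_id]] <- pair$ls
    }
    for (i in seq_len(gs$non_lesional$n_samples - n_paired)) {
      pid <- sprintf("PS%d", n_paired + i)
      sid <- paste0(pid, "_NL")
      reps[[sid]] <- simulate_sample(gs$non_lesional, config,
        sample_id = sid, patient_id = pid
      )
    }
    extra_ls <- gs$lesional$n_samples -
      n_paired - max(0L, gs$non_lesional$n_samples - n_paired)
    n_ps <- max(gs$non_lesional$n_samples, n_paired)
    for (i in seq_len(max(0L, gs$lesional$n_samples - n_paired))) {
      pid <- sprintf("PS%d", n_ps + i)
      sid <- paste0(pid, "_LS")
      reps[[sid]] <- simulate_sample(gs$lesional, config,
        sample_id = sid, patient_id = pid
      )
    }
    public <- NULL
    if (config$n_public_clones > 0L) {
      public <- generate_rearrangement(
        config$n_public_clones, config$gene_segments
      )
      psoriatic <- purrr::map_lgl(
        reps, ~ rep_metadata(.x)$group != "normal"
      )
      reps[psoriatic] <- purrr::map(
        reps[psoriatic], inject_public,
        public = public, config = config
      )
    }
    out <- cohort(reps)
    attr(out, "public_clones") <- public
    out
  }
  if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: [simulate_cohort()] followed by [write_cohort()],
#' producing per-sample clone tables plus a manifest that
#' [run_pipeline()] accepts.
#'
#' @inheritParams simulate_cohort
#' @inheritParams write_cohort
#' @return The manifest path, invisibly.
#' @export
simulate_cohort_files <- function(config, dir,
                                  dialect = c("immunoseq", "airr")) {
  write_cohort(simulate_cohort(config), dir, dialect)
}
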