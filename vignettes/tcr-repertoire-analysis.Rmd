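---
title: "Skin TCR repertoire analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin TCR repertoire analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrep)
library(dplyr)
```

This vignette is the package's account of the science it implements: the
statistics, the identity conventions, the synthetic cohort model and what
it does and does not emulate, and the design decisions taken where the
methodology admitted more than one reasonable reading.

## The analysis problem

Deep sequencing of the TCR CDR3 region turns a skin biopsy into a clone
table: one row per unique rearrangement with an abundance (template or
read count). Comparing psoriatic lesional, psoriatic non-lesional, and
normal skin then reduces to a handful of repertoire statistics computed
per sample and compared across groups:

* **richness** — the number of unique clonotypes, a proxy for how many
  distinct T-cell lineages infiltrate the tissue;
* **clonality** — how unevenly abundance is distributed across those
  lineages, separating "more T cells" from "expansion of a few clones";
* **overlap** — how much sequence is shared between samples, within a
  patient (non-lesional vs lesional) and across patients (public
  clones).

## Diversity statistics

With clone frequencies $P_i$ over $N$ unique clones,

$$H = -\sum_{i=1}^{N} P_i \log_2 P_i, \qquad
  H_N = \frac{H}{H_{max}}, \quad H_{max} = \log_2 N, \qquad
  C = 1 - H_N.$$

Entropy is depth-sensitive (sample size drives the number of observed
unique sequences), which is why the group comparison of evenness uses the
normalized form. Numerical conventions:

* frequencies must be strictly positive and sum to 1 within $10^{-6}$;
  zero-count clones are dropped upstream (at read or subsampling time),
  never passed in as zeros;
* a single-entry vector has entropy exactly 0 (returned as a constant,
  not computed, to avoid `0 * log(0)`);
* for $N = 1$, $H_{max} = 0$ leaves $H_N$ undefined; clonality is
  defined as 1, the continuous limit of maximal concentration and the
  natural boundary reading ("a single sequence makes up the entire
  sample");
* entropy uses observed frequencies as-is — no Chao/ACE-style coverage
  correction, matching the formula as conventionally applied to these
  data. Unique-count comparisons are likewise raw; sequencing depth is
  carried in the diversity table (`total_count`) so a reader can judge
  depth balance.

Statistics are computed on productive clones by default (out-of-frame or
stop-containing rearrangements are dropped and frequencies renormalized),
since group comparisons of functional repertoires are conventionally
reported on productive unique sequences; every entry point takes
`productive_only = FALSE` to retain all frames.

## Clonotype identity

Clone tables do not come with a universal definition of "the same clone".
The package provides two keys and uses each where it is the meaningful
unit:

* `nt_vj` — CDR3 nucleotide sequence + V gene + J gene (D excluded,
  allele suffixes stripped, first gene of ambiguous calls taken). This
  is the vendor-style clonotype definition; it is the default for
  within-cohort counting and within-patient paired comparisons, where
  the same physical rearrangement is being tracked.
* `aa_only` — CDR3 amino-acid sequence alone. Across patients, identical
  nucleotide rearrangements are rare, but convergent recombination can
  produce the same amino-acid junction from different nucleotide
  sequences; amino-acid identity is therefore the default for public
  clone detection, and for the pooled overlap stage of the pipeline,
  whose comparisons are predominantly cross-patient.

Both defaults are package choices, not claims about how any particular
published analysis keyed its clones; every function takes `key_mode`.

## Overlap scoring and pooling

The pairwise score is the Jaccard index on unique clonotype keys
($|A \cap B| / |A \cup B|$): symmetric, bounded in $[0,1]$, zero exactly
when nothing is shared, and the most direct reading of "fraction of
shared sequences normalized to the total number of sequences". Two
alternatives are exposed (`shared/min`, and abundance-weighted
Morisita–Horn) because the normalization choice is genuinely open;
presence/absence Jaccard is the default because the quantity being
compared across groups is sequence sharing, not abundance agreement.

All $\binom{n}{2}$ pairs are labelled by tissue pair (NN, N-NL, N-LS,
NL-NL, NL-LS, LS-LS). Pairs that compare a patient's own non-lesional
and lesional samples are flagged `excluded` and dropped from pooled
summaries and tests: within-patient sharing is systematically high and
would artificially inflate the NL-LS group, which is meant to measure
*between-patient* sharing. With 5 non-lesional and 8 lesional samples
and 5 paired patients this leaves $5 \times 8 - 5 = 35$ pooled NL-LS
records out of 190 total pairs.

## Group inference

Exactly the classical scheme such studies report: group means with SEM
($s/\sqrt{n}$) error bars; two-tailed unpaired pooled-variance Student's
t-tests for pairwise group differences (Welch available as an option but
not the default, since "unpaired Student's t-test" names the
equal-variance test); one-way fixed-effects ANOVA across the six pooled
overlap groups followed by raw pairwise t-tests. No multiple-testing
correction is applied — p-values are reported raw, and the number of
tests is visible as the number of rows returned — matching the reporting
convention of small-cohort repertoire studies. A post-hoc procedure
(e.g. Tukey) would be the textbook follow-up to the ANOVA; the package
reports raw pairwise t-tests instead and leaves the choice visible to
the analyst.

Degenerate inputs follow documented conventions rather than erroring:
identical constant groups give $p = 1$ with a `degenerate` flag
(simulated edge cases must not abort a pipeline); constant groups with
different means give $p = 0$ (the diverging-statistic limit). The t-test
and ANOVA implementations delegate to `stats::t.test(var.equal = TRUE)`
and `stats::oneway.test(var.equal = TRUE)`; the test suite cross-checks
the ANOVA against an independent hand-written sum-of-squares
decomposition and verifies the two-group identity $F = t^2$.

## The synthetic cohort generator

The generator exists so that every downstream stage has a realistic,
fully reproducible test surface. Its defaults *are* the emulated study
conditions; they are fixed once here and not tuned per analysis.

**Design.** 7 normal samples from unpaired healthy controls; 5 psoriatic
patients contributing paired non-lesional + lesional biopsies; 3 further
lesional-only patients (totals 7/5/8). Group mean richness follows the
emulated study's observed means: 2700/3200/10900 unique clones
(normal/non-lesional/lesional) for the β chain, 397/558/1570 for the γ
chain — an approximately three-fold lesional increase.

**Abundance model.** Latent clone frequencies are i.i.d. Pareto(1,
`freq_shape`) weights normalized to sum to 1 — the simplest
one-parameter heavy-tailed family spanning polyclonal to oligoclonal.
The default `freq_shape = 1.5` yields mean clonality ≈ 0.10 with
group-to-group differences well under 0.05 across the study's richness
range, i.e. "larger but not more clonal", the structure the statistics
must resolve. Because normalized entropy depends weakly on $N$,
clonality is only *exactly* group-equal when group specifications are
identical; that identical-spec configuration is what the null-calibration
tests use.

**Observation model.** Per sample, latent richness is drawn lognormally
around the group mean (`richness_dispersion = 0.3` sdlog, chosen as a
realistic between-biopsy coefficient of variation of ~30%; the emulated
study reports no within-group variances, so this is a stability choice,
not a measured one). Observed counts are a single multinomial draw of
`depth` templates from the latent frequencies, and zero-draw clones are
dropped — so observed richness is depth-dependent, as in real
sequencing, where sample size drives unique-sequence counts. The default
`depth = 10 × richness_mean` observes ~99% of latent clones, so
configured richness ratios survive subsampling.

**Paired structure.** A patient's non-lesional and lesional samples
share a clone pool of size `paired_sharing_rate` × the smaller latent
richness (default 0.25). Defining the pool against the smaller
repertoire keeps any rate in $[0,1]$ feasible for every richness draw;
defining it against the lesional richness alone would make the generator
fail stochastically whenever a low non-lesional draw met a high lesional
draw. Shared clones receive rank-correlated latent frequencies via a
Gaussian copula with Pareto marginals (`paired_freq_correlation = 0.8`),
so the most abundant lesional clones tend to be the most abundant
non-lesional clones; multinomial subsampling attenuates the observed
rank correlation below the latent value, which the tests account for by
checking against a permuted-pairing baseline.

**Public clones.** `n_public_clones` (default 3 for the γ chain, 0 for
β) amino-acid sequences are drawn once per cohort and injected into
every psoriatic sample — with an *independently drawn synonymous
nucleotide sequence per sample* — at frequency `public_frequency`
(default $10^{-3}$, counts renormalized). Sharing is therefore high at
the amino-acid level and incidental at the nucleotide level, the
structure that makes γ-chain public-clone detection meaningful.
CDR3 lengths are uniform over multiples of 3 in 27–54 nt, built from
stop-free codons (all simulated clones are productive; non-productive
records are exercised by hand-built fixtures instead).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: V(D)J recombination biology (no insertion/
deletion machinery, no CDR3 length–gene dependence, no thymic selection),
PCR/sequencing error and the vendor's error-clustering, primer bias,
template-count calibration, between-sample depth imbalance, and any real
covariance between richness and clonality. Tests against synthetic
cohorts validate the *pipeline's statistics*, not biological claims.

## Pipeline determinism and problem sizes

All randomness funnels through the seed in `cohort_config()`;
whole-cohort generation is bit-reproducible, and `run_pipeline()` on
identical inputs writes byte-identical reports (JSON with stable key
order, no timestamps; input files identified by checksum in the
provenance block). The test suite runs its distributional checks on
study-scale γ-chain cohorts (20 samples, ~2,700 latent clones per
cohort; 50–100 seeds per property) and uses reduced designs
(~60–200 clones per sample) for unit-level properties; β-scale cohorts
(~87,000 lesional clones per cohort) are exercised for correctness but
not looped over seeds.

## Known limitations

* The overlap score operates on unique clonotype presence; an
  abundance-weighted pooled analysis (beyond the Morisita–Horn option on
  single pairs) is out of scope.
* No rarefaction or richness extrapolation: unique counts are compared
  raw, so strongly depth-imbalanced real cohorts need depth inspection
  before trusting richness comparisons.
* The γ-chain public-clone model treats publicness as an injected binary
  property; real convergent recombination produces graded sharing
  correlated with CDR3 length and gene usage.
* Inference is limited to the classical t/ANOVA scheme with raw
  p-values; nonparametric alternatives and mixed models are deliberately
  absent.
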