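# tcrep

Analysis of T-cell receptor (TCR) CDR3 clonotype repertoires from skin
biopsies, for immunologists comparing diseased and healthy tissue — the
setting is a psoriasis cohort with three tissue groups (normal skin from
healthy volunteers, and paired non-lesional and lesional skin from
psoriasis patients), with the β chain sequenced from genomic DNA and the
γ chain from cDNA. The package answers the questions such a study asks:
Is lesional skin richer in unique clonotypes? Is it more clonal, or still
polyclonal? Do patients share sequences with each other more than healthy
controls do? Are a patient's expanded lesional clones already present in
their non-lesional skin?

## What it computes

For a clone table with frequencies *P<sub>i</sub>* over *N* unique
clonotypes:

- **Shannon entropy** *H* = −Σ<sub>i</sub> *P<sub>i</sub>* log₂ *P<sub>i</sub>*
  (bits), with *H*<sub>max</sub> = log₂ *N*;
- **clonality** *C* = 1 − *H*/*H*<sub>max</sub>, 0 for a perfectly even
  (polyclonal) repertoire, 1 for a monoclonal one; a singleton repertoire
  (*N* = 1) is defined as *C* = 1;
- **overlap score** between two samples: Jaccard index on unique
  clonotype keys, |A ∩ B| / |A ∪ B| (shared/min and Morisita–Horn
  offered as alternatives), pooled into comparison groups (NN, N-NL,
  N-LS, NL-NL, NL-LS, LS-LS) with within-patient NL–LS pairs excluded so
  self-sharing does not inflate the NL-LS group;
- **paired-tissue comparison**: partition of a patient's clonotypes into
  non-lesional–only / shared / lesional-only with percent-of-templates
  frequencies;
- **public clones**: clonotypes present in *every* sample of a scope
  (e.g. all lesional samples), keyed at the amino-acid level where
  convergent recombination makes cross-patient sharing meaningful;
- **group inference**: unpaired pooled-variance Student's t-tests and
  one-way ANOVA, group means with SEM, raw p-values at α = 0.05.

Clonotype identity is configurable: `nt_vj` (CDR3 nucleotide + V + J
gene, the vendor-style definition, used within patients) or `aa_only`
(CDR3 amino acid, used across patients). Two clone-table dialects are
read and written: immunoSEQ export and AIRR Rearrangement TSV.

A seeded synthetic cohort generator (`simulate_cohort()`) emulates the
study's statistical structure — group sizes 7/5/8 with 5 paired patients,
heavy-tailed clone abundances, ~3-fold lesional richness at similar
clonality, rank-correlated paired frequencies, and injected γ-chain
public clones — so the whole pipeline is testable end-to-end without any
sequencing download.

## Worked example

```r
library(tcrep)

cfg <- cohort_config("TRG", seed = 7)   # study-scale gamma-chain cohort
coh <- simulate_cohort(cfg)
report <- run_pipeline(coh)
report
#> # TCR analysis report: 20 TRG samples
#> # diversity rows: 20; pooled overlap records: 185 (5 excluded); paired patients: 5
#> # public clones: 3 in all lesional, 3 in all psoriatic samples

library(dplyr)
report$diversity |>
  group_by(group) |>
  summarise(mean_unique = mean(n_unique), mean_clonality = mean(clonality))
#>   group        mean_unique mean_clonality
#> 1 lesional           1508.         0.103
#> 2 non_lesional        566          0.0974
#> 3 normal              469.         0.205

tidy(report) |> select(metric, comparison, p_value, significant) |> head(6)
#>   metric       comparison                  p_value significant
#> 1 unique_count normal vs non_lesional    0.316     FALSE
#> 2 unique_count normal vs lesional        0.0000181 TRUE
#> 3 unique_count non_lesional vs lesional  0.000249  TRUE
#> 4 clonality    normal vs non_lesional    0.302     FALSE
#> 5 clonality    normal vs lesional        0.213     FALSE
#> 6 clonality    non_lesional vs lesional  0.779     FALSE
```

Reading: lesional skin holds roughly three times as many unique γ-chain
clonotypes as normal skin (significant at study sample sizes), while
clonality does not differ — the lesional infiltrate is larger but just as
polyclonal. `glance(report$paired$PS1)` gives one patient's
non-lesional-only / shared / lesional-only clone counts, and
`autoplot(report$paired$PS1)` draws the paired frequency scatter;
`plot_overlap_groups(report$overlaps)` shows the elevated psoriatic
γ-chain sharing driven by the public clones.

Real data go through the same path: a manifest TSV (`sample_id`,
`patient_id`, `group`, `chain`, `source_material`, `path`) plus one clone
table per sample, then `run_pipeline("manifest.tsv", dialect = "immunoseq",
out_dir = "results")`.

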