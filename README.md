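# rbpcoex

Interaction propensity and tissue co-expression analysis for
RNA-binding proteins (RBPs).

RBPs regulate their target mRNAs post-transcriptionally, and that
regulation leaves a footprint in expression data: stabilizing RBPs tend
to be **co-expressed** with their targets across tissues, repressive
RBPs **anti-expressed**. `rbpcoex` integrates a predicted protein ×
transcript interaction-propensity matrix (an upstream input — e.g. a
catRAPID-style score table) with protein and transcript expression
profiles over a shared tissue panel, and provides the statistics to ask
whether predicted interactions and expression correlation go together,
which biological processes are specific to each interaction/expression
class, whether predictions agree with knock-down experiments, and
whether intrinsically disordered regions promote RNA binding.

## The statistics at the core

Pairs are ranked by interaction score and equal-sized *interacting* /
*non-interacting* sets are selected at a percentile ("AUC") of the
score distribution: the top and bottom ⌊N(100−a)/100⌋ pairs. With
n<sub>int</sub>[·] and n<sub>no-int</sub>[·] counting qualifying pairs
in the two tails, the enrichment in co-expressed interactions at a
positive correlation threshold r<sub>th</sub> is

    E_co = ( n_int[r > r_th] − n_no-int[r > r_th] ) / n_no-int[r > r_th]

and the anti-expressed version uses r < l<sub>th</sub> < 0. Pairs are
classified at AUC 95 with correlation cuts ±0.7 into IC
(interacting/co-expressed), IA (interacting/anti-expressed) and their
non-interacting counterparts NIC/NIA. Per subset, gene-ontology terms
are tested with a conditional hypergeometric procedure (children before
parents; genes explained by significant descendants removed) and
accepted only under five criteria: ≥3 subset genes; significant
(p < 0.05) in the focal subset and non-significant (p > 0.1) in the
other three; significant against the transcriptome, the analyzed set
and the same-AUC universes; clean length-bias controls (p > 0.1); and
conserved after 80%-identity redundancy reduction. A validation battery
(top-1% Fisher, balanced bootstrap, Welch t, Kolmogorov–Smirnov on
knock-down log-fold changes, ROC/PR) and a disorder-contribution
analysis (regions with per-residue disorder score > 0.4, one-sided
Mann–Whitney region vs full-length) complete the pipeline. A
synthetic-data module generates all inputs with planted ground truth.

See `vignettes/rbpcoex-methods.Rmd` for the full model description.

## Worked example

Everything below runs on the package's synthetic cohort (200 proteins ×
2,000 transcripts, 14 tissues, ~400 planted co-expressed and ~400
anti-expressed interacting pairs):

```r
library(rbpcoex)
library(dplyr)

fix <- simulate_dataset(synthetic_config(seed = 1))

# dataset-construction filters: 50-1200 nt window + expressed in >= 1 tissue
keep_tx <- intersect(filter_length(fix$transcript_lengths, rna_window())$id,
                     filter_expressed(fix$transcripts)$id)
tx_f     <- filter(fix$transcripts, id %in% keep_tx)
scores_f <- filter(fix$scores, transcript %in% keep_tx)

corr <- correlate_pairs(fix$proteins, tx_f)   # per-tissue Z-norm + Pearson

# co-expression enrichment concentrates in the extreme score tail
enrichment_coexpressed(select_tails(scores_f, 50), corr, r_th = 0.7)
#> [1] 0.6144279
enrichment_coexpressed(select_tails(scores_f, 95), corr, r_th = 0.7)
#> [1] 5.641026

cls <- classify_pairs(scores_f, corr, auc = 95, r_cut = 0.7, l_cut = -0.7)
glance(cls)
#> # A tibble: 1 × 8
#>   n_pairs  n_ic  n_ia n_nic n_nia   auc r_cut l_cut
#>     <int> <int> <int> <int> <int> <dbl> <dbl> <dbl>
#> 1  308400   259   246    39    50    95   0.7  -0.7
```

At AUC 50 the interacting tail holds a mild excess of strongly
co-expressed pairs (+61%); at AUC 95 the excess is 5.6-fold — the
planted structure concentrates where scores are extreme. Classification
recovers ~260 IC and ~250 IA pairs (planted: ~320/~310 after
filtering), with small NIC/NIA background sets.

```r
in_tail <- unique(cls$transcript[!is.na(cls$tail_set)])
uni <- gene_universes(
  transcriptome     = fix$transcript_lengths$id,
  analyzed          = keep_tx,
  auc_subset        = intersect(in_tail, keep_tx),
  length_restricted = filter_length(fix$transcript_lengths, rna_window())$id)

gr <- run_go_analysis(cls, fix$go_set$go, uni,
                      identities = fix$identities,
                      lengths    = fix$transcript_lengths)
glance(gr)
#> # A tibble: 4 × 4
#>   subset n_terms n_pass     min_p
#>   <chr>    <int>  <int>     <dbl>
#> 1 IA          21      1 1.02e- 92
#> 2 IC          21      1 5.66e-100
#> 3 NIA         21      0 1.52e-  1
#> 4 NIC         21      0 5.14e-  1
```

Exactly one term passes all five criteria per interacting subset — the
planted IC and IA terms (`fix$go_set$ic_term`, `fix$go_set$ia_term`);
the non-interacting subsets yield nothing. `tidy(gr)` exposes every
component p-value and criterion flag per (term, subset).

The whole pipeline, from TSV/OBO inputs to TSV/JSON reports with a
manifest, runs with:

```r
simulate_dataset(synthetic_config(seed = 1), dir = "fixtures")
run_pipeline("fixtures", "out", run_config(seed = 1))
```

`autoplot()` methods exist for enrichment sweeps, classifications,
ROC/PR bundles and disorder-fraction summaries; `tidy()`/`glance()`
for classifications, sweeps, GO results and bootstrap results.

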