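---
title: "Methods: interaction propensity and tissue co-expression for RNA-binding proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction propensity and tissue co-expression for RNA-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

RNA-binding proteins (RBPs) regulate their target mRNAs
post-transcriptionally, and regulation leaves a footprint in expression:
a stabilizing RBP tends to be co-expressed with its targets across
tissues, a repressive RBP anti-expressed. `rbpcoex` quantifies that
footprint. Starting from a real-valued protein x transcript
interaction-propensity matrix (produced upstream by a sequence-based
predictor; consumed here, never computed), and protein and transcript
expression profiles over a shared tissue panel, the package (i) selects
equal-sized sets of putatively interacting and non-interacting pairs at
a percentile of the score distribution, (ii) measures how strongly
co-expressed and anti-expressed pairs are enriched among predicted
interactions, (iii) classifies pairs into four subsets (IC, IA, NIC,
NIA) and asks which gene-ontology terms are specifically
over-represented in each under a five-criteria acceptance rule, (iv)
validates predicted targets against knock-down experiments, and (v)
asks whether intrinsically disordered protein regions promote RNA
association at low interaction propensities.

## Core statistics

**Tail selection.** "AUC" here is a percentile of the empirical score
distribution, not a classifier ROC area. At percentile $a$, the
interacting set is the top $\lfloor N (100 - a)/100 \rfloor$ pairs and
the non-interacting set the bottom ones, so both sets always have equal
size. Ties at either cut are broken lexicographically by
(protein, transcript) id, which makes selection deterministic across
platforms. At the published cohort scale (35,818 transcripts x 1,156
proteins) the tail sizes are 20,702,804 pairs at $a = 50$ and 2,070,280
at $a = 95$.

**Enrichment.** With $n_\mathrm{int}[\cdot]$ and
$n_\mathrm{no\text{-}int}[\cdot]$ counting qualifying pairs in the two
tails, the co-expression enrichment at a positive correlation threshold
$r_{th}$ is

$$
E_\mathrm{co}
  = \frac{n_\mathrm{int}[r > r_{th}] - n_\mathrm{no\text{-}int}[r > r_{th}]}
         {n_\mathrm{no\text{-}int}[r > r_{th}]},
$$

and the anti-expression enrichment replaces the condition by
$r < l_{th}$ with $l_{th} < 0$. The statistic is bounded below by $-1$;
a zero denominator makes the point undefined and it is omitted from
curves rather than forced to a value. Pairs whose correlation is
undefined (a constant profile) are removed, and both tails are then
re-trimmed to the common size by dropping the least-extreme scores, so
the equal-size contract survives the removal deterministically. The
score-sign variant of the statistic (requiring positive scores in the
interacting tail and negative in the other) is available behind the
`require_sign` flag; the default uses pure tail membership.

**Expression encoding and correlation.** Immunohistochemistry calls
no/low/intermediate/high map to 0/1/2/3. Each tissue column is then
Z-normalized with the population (divide-by-$n$) standard deviation —
the tissue panel is the entire universe of the study, not a sample from
a larger one; a `population_sd = FALSE` switch gives the $n-1$ variant.
Constant columns map to zeros and are reported. Pearson correlations
are computed between every protein profile and every transcript profile
over the shared panel. Because per-tissue Z-normalization is
idempotent, `correlate_pairs()` (which normalizes internally unless the
input is flagged as normalized) returns identical correlations whether
or not matrices were pre-normalized; note this is a statement about the
pipeline's idempotence, not about Pearson's invariance under column-wise
standardization, which does not hold in general. Pairs with a constant
profile get an undefined correlation and are excluded from enrichment
counts rather than set to 0, which would dilute the statistics with
artefacts.

**Classification.** At the default percentile of 95 and correlation
cuts of +0.7 / -0.7, IC pairs sit in the interacting tail with positive
score and $r \ge 0.7$, IA with $r \le -0.7$; NIC/NIA mirror them in the
non-interacting tail with negative scores. The score-sign condition is
part of the subset definitions (interacting subsets require positive
propensities), so tail pairs violating it stay unclassified. The |0.7|
cut corresponds, on the real cohort, to the 95th percentile of the |r|
distribution; `correlation_percentile()` exposes that consistency
check.

**Conditional GO over-representation.** Each subset's transcripts are
tested per term with an upper-tail hypergeometric test, conditioned on
the ontology: terms are processed children before parents within each
namespace, and genes annotated to an already-significant descendant
(child significance 0.05, the same level as the acceptance rule's
significance threshold) are removed from both the parent's sample and
universe counts. A term then passes for a subset only if all five hold:

1. annotated to strictly more than 2 genes of the subset (i.e. at least 3);
2. significant ($p < 0.05$) in the focal subset and non-significant
   ($p > 0.1$) in the other three subsets at the same percentile;
3. significant against all three nested universes — the full
   transcriptome, the analyzed (length- and expression-filtered) set,
   and all genes under the same percentile (both tails pooled);
4. non-significant ($p > 0.1$) in both bias controls: the analyzed set
   against the transcriptome, and the length-restricted set against the
   transcriptome (a term enriched merely among transcripts passing the
   50–1,200 nt window would otherwise masquerade as biology);
5. still significant after reducing the gene sets to 80%-identity
   representatives.

The focal p-value backing criteria 2 and the reported
Benjamini–Hochberg column is the conditional test against the analyzed
universe; criterion 3 additionally demands significance against the
other two universes. The procedure reports raw p-values gated by these
criteria — no multiple-testing correction is applied inside the rule,
which follows the original design; the BH column is informational.
Where "the others" could mean other subsets at any percentile, the rule
is evaluated within one percentile at a time.

**Validation battery.** For a protein with experimentally bound targets
(e.g. from PAR-CLIP) and a knock-down expression experiment, the
package cross-tabulates the top 1% of predicted scores against the
bound/unbound label (two-sided Fisher; exactly
$\lfloor N \cdot f \rfloor$ pairs in the slice, ties broken by id),
repeats the test under balanced bootstrap resampling of the negatives,
compares score distributions with a two-sample t-test (Welch by
default — the variance assumption is not stated in the source
procedure, and the pooled variant sits behind a flag), tests the
knock-down log-fold-change shift of targets with a two-sample
Kolmogorov–Smirnov test, reports the percentage of top-ranked
transcripts with positive LFC under both predicted and experimental
rankings, and draws ROC/precision-recall curves at several
class-imbalance ratios (negatives subsampled, seeded). All tests are
two-sided except where noted. The balanced bootstrap is granular by
construction: a top-1% slice of a balanced subsample with a few hundred
rows holds only a handful of pairs, so its p-values are floored well
above those of the full-cohort test; the bootstrap is a robustness
check, not a power improvement.

**Disorder contribution.** Disordered regions are maximal runs of
residues with disorder score strictly above 0.4; runs shorter than
`min_len` (default 50 residues, matching the lower bound of the protein
analysis window so that regions are themselves scoreable) are
discarded. Per protein, region-vs-full-length interaction scores over a
common transcript set are compared with a one-sided Mann–Whitney U test
(region greater); the test is one-sided because the question is
directional. The per-protein promoting calls are then binned by mean
full-length propensity and summarized separately for proteins with and
without canonical RNA-binding domains; empty bins are absent from the
output, never reported as zero. Whether the original analysis ran the
test per protein or per bin is not fully explicit; it is run per
protein here, with the per-bin aggregate reported alongside.

**Dataset construction.** Transcripts outside 50–1,200 nt, proteins
outside 50–750 aa, and entities not expressed (raw value > 0) in at
least one tissue are excluded before analysis. Redundancy reduction
reproduces the greedy longest-first cluster-representative rule over a
*supplied* pairwise identity table (ties in length broken
lexicographically; absent pairs count as identity 0, matching tools
that only report above-threshold matches); no alignment is computed.
The protein dataset uses a 75% identity cutoff at construction; the
80–95% range used for robustness scans is the same parametric
operation. Profiles for novel sequences can be transferred by homology:
among the ten top-ranked hits, candidates need e-value at most 0.01 and
whole-sequence similarity at least 75% (proteins) or 95% (transcripts),
and the best-ranked candidate wins. Whether the original rule averaged
the ten profiles or took the best hit is not stated; best-hit is used
because it is deterministic and auditable, and all candidates are kept
as provenance.

## What the synthetic cohort emulates

`simulate_dataset()` generates every input the pipeline consumes, with
planted ground truth for recovery testing. The default cohort is
desk-scale: 200 proteins x 2,000 transcripts over 14 tissues (the
tissue count of the human atlas setting; the published cohort's
1,156 x 35,818 adds nothing for testing the machinery).

- *Expression.* Background profiles are independent standard normals
  per tissue. Each planted pair shares a latent tissue factor with
  loading $\sqrt{\rho}$ on both sides, giving population correlation
  $+\rho$ (IC) or $-\rho$ (IA) in closed form; the default
  $\rho = 0.8$ places planted pairs well beyond the |0.7| cut while
  leaving sampling noise visible at 14 tissues. Abundances are the
  affine map $10 + 2z$ of the latent profiles, which preserves all
  pairwise correlations exactly and keeps values positive. One percent
  of background transcripts are zeroed across all tissues so the
  expression filter has work to do. Ordinal matrices are per-tissue
  quartile binnings of the continuous abundances — the simplest noise
  model for qualitative staining calls.
- *Scores.* Standard-normal background; planted pairs shifted by 3
  SDs, which puts >95% of them in the top decile (normal-tail
  arithmetic) and nearly all in the top-5% tail used for
  classification. 0.1% of pairs are planted IC and 0.1% IA — about 400
  pairs each, enough to dominate the extreme tail without distorting
  the score distribution.
- *Lengths and identities.* Transcript lengths are uniform on
  [30, 1,500], so roughly a fifth fail the 50–1,200 window; planted
  transcripts draw from the same distribution, so annotations carry no
  length-conditional structure and the bias controls stay null. Five
  percent of transcripts get a near-duplicate partner at 85–99%
  identity, exercising the redundancy reduction.
- *Ontology.* A 21-term, two-namespace DAG: a biological-process root
  with two mid-level terms, one leaf preferentially annotated to 70% of
  the true IC transcripts, one to IA transcripts, fourteen 5-gene
  background leaves, and a small cellular-component sub-DAG. Five-gene
  background terms mirror specific leaf terms of real ontologies and
  keep the hypergeometric tests discrete.
- *Knock-down.* The first protein is designated the knock-down
  subject; 5% of transcripts are its bound targets. Bound targets'
  log-fold changes are displaced by `lfc_shift` (default +1 SD;
  negative values model targets that are down-regulated on depletion),
  and a `clip_score` column emulates the cross-linking read signal used
  to rank experimental interactions.
- *Disorder.* Protein lengths are uniform on [50, 750]; two-thirds of
  proteins carry one contiguous disordered segment (scores 0.45–0.9 on
  a 0.05–0.35 baseline). The probability that a region out-scores its
  full-length chain starts at 0.66 for the lowest-propensity proteins
  and decays linearly to zero, halved when a canonical RNA-binding
  domain is present — the qualitative geometry the disorder analysis
  should recover.

The generator does **not** emulate realistic tissue-specific expression
programs, real GO topology, isoform structure, or correlated noise
between the score matrix and expression. Passing recovery tests
therefore demonstrate that the machinery recovers planted structure of
the assumed form at realistic sizes — not that the biological findings
reproduce on real data.

## Numerical choices and edge cases

- Percentile tail sizes are floored; percentile cuts on correlations
  use the empirical type-7 quantile.
- All id-dependent tie-breaks use radix (byte-order) sorting, so
  results do not depend on the session locale.
- Constant expression columns normalize to zeros (reported); constant
  profiles give undefined correlations (excluded, reported).
- Hypergeometric tests are upper-tail $P[X \ge k]$; degenerate counts
  ($n = 0$, $K = 0$) give $p = 1$ rather than an error. Infeasible
  count combinations are rejected.
- Fisher tables with an empty margin return $p = 1$ with a warning.
- The Mann–Whitney contribution test reports `underpowered` when the
  smallest achievable p-value exceeds the significance level (e.g. one
  transcript per side), rather than erroring.
- Every stochastic operation takes an explicit seed; the pipeline
  writes the seed, all thresholds, and input digests into its manifest,
  and reruns are byte-identical.

## Problem sizes used by the test and acceptance suites

The suites run the default 200 x 2,000 cohort for recovery checks;
oracle-equivalence properties use 1,000 random small instances per
statistic (pair tables of ~100–200 rows, universes up to 25 genes for
exhaustive enumeration); null-calibration studies use 200 replicates
(10,000 transcripts for the Fisher null, 250 targets vs 5,000
non-targets for the KS null and power). These sizes were chosen so the
whole suite completes in about a minute while keeping every Monte-Carlo
margin at three standard errors or better.

## A note on the five-criteria rule under label permutation

The acceptance rule gates raw p-values (0.05 significant / 0.1
non-significant) and applies no multiple-testing correction, by design.
Consequently its family-wise false-pass rate grows with the number of
testable terms: on the 21-term synthetic ontology, label-permutation
nulls leave on average roughly half to one passing (term, subset)
combination per permutation — mostly 5-gene terms reaching 3 subset
genes, which is already significant at these subset sizes. Users who
need family-wise control on large ontologies should filter on the
emitted Benjamini–Hochberg column in addition to the five criteria;
the rule alone is a specificity filter, not an error-rate guarantee.

## Known limitations

- The interaction-propensity and disorder predictors are upstream
  inputs; nothing here validates their accuracy beyond the knock-down
  battery.
- The homology profile transfer returns the single best-ranked
  qualifying hit; averaging over candidate profiles is not
  implemented.
- The negative sets of the validation battery must be disjoint from
  the positives; workflows in which the negative pool silently
  contains positives (e.g. "all transcripts") need the overlap removed
  first.
- The conditional GO procedure implements the classic child-decrement
  scheme; more elaborate conditioning (weights, elimination orders) is
  out of scope.
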