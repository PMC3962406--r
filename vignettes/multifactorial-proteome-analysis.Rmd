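---
title: "Multifactorial analysis of 8-plex proteome ratio tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactorial analysis of 8-plex proteome ratio tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexfactor)
```

## The experimental design this package models

An 8-plex isobaric-labeling (iTRAQ) experiment quantifies up to eight
samples in a single mass-spectrometry run, one reporter channel per
sample. `plexfactor` targets the case where the eight channels realize a
complete 2×2×2 factorial design — in the motivating application, ethanol
versus control diet × CYP2E1 knockout versus wild type × female versus
male mouse liver. One channel (tag 114: wild-type, control diet, male) is
the reference, and every other channel is expressed as a ratio against
it, giving seven *observations*. An observation is written
`"num:den"`, e.g. `"116:114"` is the ethanol effect in wild-type males.

The primary data object is the `quant_table`: per protein, a log2 ratio
`log2 R` and a ratio-test p-value for each observation. `log2 R = 0`
means no change; the p-value comes from the upstream quantification
engine and tests the ratio against 1. Because different publications
reference the same channel against different denominators (the female
ethanol effect appears both as `115:113` and `115:114`),
`re_reference()` converts between denominators with the exact identity
`log2(a/b) = log2(a/d) − log2(b/d)`; derived columns get no p-value,
since ratio-level data cannot re-test a derived ratio.

## Significance filtering and set comparison

A protein is *significantly changed* in an observation when
`|log2 R| > 1` (two-fold) **and** `p < 0.05`. Both inequalities are
strict, so boundary rows (`|log2 R| = 1`, or a p-value printed as
exactly 0.050) are excluded — this matters in practice: one row of the
packaged interaction table prints `p = 0.050` and therefore does not
pass. No multiple-testing correction is applied across proteins; the
procedure is deliberately the simple per-protein filter, and users who
want FDR control should apply it upstream. Tables that list only
already-significant entries (and hence print no p-values) are re-counted
with `significance_criteria(alpha = NA)`, which disables the p criterion.

`overlap_analysis()` partitions two significant sets into shared and
exclusive accessions and flags shared proteins whose ratios point in
opposite directions (`sign(log2R_a)·sign(log2R_b) < 0`) — the
formimidoyltransferase-cyclodeaminase pattern, up in ethanol-fed males
and down in females, is recovered this way from the packaged table.

The multi-observation stages use a weaker filter, `changed_proteins()`:
p < 0.05 in at least one of the listed observations, with no fold-change
threshold.

## PCA and Hotelling T²

`run_pca()` treats proteins as samples and observations as variables.
This orientation is the only one that yields a per-protein outlyingness
measure while projecting the seven observations as vectors in a biplot.
Columns are mean-centered but not variance-scaled by default (all
columns are already on the common log2-ratio scale; a `scale.` switch is
provided). Missing cells are first imputed by `build_matrix()` with the
no-change value 0 — the protocol's reading that a missing quantification
is best represented as "no significant change". The imputed-cell mask is
kept, because downstream stages differ in whether imputed values are
data: clustering uses them, ANOVA excludes them.

`hotelling_rank()` computes, per protein,

T²ᵢ = Σ_{k ≤ m} s²ᵢₖ / λₖ,

where sᵢₖ is the protein's score on component k, λₖ the component
variance, and m the smallest number of components whose cumulative
explained variance reaches `variance_target` (default 0.90). The
variance-driven m generalizes the "top six components explain >90%"
rule beyond seven observations. With all components retained, T² is
exactly the squared Mahalanobis distance to the column means — the unit
tests assert this identity against a direct `solve(cov(x))`
computation. The `selected` subset keeps proteins with T² strictly
greater than the third quartile of all T² values; the quartile uses R's
default linear-interpolation quantile (type 7), and ties at Q3 are
excluded by the strict inequality.

## ANOVA and Tukey–Kramer comparison

`observation_anova()` runs a one-way fixed-effects ANOVA with the
observation columns as groups and protein-level log2 ratios as
replicates within each group. Treating proteins as independent
replicates ignores protein-level pairing across observations; that is a
deliberate fidelity choice matching the original analysis protocol, and
is the reason the result should be read as a coarse
"do these conditions shift the changed-protein distribution" test, not
a per-protein inference. Originally-missing cells are excluded rather
than imputed (`use_imputed = TRUE` reproduces the imputed variant), so
group sizes can differ — which is why the pairwise stage is
Tukey–Kramer rather than plain Tukey HSD:

CI half-width = q_{α,k,df} / √2 · √(MS_within (1/nᵢ + 1/nⱼ)),

with the studentized-range quantile from `qtukey()`. With equal group
sizes this reduces to Tukey's HSD exactly. A pair is significant at the
family level when its interval excludes zero.

## Hierarchical clustering of observations

`normalize_within_observation()` standardizes each observation column to
mean 0, sd 1 (sample n−1 convention by default, switchable), after
imputation. `cluster_observations()` then applies complete-linkage
agglomeration on Euclidean distances between observation columns and
reports the two-way cut at the top split — for a factorial design the
natural question is which factor divides the conditions first. The
protein-side dendrogram is not part of the package's comparison surface.

## Interaction detection: K-means on the deviation distance

To ask whether one factor reverses another's effect, each protein is a
point (E_a, E_b): its log2 change under condition a (e.g. ethanol alone,
x-axis) and condition b (e.g. knockout + ethanol, y-axis). If the second
factor had no influence, points would sit on the identity line
E_a = E_b. The *deviation from equal expression* is the perpendicular
distance to that line,

D = |E_a − E_b| / √2,

and `kmean_deviation()` clusters the scalar D (one-dimensional K-means,
k = 3 by default). Clustering the distance rather than the 2-D point is
the choice consistent with the published cluster geometry: clusters form
bands around the identity line and the outermost cluster contains
members on both sides of it. Any positive rescaling of D produces
identical clusters, so the √2 factor is a convention. Sections are
labeled by the sign rule — `lower_right` (E_a > E_b: the second factor
pushes expression down relative to the first) and `upper_left`
(E_a < E_b).

Numerical choices: initialization is deterministic (centroids at the
1/6, 3/6, 5/6 quantiles of the distances) plus seeded random restarts,
and the best within-cluster sum of squares wins, so labels are
reproducible; clusters are renumbered by ascending centroid (cluster 1
hugs the line, cluster k is farthest); `k` larger than the number of
distinct distances is refused. On every test instance up to 15 points
the converged solution equals the exhaustive optimum over contiguous
partitions of the sorted distances (1-D K-means optima are contiguous).

## Upstream-regulator activation scoring

`score_regulators()` is an open, unweighted activation scorer on a
user-supplied signed regulator→target edge list. For a regulator with N
in-dataset targets that have both a known edge sign and a nonzero
observed direction,

z = (n_consistent − n_inconsistent) / √N,

where a target is consistent with activation when its observed
direction (the sign of its log2 ratio) equals the edge sign; z ≥ +2
predicts activation, z ≤ −2 inhibition. Target-set enrichment is the
hypergeometric upper tail of drawing the dataset from a background of
`background_size` quantified proteins (in the motivating study, 863).
Unsigned edges count toward the overlap but not toward z.

This deliberately omits the proprietary edge weighting and
literature-bias corrections of commercial knowledge-base tools, so
published weighted z-scores are approximated, not reproduced (the
seven-target NRF2 panel scores 7/√7 ≈ 2.65 here against a published
weighted 2.56); the scorer is validated by its analytic properties
(sign symmetry, |z| ≤ √N, exact hypergeometric tail) rather than
against any commercial output.

## The synthetic factorial generator

`generate_quant_table()` emulates the study design so every stage is
testable against ground truth. Per protein, the true log2 ratio versus
the reference is β_ko·KO + β_e·E + β_g·G + β_koxe·KO·E, each β applied
to its own disjoint block of carrier proteins; replicate-level log2
ratios add Normal(0, noise_sd) noise; the per-cell p-value is a
two-sided one-sample t test of the replicates against 0 (a transparent
stand-in for proprietary ratio statistics); cells then drop out
independently with probability `missing_prob`.

Defaults are fixed once to a realistic regime for a chronic-exposure
liver study: 150 proteins per run (a desk-scale stand-in for the ~270
changed proteins of a full cohort), 4 replicates (the study's four mice
per group), noise_sd 0.5 in log2 units, 10% carriers per effect,
β_ko = 2 > β_e = 1 > β_g = 0.5 with interaction β_koxe = −1.5 (the
knockout reversing the ethanol induction — the design's central
phenomenon), and 5% missingness. Under the null the generated p-values
are uniform, and carrier recall matches the analytic noncentral-t power
at the same settings — both are asserted in the test suite.

What the generator does *not* emulate: isotope impurity and ratio
compression, peptide-to-protein rollup, correlated missingness
(censoring at low intensity), and heavy-tailed noise. Passing recovery
tests therefore demonstrate the statistical machinery is correct under
the stated model, not that real spectra meet that model.

`recovery_suite()` repeats the full chain over independently seeded
simulations (200 by default; at that size each suite runs in seconds)
and reports the knockout-separation rate of the hierarchical two-way
cut, the family-wise Tukey–Kramer positive rate (the false-positive
rate under an all-null configuration), the enrichment odds ratio of
interaction carriers in the farthest K-means cluster, and the Spearman
correlation between true effect magnitude and Hotelling T².

## Degenerate inputs and edge policies

* Proteins missing in every chosen observation are dropped with a
  warning before imputation.
* Zero-variance PCA input and zero-spread normalization columns are
  contract errors, not silent NaNs.
* Zero-variance components inside the retained T² subspace are skipped
  with a warning.
* An empty K-means cluster is avoided by multi-start selection; a start
  that degenerates is discarded.
* A regulator with no in-dataset targets is reported with N = 0,
  undefined z and overlap p = 1 rather than dropped.
* The degenerate `re_reference(tab, a, a)` self-ratio returns an
  all-zero column; self-ratio columns in input *files* are rejected.

## Reproducing the packaged analyses

The packaged tables (see `plexfactor_example()`) transcribe the printed
summary tables of the motivating chronic-ethanol CYP2E1 study, and
`scripts/acceptance.R` in the source repository recomputes the headline
numbers from them end to end. The full-cohort quantification table
(deposited at ProteomeXchange as PXD000635) is not redistributable here;
`read_quant_table()` ingests a transcription of it directly should one
be available locally, and the acceptance suite documents the expected
drop-in path.

```{r example}
tab <- read_quant_table(plexfactor_example("ethanol_gender"))
male <- significant_proteins(tab, "116:114", significance_criteria(alpha = NA))
female <- significant_proteins(tab, "115:113", significance_criteria(alpha = NA))
male
female
overlap_analysis(male, female)
```
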