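---
title: "scMetR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scMetR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind the package, the
parameters that matter, the simulator that backs the test suite, and the
design choices made where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

A tumor cell's metastatic competence is approximated by two orthogonal,
rank-based signals. **S_EMT** is a single-sample GSEA score of an
EMT-associated gene set: within each cell, genes are ranked by expression
(descending; ties broken lexicographically by gene identifier so the score
is deterministic), and a weighted running sum accrues
`(N - position + 1)^alpha` — the rank counted from the bottom, normalized by
the in-set total — at in-set genes and `-1/(N - |G|)` at out-of-set genes.
The raw score is the *sum* of the running sum over all positions (the
ssGSEA sum statistic, not the GSEA maximum deviation), which makes it
invariant under any strictly monotone transform of a cell's expression.
`alpha = 0.25` follows the original single-sample GSEA convention; the
paper-level choice is not recoverable, so it is exposed as an argument.

**S_CyTo** is a differentiation-potential score in the CytoTRACE family:
the per-cell detected-gene count is the raw potency signal; each gene's
expression is correlated with that count across cells and the mean
log-normalized expression of the `topN = 200` most positively correlated
genes forms the gene-counts signature; the signature is smoothed over the
`k = 30` nearest neighbors (Euclidean metric in a 30-component PCA of the
log-normalized matrix, the cell itself included) and finally
rank-transformed to [0, 1] (ties averaged). The original tool's
NNLS-regression and Markov-diffusion smoothing are deliberately replaced by
kNN-mean smoothing: the replacement is simpler, fast, order-equivariant,
and smoothing can be disabled (`smooth = FALSE`). The package does not aim
to reproduce the original tool's numeric outputs, only the signal it keys
on; the recovery tests quantify what the simplification retains.

Both scores are min-max scaled to [0, 1] over the scored population and
combined as

\[ X_m = S_{EMT} + S_{CyTo}, \quad
   Score_m = \frac{X_m - (\overline{S_{EMT}} + \overline{S_{CyTo}})}
                  {\sqrt{SD^2_{EMT} + SD^2_{CyTo} + 2 r\, SD_{EMT} SD_{CyTo}}} \]

with `r` the Pearson correlation of the two inputs. The denominator is the
sample SD of the sum for *any* consistent SD estimator; the package uses the
n−1 convention throughout, and the cross term is computed as `2 cov(.,.)` so
the formula remains defined when one input is constant. Standardization is
therefore exact (mean 0, SD 1) by construction — the acceptance suite
asserts it to 1e-9. Perfectly anticorrelated inputs of equal spread
collapse the denominator; this raises a "degenerate score distribution"
error rather than returning infinities.

## Tier classification

Each tumor sub-cluster is compared against all remaining tumor cells with a
two-sample Wilcoxon rank-sum test (normal approximation with tie and
continuity correction for larger groups, exact enumeration where base R
provides it). Sub-clusters one-sidedly *higher* at `alpha = 0.01` are MFTC,
*lower* ones ConvTC, the rest TransMTC.

Significance alone is not a workable rule at single-cell sample sizes: with
hundreds of cells per cluster the rank-sum test resolves shifts of a few
percent of a rank unit, so an intermediate cluster that drifts marginally
off the rest-average would be promoted to an extreme tier even though it is
biologically transitional. Intermediate clusters remaining transitional
despite highly powered tests is precisely the structure the tier taxonomy
is meant to express. The classifier therefore also requires at least a
medium effect for an extreme call: the rank-biserial correlation of the
cluster-vs-rest comparison (`2*AUC − 1`) must reach `minEffect = 0.3`
(Cohen's conventional medium boundary) in the corresponding direction.
`minEffect = 0` restores the literal p-only rule. If no cluster clears the
bar in either direction every cluster is TransMTC, with a warning — a null
result, not an error.

## Re-clustering and resolution selection

Tumor cells are re-clustered on a PCA embedding of the top highly variable
genes. The graph is a shared-nearest-neighbor graph (k = 20 neighbors
including self, Jaccard edge weights, edges below 1/15 pruned) partitioned
by Louvain modularity optimization at each resolution of the grid 0.1–1.0
in steps of 0.1. Each clustering is scored by the mean silhouette width
(Euclidean distances on the same embedding; singleton clusters contribute
0 by the usual convention) and the resolution with the largest mean
silhouette wins, ties going to the smallest resolution. Resolutions that
collapse to a single cluster are recorded with `NA` silhouette and excluded
from the argmax. The representation in which the silhouette is computed is
not identifiable from the methodology being followed; the PCA embedding is
this package's documented default.

## Signature genes, enrichment, survival

MSGs are derived by per-gene Wilcoxon tests between MFTC and ConvTC on
log-normalized expression, restricted to genes detected in at least 10% of
either group. The log fold change is `ln(mean(expm1(a)) + 1) −
ln(mean(expm1(b)) + 1)` — natural log with a pseudocount on de-logged
means, the convention of the mainstream single-cell DE implementations.
Benjamini–Hochberg adjustment is applied across tested genes and the
signature rule is strict: `adj_p < 0.05` *and* `|logFC| > 0.25`. One
caution discovered while validating against the simulator: when group
detection rates differ (as they do when differentiation potential is
encoded in detected-gene counts), the rank-sum test direction can disagree
with the mean-based fold change for shallowly expressed genes, thinning the
down-regulated signature; this is a property of the test, not a bug.

Over-representation uses the hypergeometric upper tail of the query/set
overlap within the supplied universe, BH-adjusted across sets, reporting
rows with overlap ≥ 1 and adjusted p < 0.05. Gene-set collections come from
user GMT files; no ontology is bundled or downloaded.

Bulk cohorts are scored with the same ssGSEA statistic on the up-regulated
MSGs. The cutpoint maximizes the absolute standardized log-rank statistic
`(O − E)/sqrt(V)` over all score thresholds leaving at least `minprop =
0.1` of samples on each side (ties to the lower threshold). The reported
log-rank p at the selected cutpoint replicates the common
cutpoint-then-test procedure and is **anti-conservative by construction**
(maximal selection); the null-calibration test therefore asserts
p-uniformity only for fixed (median) splits. Standardized maximally
selected statistics also inflate at the admissibility boundary, which is
what `minprop` exists to contain.

## Drug reversal screening

Per-condition drug rankings (genes ordered by fold change, ties by gene
identifier) are merged into one Prototype Ranked List per drug by
hierarchical majority voting: repeatedly merge the pair of lists with the
smallest Spearman footrule distance (ties to the first pair in stable input
order) via Borda aggregation (mean ranks, lexicographic tie-break). With
all pairwise distances distinct the result is independent of input order.

Because a PRL carries ranks but no magnitudes, preranked GSEA runs on
centered rank scores `(N+1)/2 − i` with weight exponent 1; the enrichment
score is the signed maximum deviation of the weighted KS running sum, and
its extrema are evaluated only at hit boundaries (an O(|S|) identity the
test suite checks against a full-walk oracle and against the independent
`fgsea` implementation). The permutation p permutes gene labels and, by
default, reads the tail of the observed ES sign — the convention of fast
GSEA implementations. That default is *not* a calibrated unconditional
p-value: choosing the tested tail from the data doubles the tail mass, so
`alternative = "less"`/`"greater"` are provided to fix the direction in
advance; those are uniform under the null up to the `1/(nPerm+1)` floor.
Candidate calling is unaffected by the distinction: a drug is a candidate
when the up-signature is depleted (`es_up < 0`, `p_up < 0.05`) or the
down-signature enriched (`es_down > 0`, `p_down < 0.05`), and each such
direction-restricted test is an exact alpha-level test. Note the OR of the
two signature tests has a familywise null rate of up to roughly twice the
per-test level; the calibration checks measure the per-signature rate.

## The synthetic-data generator

The generator defines the conditions under which every recovery claim is
tested, and its defaults are fixed once:

- counts are negative binomial (`variance = mu + 0.5 mu^2`) around
  lognormal gene baselines (median 0.5 counts per cell per gene), with 20%
  independent dropout;
- 2000 genes, 1000 cells, 60% tumor cells, three tumor sub-populations
  with EMT activity and differentiation potential (0.9, 0.5, 0.1);
- EMT activity multiplies the 100 planted EMT genes' means by
  `1 + 3 * activity` — a strong but realistic programme (up to ~3.7-fold);
- differentiation potential is realized through the *fraction of genes a
  cell expresses*: each gene survives in a cell with probability
  `0.4 + 0.6 * d`. This is a generative commitment the methodology itself
  never makes; it is chosen because the detected-gene count is exactly the
  signal a CytoTRACE-style score keys on, and it makes potency recovery a
  falsifiable claim;
- bulk cohorts draw a per-sample burden `b ~ U(0,1)` scaling the planted
  genes, with exponential survival of rate `0.01 * exp(2b)` and 30%
  independent censoring;
- drug panels contain 20 drugs, half true inhibitors that shift the
  signature genes by ±2 (in log-FC units, against unit-normal noise) in
  each of 3 conditions.

All randomness flows from one master seed through per-component sub-streams
so each generator is independently reproducible. The simulator does *not*
model batch effects, doublets, ambient RNA, per-gene dispersion
heterogeneity, or correlated gene programmes beyond the planted one —
passing recovery tests demonstrates internal consistency of the pipeline
under its own assumptions, not performance on real tissue.

Test and acceptance problem sizes (600–1000 cells, 1000 genes, 200-sample
cohorts, 50-replicate null screens, 100–1000 permutations) were chosen as
the smallest scales at which the planted effects are comfortably
identifiable; they are stated here so results are interpretable, and they
run in well under a minute each.

## Degenerate inputs and numerical conventions

- Expression ties: always broken lexicographically by gene identifier;
  cell permutations permute outputs exactly.
- Constant expression vectors are scored (the gene-id ordering applies) but
  flagged; a constant score vector min-max scales to all 0.5 with a
  warning.
- A matrix of fully identical cells carries no potency ordering;
  `cytotraceScore` returns tied 0.5 scores, while `gcsScore` alone raises
  "no potency signal" (a constant detected-gene count with non-identical
  cells is a genuine error).
- QC thresholds are strict inequalities exactly as worded ("more than 40%",
  "more than 7500", "more than 100,000", "fewer than 3"); cells are
  filtered before genes so gene detection counts refer to retained cells,
  and both orders are reported in the `QCReport`.
- BH adjustment is monotone and never below the raw p; it is *not*
  idempotent on arbitrary adjusted vectors (re-adjusting rescales by `n/j`
  again), so no such invariant is asserted.
- Permutation p-values are floored at `1/(nPerm + 1)`; zero p-values are
  never reported.

## Known limitations

- The tier rule (significance + medium effect vs the rest) is an
  operationalization of a taxonomy that the source methodology states only
  by example; other defensible rules (e.g. ordering-based tertiles) exist.
- The differentiation-potential score is a deliberate simplification of
  the cited tool; agreement with it on real data is not claimed.
- The cutpoint-selected survival p is biased toward significance; a
  permutation-adjusted alternative would be the honest inferential choice
  and the fixed-split test is provided for calibrated questions.
- ssGSEA scores are min-max scaled within the scored population, so scores
  are comparable within a dataset, not across datasets.
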