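# scMetR

Tumor cells within a single carcinoma differ in their propensity to
metastasize. **scMetR** estimates that propensity per cell from scRNA-seq
data by combining two signals that track metastatic competence from opposite
directions:

- **S_EMT** — a single-sample GSEA (ssGSEA) enrichment score of an
  EMT-associated gene set (e.g. dbEMT 2.0), per cell;
- **S_CyTo** — a CytoTRACE-style differentiation-potential score built on
  the per-cell detected-gene count; higher values mean less differentiated
  cells.

Both scores are scaled to [0, 1] and their sum is standardized:

```
X_m   = S_EMT + S_CyTo
MX_m  = mean(S_EMT) + mean(S_CyTo)
SDX_m = sqrt( SD(S_EMT)^2 + SD(S_CyTo)^2 + 2 r SD(S_EMT) SD(S_CyTo) )
scMetR = (X_m − MX_m) / SDX_m
```

where `r` is the Pearson correlation of the two scores. `SDX_m` is exactly
the standard deviation of the sum, so `scMetR` has mean 0 and SD 1 over the
scored population by construction. Tumor sub-clusters whose scMetR
distribution sits significantly above the remaining tumor cells (one-sided
Wilcoxon rank-sum, p < 0.01, with at least a medium rank-biserial effect)
are called **MFTC** (metastasis-featuring tumor cells), significantly lower
ones **ConvTC** (conventional), and everything in between **TransMTC**
(transitional).

Downstream modules derive **metastatic signature genes** (MSGs: Wilcoxon DE
between MFTC and ConvTC at BH-adjusted p < 0.05 and |log-FC| > 0.25), test
them for over-representation in user-supplied GMT collections, stratify bulk
survival cohorts by the ssGSEA score of the up-regulated MSGs at a maximally
selected log-rank cutpoint, and screen drug perturbation profiles for
signature reversal: per-condition fold-change rankings are merged into one
Prototype Ranked List per drug (footrule-paired, Borda-aggregated
majority voting) and tested by preranked GSEA — a drug whose down-regulated
genes are enriched for up-MSGs is a candidate metastasis inhibitor.

The package ships a synthetic-data module that generates scRNA-seq counts
with planted EMT-activity and differentiation-potential gradients, survival
cohorts whose hazard follows signature burden, and drug profiles with known
inhibitors, so every claim above is testable against ground truth.

## Worked example

```r
library(scMetR)

cfg <- simConfig(nGenes = 1000, nCells = 600, cellTypeProps = c(tumor = 1),
                 emtActivity   = c(0.9, 0.5, 0.1),
                 diffPotential = c(0.9, 0.5, 0.1), seed = 7)
sim <- simulateScRNAseq(cfg)
sce <- normalizeLog1p(qcFilter(sim$sce))

sEmt  <- ssgseaScore(sce, sim$truth$emtGenes, alpha = 0.25)
sCyto <- cytotraceScore(sce, topN = 200, k = 30)
risk  <- scMetRScore(sEmt$scaled_score, sCyto$scaled_score)
tiers <- classifySubpopulations(risk, sim$truth$subpop[colnames(sce)])
print(tiers, digits = 3)
```

```
  sub_cluster n_cells median_scmetr effect_size   p_high    p_low p_vs_rest
1           1     202        1.1686      0.9964 5.99e-89 1.00e+00  5.99e-89
2           2     206       -0.0572     -0.0289 7.19e-01 2.81e-01  2.81e-01
3           3     192       -1.1801     -0.9927 1.00e+00 4.22e-86  4.22e-86
      tier
1     MFTC
2 TransMTC
3   ConvTC
```

The three planted risk levels are recovered as one MFTC, one TransMTC and
one ConvTC sub-cluster: the high-activity sub-population scores about 1.2
standardized units above the population mean with a near-perfect
rank-biserial effect (0.996), the low-activity one symmetric below, and the
intermediate one is not separable from the rest (p = 0.28). Every cell's
tier matches its planted tier in this run (`cellTiers(tiers, ...)`).

`runPipeline(pipelineConfig(...), outDir)` chains all stages — QC,
normalization, both scores, silhouette-selected re-clustering, tier calling,
MSG derivation, survival stratification and the drug screen — and writes
config-stamped TSVs; identical config and seed reproduce byte-identical
outputs.

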