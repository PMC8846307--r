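# refstab

Reference-gene stability analysis for RT-qPCR normalization.

## The problem

Relative RT-qPCR quantification divides every target gene's signal by a
normalization factor built from reference ("housekeeping") genes, so the
whole analysis is only as good as the stability of those references.
`refstab` selects stable references from a candidate panel measured on a
pilot experiment: a complete samples x genes matrix of quantification-cycle
(Cq) values, optionally with a condition label per sample. It is aimed at
anyone validating reference genes for a new tissue, species or experimental
condition.

## Methods at the core

Four standard stability algorithms, authored in full here, plus a consensus:

* **geNorm** — gene stability `M_j = mean_k SD_samples( log2(q_j / q_k) )`
  on relative quantities `q = 2^(min Cq - Cq)`; stepwise exclusion of the
  highest-M gene down to the tied best pair, and the pairwise-variation
  analysis `V(n, n+1) = SD( log2(NF_n / NF_{n+1}) )` with the conventional
  `V < 0.15` rule for the optimal panel size.
* **NormFinder** — model-based decomposition of log2 expression into
  intragroup variances (bias-corrected, truncated at zero) and shrunken
  intergroup deviations; stability = |shrunken deviation| + its shrunken
  standard error, averaged over groups. Grouped and ungrouped variants.
* **BestKeeper** — descriptives on raw Cq with SD(CP) = mean absolute
  deviation (acceptable when < 1 cycle), geometric-mean-anchored x-fold
  ranges, pairwise Pearson correlations, and each gene's correlation with
  the BestKeeper index (per-sample geometric mean Cq).
* **Comparative delta-Ct** — mean SD of pairwise Cq differences (identical
  to the first geNorm iteration at 100% efficiency).
* **Consensus** — geometric mean of the four methods' ranks
  (RefFinder-style), with geNorm's tied best pair entering as a min-rank
  tie.

A synthetic-data module (`cq_sim_spec()` / `simulate_cq()`) draws Cq
matrices from the additive gene + sample-loading + group-shift + noise
model the methods assume, so every estimator is tested by parameter
recovery. Target-gene validation (`normalize_targets()`,
`panel_contrast()`) contrasts normalization under a best vs worst panel and
flags direction reversals.

## Worked example

The bundled benchmark, `bovine_pbmc_cq()`, holds Cq values for 10 candidate
reference genes in PBMCs of 30 cattle from two contrasting environments
(15 cold-arid high-altitude, 15 hot-arid lowland animals):

```r
library(refstab)
cq  <- bovine_pbmc_cq()
fit <- refgene_stability(cq)
fit
#> Reference-gene stability analysis: 30 samples, 10 genes
#> geNorm best pair:     RPS9 = RPS15  (M = 0.465)
#> NormFinder best:       RPL4  (stability = 0.236)
#> BestKeeper best:       GAPDH  (SD[+/-CP] = 0.52)
#> consensus order:       RPS9 > RPS15 > GAPDH > RPL4 > HMBS > EEF1A1 > B2M > UXT > ACTB > HPRT1
#> optimal panel (V < 0.15): RPS9, RPS15, GAPDH
```

Reading the output: the geNorm best pair RPS9/RPS15 share stability
M = 0.465 (well under the 1.5 acceptability ceiling); NormFinder, which
penalizes genes whose expression shifts between the two environments,
agrees that the ribosomal genes and RPL4 lead; BestKeeper's most consistent
gene by raw-Cq dispersion is GAPDH (mean absolute deviation 0.52 cycles);
and the consensus puts RPS9, RPS15 and GAPDH on top while HPRT1 — which
sits ~4 cycles lower in the hot-arid animals — is uniformly last. The
pairwise-variation analysis says three genes suffice:

```r
pairwise_variation_series(relative_quantities(cq))
#> geNorm pairwise variation (threshold 0.15):
#>   V2:3 = 0.169
#>   V3:4 = 0.116 *
#>   V4:5 = 0.101 *
#>   ...
#> optimal number of reference genes: 3
```

`summary(fit)` prints the full per-method ranking table, `plot(fit)` draws
the M-curve and V-bar panels, and `simulate(fit, nsim, seed)` generates
moment-matched synthetic datasets. `run_analysis(run_config(...))` drives
the same pipeline from a (YAML-configurable) specification and writes
per-method CSV reports.

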