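---
title: "Selecting stable reference genes for RT-qPCR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes for RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR divides a target gene's signal by that of
one or more reference ("housekeeping") genes, so any instability in the
references propagates directly into the biology being reported. Reference
genes are usually picked from a candidate panel by running several stability
algorithms on a pilot matrix of quantification-cycle (Cq) values — one value
per sample and candidate gene — and looking for consensus. `refstab`
implements that entire workflow: the four standard algorithms, the
consensus ranking, the optimal-panel-size analysis, and a validation step
that contrasts normalization under a good and a bad panel.

The package ships a benchmark dataset, `bovine_pbmc_cq()`: Cq values for 10
candidate reference genes in peripheral blood mononuclear cells of 30
cattle, 15 from cold-arid high-altitude (hypoxic) herds and 15 from hot-arid
lowland (normoxic) herds. The previously reported stability results for this
dataset are stored alongside it and recomputed by `reproduce_benchmarks()`,
which is both a regression test and a worked example of every method.

## Input model and transform

All methods operate on a complete samples-by-genes Cq matrix (`cq_matrix()`;
missing values are rejected, not imputed, because every score below is a
dispersion statistic that imputation would shrink). Cq is a log2-scale
quantity: one cycle is one doubling at 100% amplification efficiency.

geNorm and NormFinder take relative quantities
`q = E^(min(Cq) - Cq)` per gene (`relative_quantities()`), with `E = 2` by
default. The per-gene minimum only rescales each gene's column, so every
statistic below that is built from log-ratios or centered logs is unchanged
by it; per-gene bases from standard-curve slopes
(`efficiency_from_slope()`, `E = 1 + pct/100`) are supported but off by
default, matching the near-universal convention of running stability
analysis on the `2^-dCq` scale. BestKeeper and the comparative delta-Ct
method use raw Cq directly.

## The four stability algorithms

**geNorm** (`genorm_ranking()`). For genes *j*, *k* the pairwise
variability `V_jk` is the SD over samples of `log2(q_j / q_k)`; the gene
stability `M_j` is the mean of `V_jk` over all partners. The least stable
gene (highest M) is removed and M recomputed until two genes — the tied
best pair — remain. The stability value *reported* for each step is the
average M of the genes still in the set at that step, the convention of the
original software's chart; it decreases monotonically along the exclusion
path and ends at the terminal pair's shared pairwise variability.
`pairwise_variation_series()` then asks how many genes a normalization
factor needs: `V(n, n+1)` is the SD of `log2(NF_n / NF_{n+1})` over samples,
where `NF_n` is the geometric mean of the *n* best genes' relative
quantities, and the optimal panel size is the smallest *n* with
`V < 0.15`. The threshold is a community convention, not a statistical
test; when nothing falls below it the full panel is returned with a
warning rather than an error, since a V slightly above threshold is
routinely accepted in practice.

**NormFinder** (`normfinder_grouped()`, `normfinder_ungrouped()`). A
model-based decomposition on log2 relative quantities: each sample's mean
over genes (the loading effect) is removed, then per gene and group the
intragroup variance is estimated with a bias correction — sample-centering
mixes a `1/k` share of all genes' noise into every column, hence the
`(v_ig - mean(v)/( k-1 )) * k/(k-2)` form, truncated at zero — and the
intergroup deviations `d_ig` (each gene's group means around its own
average) are shrunk toward zero in proportion to their sampling noise. The
stability value combines `|shrunken d|` with the shrunken standard error;
lower is better. Genes with few-cycle condition shifts (like HPRT1 in the
bundled data, about 4 cycles between environments) are heavily penalized
even when their within-group noise is small. Grouping is caller-visible:
environments, breeds, any labelling, or none — the ungrouped variant
reduces to the bias-corrected noise SD and is what the popular web
consensus tool uses internally.

**BestKeeper** (`bestkeeper()`). Descriptive statistics on raw Cq. Its
"SD (CP)" is the *mean absolute deviation* about the arithmetic mean, not
the classical SD — on the bundled data this is what reproduces the
published 0.52 (GAPDH) and 2.08 (HPRT1) exactly, while the classical SD
gives 0.64 and 2.21 — with the conventional acceptability rule `SD < 1`
cycle. Fold-change extremes are anchored on the geometric mean
(`-E^(geo - min)`, `+E^(max - geo)`); anchoring on the arithmetic mean
does not reproduce the published x-fold values. Pearson correlations
between genes and between each gene and the BestKeeper index (per-sample
geometric mean of Cq over candidates) use t-distribution p-values with a
reporting floor of 0.001, the customary floor in printed tables;
full-precision p-values are retained in `p_exact`.

**Comparative delta-Ct** (`delta_ct_scores()`). The mean over partner genes
of the SD of pairwise Cq differences. With `E = 2` this is algebraically
identical to the first geNorm iteration (the test suite asserts equality to
1e-12); it is kept as a separate method because the consensus ranking needs
its rank column.

## Consensus ranking

`reffinder_pipeline()` ranks the genes under each of the four methods —
delta-Ct score, geNorm stepwise stability, *ungrouped* NormFinder, and
BestKeeper SD — and aggregates by the geometric mean of the four ranks.
Two conventions were fixed by checking all thirty published composite
values of the bundled dataset (combined, cold-arid, hot-arid):

* geNorm's terminal pair enters as a genuine tie with **min-rank** policy
  (both genes rank 1, the next gene ranks 3). This reproduces every
  published composite exactly (e.g. the runner-up's 1.86 = (1·2·2·3)^(1/4));
  the alternative consecutive policy does not. Consecutive ranking remains
  available via `ties = "consecutive"`.
* BestKeeper contributes its SD ranking, not its index-correlation ranking
  (`bestkeeper_by = "index_r"` is available since the web tool's internals
  are not published).

## The synthetic generator

`cq_sim_spec()` / `simulate_cq()` draw Cq matrices from the additive model
all four methods implicitly assume: per-gene baseline, a per-sample Gaussian
loading offset shared across genes (SD in cycles), per-group-and-gene
shifts, and per-gene Gaussian noise. This gives known-truth datasets for
parameter recovery: the test suite checks that NormFinder's variance
estimates are nearly unbiased (mean |bias| < 10% at two groups of 100
samples, 10 genes, 200 replicates), that a gene with 10x the noise SD of
its peers is ranked worst by geNorm, delta-Ct and NormFinder in at least
95 of 100 seeded datasets, and that loading offsets are invisible to the
ratio-based methods but inflate BestKeeper's dispersion — the structural
difference between the method families. `fit_sim_spec()` moment-matches a
spec to real data (`bovine_sim_spec()` for the bundled matrix), and
`simulate()` on a fitted `refgene_stability` object draws look-alike
datasets.

What the generator does *not* emulate: amplification-efficiency differences
between genes, technical-replicate structure, inhibition or plate effects,
and non-Gaussian Cq error. Passing recovery tests therefore demonstrates
correctness of the estimators under the methods' own model, not robustness
to those artifacts.

## Validation of a chosen panel

`normalize_targets()` divides a target gene's relative quantity by the
panel's normalization factor and summarizes per group (mean, SD,
SE = SD/sqrt(n), fold difference). `panel_contrast()` runs a best and a
worst panel side by side and flags targets whose between-group fold
difference *materially* reverses direction: both panels must disagree in
direction and each deviate from 1 by at least a 1.2x margin. The margin is
a deliberate design choice — without it, sampling noise around a true fold
of 1 trips the flag in a sizeable fraction of null datasets, which would
make the reversal report meaningless. A reference gene whose own expression
shifts with the condition subtracts that shift from every target it
normalizes, which is exactly the failure mode the contrast makes visible
(asserted in the tests with an adversarially confounded panel).

## Numerical and reporting choices

* SDs use the n-1 denominator throughout; logs are base 2 everywhere.
* geNorm exclusion ties remove the later column (deterministic).
* NormFinder variance estimates are truncated at zero; the degenerate
  all-constant input yields stability 0, not NaN.
* Admissible Cq range is [5, 45] cycles; out-of-range input is a hard
  error (it almost always means relative quantities were supplied).
* Report files round to 3 decimals; all comparisons in code use full
  precision.
* Expression tiers split mean Cq at 20 and 23.5 cycles; the boundaries sit
  in the empty gaps between the bundled data's abundance clusters and are
  reporting labels only.

## A known benchmark discrepancy

`reproduce_benchmarks()` recomputes 17 previously reported values for the
bundled dataset. Sixteen reproduce within the printed rounding: all geNorm
M values and pairwise variations, the complete BestKeeper table and its
correlations, the consensus composites, the efficiency conversion. The one
exception is the NormFinder stability column: the implemented model-based
estimator gives 0.236 for the best gene (RPL4) in the two-environment
analysis where 0.282 was reported, with the same leading gene but a
slightly different ordering among the near-tied ribosomal genes. A
systematic search over the standard estimator variants (grouping by
environment, by breed, or none; shrinkage variants; n vs n-1 denominators;
alternative correction constants; log bases) reproduces the reported
column's ordering almost perfectly under breed subgroups but never the
values, while geNorm and BestKeeper reproduce exactly from the same matrix.
The discrepancy therefore lies in the internals of whatever NormFinder
build produced the reported column, not in the data or transform; the
package keeps the published estimator rather than fitting ad hoc constants
to one table, and `reproduce_benchmarks()` reports that row as a documented
failure instead of hiding it.

## Problem sizes

The bundled analyses (30 x 10) run in well under a second. The simulation
-based tests use two groups of 15-100 samples, 10 genes and 50-200
replicates per property — sizes chosen so each recovery experiment has
enough power for a >= 90-95% majority criterion while the whole suite stays
interactive (seconds, not minutes).

## Limitations

* Stability scores are relative to the candidate panel: a panel of
  co-regulated genes can look uniformly "stable". The intergroup-deviation
  table (`intergroup_variation()`) should always be inspected alongside
  the rankings.
* The consensus is a rank aggregate; it inherits whatever biases the four
  methods share (notably, all reward low variance regardless of cause).
* No replicate handling: technical replicates must be averaged upstream.
* The pairwise-variation threshold 0.15 is a convention; treat
  `optimal_n` as guidance, not inference.
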