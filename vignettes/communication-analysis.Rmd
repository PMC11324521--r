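---
title: "Condition-differential cell-cell communication with commshift"
author: "commshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-differential cell-cell communication with commshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commshift)
```

# Overview

`commshift` implements a permutation-based workflow for asking how
cell-cell communication changes between two experimental conditions (for
example a conditional knockout versus its control) in droplet scRNA-seq
data. It covers five stages:

1. barcode/gene quality control with a library-complexity statistic;
2. depth normalization, highly-variable-gene selection and capped scaling;
3. pseudobulk negative-binomial differential expression with one-vs-many
   aggregation;
4. ligand-receptor interaction scoring (LRIScore), a condition-differential
   communication score (LRIDiffScore), and permutation tests for both;
5. pseudotime-binned gene-module detection on a thresholded correlation
   network.

A negative-binomial simulator with planted ground truth
(`simulateDataset()`) makes every stage testable end to end without any
external download.

# The interaction model

For a directed ligand-receptor pair $(L, R)$, a sender cell type $s$ and a
receiver cell type $r$, let $\mathrm{Lmean}$ be the mean (non-log)
depth-normalized expression of $L$ over the sender's cells and
$\mathrm{Rmean}$ the same for $R$ over the receiver's cells, computed per
condition. The interaction score is the product

$$\mathrm{LRIScore} = \mathrm{Lmean} \cdot \mathrm{Rmean},$$

which, unlike the arithmetic mean used by earlier permutation tools,
penalizes interactions in which either partner is lowly expressed: the
score is zero whenever one side is silent. Its null distribution is built
by re-assigning cell-type labels at random (10,000 permutations by
default) and recomputing every score; the p-value is the fraction of
permuted scores matching or exceeding the observed one, adjusted jointly
across all (sender, receiver, pair, condition) records with
Benjamini-Hochberg, and a z-score locates the observed score inside its
permutation background.

Communication change between a mutant condition $m$ and a control $c$ is
summarized per (sender, receiver, pair) by

$$\mathrm{LRIDiffScore} =
  \tfrac{1}{2}\left(\log_2\frac{\mathrm{Lmean}_m + \varepsilon}
                               {\mathrm{Lmean}_c + \varepsilon}
            + \log_2\frac{\mathrm{Rmean}_m + \varepsilon}
                         {\mathrm{Rmean}_c + \varepsilon}\right),$$

the mean (not the product) of the two log fold changes, so coordinated
up- or downregulation of ligand and receptor is emphasized over sheer
magnitude on one side. Its null comes from permuting condition labels.
An interaction is reported as significantly changed when
(i) its LRIScore is significant (adjusted $p \le 0.05$) in at least one
condition, (ii) the LRIDiffScore permutation $p_{adj} \le 0.05$, and
(iii) $|\mathrm{LRIDiffScore}| \ge 1$ (`significantInteractions()`).

## Numerical choices

* The diff score is evaluated as
  $\big((\log_2(L_m+\varepsilon) - \log_2(L_c+\varepsilon)) +
  (\log_2(R_m+\varepsilon) - \log_2(R_c+\varepsilon))\big)/2$. This
  grouping makes the score negate *exactly* (to the last bit) under a
  condition swap, which the test suite asserts; the algebraically
  equivalent ratio form does not.
* $\varepsilon = 10^{-9}$ by default. With $\varepsilon = 0$ a record with
  a structurally zero mean is emitted with an `undefined` flag rather than
  silently dropped.
* One shared permutation stream (a single seed) serves all interactions.
  This costs one group-means recomputation per permutation — a single
  dense matrix product over the ligand/receptor genes — and makes the
  whole test reproducible and fast.
* p-values are the raw permutation fractions (`count / nPerm`); zeros are
  possible and only clamped inside Fisher combination.

## The direction-sensitive diff p-value

The tail of the condition-permutation test is selected by the observed
sign: for a nonnegative score the upper tail, otherwise the lower tail.
The raw sign-selected tail fraction is *not* a calibrated p-value — under
an exchangeable null it is approximately uniform on $[0, 0.5]$, so a
0.05 threshold would reject about 10% of null records. `lriDiffPermTest()`
therefore doubles the sign-selected tail (capped at 1), the standard
equal-tail two-sided permutation p, which is approximately uniform under
the null (the suite verifies rejection at 0.05 within [0.03, 0.07] and a
Kolmogorov-Smirnov distance below 0.1 on 2,400 null records) while the
direction of change remains encoded in the score's sign.
`doubleTail = FALSE` restores the raw one-tailed fraction.

## Permutation stratification

Cell-type labels are shuffled within each condition stratum (scores are
defined per condition), and condition labels within each cell-type
stratum (preserving per-type group sizes). Both tests expose
`stratify = FALSE` for a global shuffle; the results are very similar on
balanced designs, but the stratified scheme keeps the two tests'
exchangeability arguments clean.

# Quality control

Per barcode, `barcodeMetrics()` reports total UMIs, detected features,
mitochondrial and hemoglobin count percentages, and the complexity
statistic $\log_{10}(\text{features})/\log_{10}(\text{UMIs})$ — low values
flag degenerate libraries in which many reads concentrate on few genes.
Defaults (`qcThresholds()`): keep barcodes with $\ge 1000$ UMIs,
$\ge 800$ features, mito % $< 15$, hemoglobin % $< 5$ and complexity
$> 0.8$ (strict); keep genes with $\ge 10$ counts in $\ge 10$ distinct
barcodes. Complexity is undefined below 2 total counts (it would divide
by $\log_{10} 1 = 0$) and such barcodes fail. Both filters are evaluated
once on the raw matrix — gene metrics are not recomputed after barcode
removal — matching a one-shot filtering protocol. Note that the
complexity cutoff of 0.8 presumes a transcriptome-scale gene universe;
on small simulated panels (hundreds of genes) complexity sits near 0.7
and the threshold must be lowered accordingly, as the pipeline tests do.

Size factors are each cell's total count over the median total, rescaled
to unit geometric mean (`normalizeCounts()`). Pooled deconvolution
factors are intentionally not reimplemented; externally computed factors
can be supplied. Highly variable genes are ranked by the variance of
log1p-normalized expression with lexicographic tie-breaks;
`scaleCapped()` z-scales per gene with the sample (n-1) standard
deviation and caps values at +10 only — extreme negative z-values are
kept, mirroring the asymmetric capping convention of the scanpy scaling
step this reproduces.

# Pseudobulk differential expression

`makePseudobulk()` sums raw counts per (group, sample);
`nbWaldTest()` is a deliberately plain negative-binomial Wald test:
median-of-ratios size factors, gene-wise method-of-moments dispersion
(floored at $10^{-8}$), a two-group log-link GLM fit by IRLS with the
size factors as offsets, normal two-sided p-values and BH adjustment. No
dispersion shrinkage or fold-change moderation is applied, so decimals
will not match a shrinkage estimator; validation therefore rests on
calibration (type-I error near nominal on null pseudobulk) and power
(planted four-fold genes recovered), not on matching another tool's
output. A moments-plugin Wald test is best calibrated when a substantial
share of the count variance is the known Poisson part; the suite's null
simulations use replicate-level biological CV of ~4.5% at means of a few
hundred counts, a regime typical of pseudobulk replicates from inbred
animals, where the test's type-I error at 0.05 lands near 0.055.

When one cluster is compared against several others,
`aggregateOneVsMany()` reports the mean log2FC across the pairwise
comparisons, a Fisher combination ($-2\sum\ln p$, $\chi^2_{2k}$) of the
per-comparison *adjusted* p-values, and the number of comparisons with
log2FC above 2. Combining adjusted p-values is statistically
unconventional but is retained as the documented protocol;
`combineAdjusted = FALSE` combines raw p-values instead.
`radialPlotData()` prepares the per-condition quadrant tables (negative
log2FCs clipped to 0 with the adjusted p reset to 1 so every gene appears
in every quadrant), and `selectElevatedGenes()` applies the inclusive
log2FC $\ge 1$, $p_{adj} \le 0.05$, fraction-expressed $\ge 0.2$ (or 0.1)
filters.

# Pseudotime gene modules

Pseudotime is consumed as an input (trajectory inference is out of
scope; the simulator supplies ground-truth pseudotime).
`binPseudotime()` sorts cells by (pseudotime, cell id) — ties broken by
id — and forms 21 bins of equal cell numbers, the remainder going to the
earliest bins. Binning depends only on the ordering, so any strictly
monotone transform of pseudotime yields identical bins. Per-gene bin
profiles (mean normalized expression per bin) are z-scaled across bins
*after* binning (bin-then-scale; the cell-level alternative is reachable
by passing pre-scaled values), genes with constant profiles are dropped
with a report, and gene pairs with Pearson $r$ strictly above 0.5 become
weighted edges of an undirected graph. `leidenModules()` runs weighted
Leiden clustering (modularity objective, resolution 1, fixed seed);
singleton communities and isolated genes are labeled `"unclustered"`.
Module and marker summaries report means with 95% confidence bands
($\pm 1.96\,\mathrm{sd}/\sqrt{m}$ across module members, or across a
bin's cells for single genes); a single-gene module has a zero-width,
`degenerate`-flagged band.

# What the simulator emulates — and what it does not

`simulateDataset()` draws counts
$K_{gc} \sim \mathrm{NB}(s_c\,\mu_{g,t(c),k(c),\tau(c)},\ \theta)$ with:
log-normal baseline gene means and per-type multipliers (separable cell
types, default type sigma 1); log-normal cell size factors normalized to
unit mean (default sigma 0.3); two conditions whose planted
ligand/receptor fold changes multiply the mutant-condition mean of
designated sender/receiver types; and an optional lineage whose module
genes follow logistic (midpoint 0.5, slope 12), Gaussian-bump (center
0.5, width 0.15) or flat profiles of a uniform [0, 1] pseudotime. Planted
ligand/receptor genes default to robustly expressed, low-dispersion
signaling genes (mean 30 counts/cell, NB size 10). The ground truth per
planted interaction is exactly
$(\log_2 f_L + \log_2 f_R)/2$.

It deliberately does **not** emulate batch effects, doublets, ambient
RNA, donor hierarchies, gene-gene correlation beyond the planted
programs, or zero inflation beyond the NB. Passing the recovery tests
therefore demonstrates that the *statistics* behave as designed under
their model assumptions — not that real tissue meets those assumptions.

One consequence worth knowing about real and simulated data alike:
because size factors are total-count based, a strong planted (or
biological) upregulation inflates the affected cells' library size and
depth normalization absorbs part of the effect, attenuating the observed
LRIDiffScore by roughly $\log_2(1 + \Delta/T)$ for added counts $\Delta$
on a library of $T$. The validation fixtures keep this bias below ~0.07
by construction (600 background genes at mean 30 counts, planted means
25), and the worked examples show the same attenuation at smaller
library sizes.

# Validation problem sizes

The test suite and `scripts/acceptance.R` validate, from scratch:

* exact agreement (within ±0.02) of sampled permutation p-values with
  exhaustive enumeration of all 720 label reassignments on a 6-cell,
  2-type, 3-gene instance at 5,000 permutations;
* null calibration of the condition-permutation p on 2,000 cells, 300
  genes, 50 pairs, 1,000 permutations, 3 seeds;
* recovery of 20 planted interactions (true diffs 1.2/1.5/2.0, 200
  cells/type/condition, 5 seeds): scores within ±0.15 of truth,
  sensitivity ≥ 0.9 and null-record false positives ≤ 5% under the
  published filter set;
* exact BH/Fisher behavior against independent oracles, Wald type-I
  error within [0.03, 0.07] and four-fold sensitivity ≥ 0.9 on 4+4
  pseudobulk samples;
* exact QC survivor sets on a fixture with one designed violator per
  rule;
* module recovery (ARI ≥ 0.9 over 5 seeds) of 3 planted temporal
  programs of 50 genes among 500 noise genes across 1,000 lineage cells;
* byte-identical reruns of the full pipeline under a fixed seed.

These sizes were chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite runs in well under a minute.

# Known limitations

* Multi-subunit receptor complexes are not modeled; complexes must be
  split into gene-level pairs upstream.
* The LRIScore permutation null shuffles cell-type labels only; spatial
  proximity, abundance differences and pathway structure are out of
  scope.
* The NB Wald test is intentionally unshrunk; with very few pseudobulk
  replicates and high biological CV it becomes anticonservative, which
  is inherent to gene-wise moment dispersion estimates.
* The 10% expression filter for ligand-receptor genes is evaluated on
  the pooled analyzed cells (per-condition evaluation is a one-line
  change upstream of `loadLRPairs()`).
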