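---
title: "Ecology-style analysis of dual-polarity LC-MS metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecology-style analysis of dual-polarity LC-MS metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolodiv)
```

## The analysis model

Untargeted LC-MS metabolomics produces, per electrospray ionization (ESI)
polarity, a feature table: rows are spectral features identified by a
mass-to-charge ratio and a retention time (an "m/z_rt" pair), columns are
biological samples, and cells are ion abundances. `metabolodiv` analyzes
such tables for a two-genotype (wild type vs the nitrate-reductase-null
*nia1/nia2* double mutant), two-nitrate-level (4 vs 0.2 mM), two-age
(15 vs 30 days after germination), two-organ (rosette vs root)
hydroponic *Arabidopsis thaliana* design, in four stages:

1. **Population diversity.** Each m/z_rt feature is treated as a species
   and each LC-MS run as a sampling unit. Observed richness S is
   complemented by nonparametric estimators built from incidence counts
   (Q1 = features seen in exactly one sample, Q2 = in exactly two, m
   samples): Chao1 ($S + Q_1^2 / 2Q_2$, or the bias-corrected
   $S + Q_1(Q_1-1)/2$ when $Q_2 = 0$) and the first- and second-order
   jackknives. Shannon diversity $H' = -\sum p_i \ln p_i$ (natural-log
   units) and Pielou evenness $J' = H'/\ln S$ summarize abundance
   structure; sample-based accumulation curves (exact rarefaction or
   seeded permutation averaging) separate the common core of the
   metabolome from its rare tail; rank–abundance curves are fitted
   against the broken-stick null, whose expected share at rank $i$ of
   $S$ is $\frac{1}{S}\sum_{k=i}^{S} 1/k$.
2. **Chemometrics.** Sample columns are quantile-normalized to the mean
   order-statistic profile, then $\log_2(x + 1)$-transformed. Structure
   discovery uses centered (unscaled) PCA and Ward clustering on the
   Pearson correlation distance $d_{ij} = 1 - r_{ij}$. Because
   unsupervised views of such designs are often inconclusive, the four
   design factors are also ranked by fitting a shallow regression tree
   per feature (intensity ~ factors) and aggregating each factor's
   variance reduction across features.
3. **Differential markers.** Within each genotype-by-organ cell, the
   4 mM and 0.2 mM nitrate groups are contrasted. The fold change is the
   ratio of group means with a pseudocount,
   $FC = (\bar{x}_A + c)/(\bar{x}_B + c)$, and a feature is a
   differential marker when $\max(FC, 1/FC) \ge 2$ (two-sided,
   inclusive). Calling is done **per ESI mode** and the per-mode
   differential sets are then unioned per contrast — pooling the raw
   libraries first would let polarity-specific ionization efficiency
   mask real signals (the mutual suppression effect). Across contrasts,
   markers are partitioned into unique (one contrast) vs shared (two or
   more).
4. **Annotation and enrichment.** A differential m/z is presumptively
   annotated by inverting adduct arithmetic, $M = |z| \cdot m/z -
   \Delta$, against a compound database of neutral monoisotopic masses
   within a ppm tolerance; every compound within tolerance is reported
   (no MS/MS confirmation is attempted). Annotated compound sets feed
   pathway over-representation: an upper-tail hypergeometric (Fisher)
   p-value and a seeded permutation null with the add-one estimator
   $p = (1 + \#\{k_{null} \ge k\})/(1 + B)$. Pathways are classed
   prevalent when enriched in strictly more than half of the contrasts,
   and activity is reported in the field's "k of K members" idiom.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mz_digits`, `rt_digits` | 4, 2 | rounding that defines feature identity; acquisition software tolerances vary, so this is configurable rather than inferred |
| `detection_threshold` | 0 | intensity strictly above it counts as presence |
| `pseudocount` (FC) | 1 | stabilizes ratios when a group mean is 0 (raw ion counts are large, so 1 is negligible elsewhere) |
| `fc_min` | 2 | two-sided differential threshold, inclusive |
| `p_max` | off | optional Welch-test ceiling on log2 intensities; off because the marker definition is fold-change-based |
| `ppm_tolerance` | 10 | annotation mass window, typical for high-resolution instruments |
| adduct set | +H/+Na/+K/+NH4; −H/+Cl/+HCOO | the common singly charged electrospray adducts; replaceable via a rule table |
| `n_permutations` (SAC) | 100 | orderings averaged for accumulation curves |

## What the synthetic generator emulates — and what it does not

`simulate_feature_table()` draws per-feature baseline abundances from a
log-normal (meanlog 8, sdlog 1.5), giving the few-dominant/long-tail
shape real feature communities show, and adds log-normal replicate noise
(sdlog 0.3 by default). A configurable fraction of features is "rare",
with a high per-sample dropout probability — this is what bends
accumulation curves and feeds Q1/Q2. Planted effects multiply the mean in
one factor's treatment level before dropout, so the true fold change is
well defined; affected sets are disjoint across effects and recorded in
the ground truth. Annotatable features take their m/z from an
adduct-transformed compound mass plus Gaussian ppm noise (sd 2 ppm);
decoys are placed at least three tolerances from every adduct-transformed
compound mass, giving unambiguous negative controls.

The generator does **not** simulate chromatography (retention times are
uniform draws), isotope patterns, correlated features from shared
precursors, inter-batch drift, or heteroscedastic intensity noise.
Passing recovery tests therefore show the pipeline's logic is correct
under its own assumptions — not that real nitrate-starvation data would
be recovered at the same rates.

Because the study's spectral libraries are not deposited,
`paper_scale_fixture()` rebuilds only the *set structure* of the
published bookkeeping (four contrasts per mode; 1818 = 998 unique + 820
shared ESI+ markers; 3214 = 1408 + 1806 ESI−; 735 annotations split
315/420 by genotype; 79 pathways = 16 single-contrast + 63
multi-contrast) so that the partition, summary and percentage machinery
can be exercised against known totals. Which features sit in which
contrast is synthetic and meaningless.

## Numerical choices

- **Percentages are truncated, not rounded, to two decimals**
  (`asymptote_summary()`, `partition_unique_shared()`): a reported share
  never overstates, and reported parts stay consistent with their
  printed totals.
- **Quantile before log.** Quantile normalization runs on raw
  intensities (zeros map cleanly); the log uses pseudocount 1 so zero
  maps to zero.
- **Ward on correlation distance.** Ward's criterion is derived for
  squared Euclidean distances; applying it to $1 - r$ (as metabolomics
  heatmap tools do) is a deliberate, documented approximation.
- **Rank–abundance goodness of fit** is the residual sum of squares on
  relative abundances, with a Gaussian-likelihood AIC; a perfect fit has
  deviance 0. Preemption fits its single parameter by golden-section
  search; the log-normal model fits two parameters to normal quantiles.
- **Second-order jackknife** uses the standard formula and *can* fall
  below observed richness when doubletons dominate singletons; no floor
  is imposed.
- **Compact letter displays** come from an insert-and-absorb pass over
  the Tukey HSD adjusted p-values.
- **Degenerate inputs** error early and name the offender: all-zero
  abundance vectors, constant samples under correlation, selectors that
  match no samples, partitions whose parts disagree with their totals
  (the summary report refuses to assemble).

## Design decisions that were genuinely open

- **Per-mode contrasts.** The four nitrate contrasts (genotype × organ)
  include both sampling ages on both sides, keeping time matched within
  a contrast; merged contrasts union the two modes' differential sets
  under the same labels.
- **FC on raw means.** Fold changes use raw group-mean intensities, not
  quantile-normalized values: quantile normalization equalizes column
  distributions, which is desirable for ordination but distorts
  between-group ratio magnitudes.
- **Incidence-based estimators.** Chao1/jackknife use presence across
  samples rather than abundance singletons, which are ill-defined for
  continuous intensities.
- **Per-feature trees.** Factor ranking fits one depth-limited
  regression tree per feature and aggregates importance, rather than one
  classifier over all features; with 16-sample designs a single deep
  model would overfit, and aggregation gives a variance-decomposition
  reading.
- **Diversity on summed replicates** per group by default (configurable
  to per-sample averaging): summing stabilizes the abundance-share
  estimates that H' needs at modest replicate counts.

## Problem sizes used by the test and acceptance suites

Recovery runs use 300 features per mode, a full 2×2×2×2 design with 6
replicates per cell, planted genotype effects at fold change 4 on 20% of
features, and sdlog-0.25 replicate noise; annotation recovery uses a
60-compound/6-pathway database with half of 120 features annotatable at
2 ppm noise against a 10 ppm tolerance; permutation enrichment uses 1000
draws. These sizes give the statistical properties being tested room to
express themselves while keeping a full run in seconds.

## Known limitations

- Annotation is presumptive (MSI level ~3): one m/z can and does map to
  several compounds, and KEGG-style codes inherit that ambiguity.
- The broken-stick comparison is a null-model fit, not a model-selection
  study; AIC values are comparable only across models fitted to the same
  ranks.
- The permutation null draws compounds uniformly, ignoring any mass- or
  pathway-size-dependent annotation bias; the Fisher p shares this
  assumption.
- No multiple-testing correction is applied to fold-change calling; the
  marker definition is a threshold rule, not an inference procedure.
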