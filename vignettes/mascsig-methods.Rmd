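---
title: "Methods: signature derivation, activation scoring and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, activation scoring and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mascsig)
```

This vignette records the statistical design of `mascsig`: the models behind
the synthetic generators, the definition of every estimator, and the
conventions (tie handling, tail directions, undetected-well coding) that a
reader needs to interpret results or reproduce them independently.

## The scientific workflow

The package implements the analysis chain used to derive a mammary stem cell
(MaSC) gene signature and test its prognostic value in breast cancer:

1. **Derivation.** Compare purified MaSC expression profiles against each
   differentiated population (myoepithelial, luminal ER−, luminal ER+) with a
   permutation-based moderated statistic (SAM), and keep the genes
   significantly up in the stem cells in *every* comparison. Intersecting all
   comparisons is what removes genes shared by the whole basal lineage.
2. **Scoring.** Summarise signature activation per tumour, either as the mean
   median-centred expression of the signature genes or as a
   relevance-network score that first prunes genes inconsistent with the
   signature's correlation structure.
3. **Stratification.** Dichotomise tumours on the score, compare survival by
   Kaplan-Meier/log-rank/Cox, and calibrate the result against
   expression-matched random gene lists.
4. **Companion analyses.** Nearest-centroid subtyping, hypergeometric
   gene-list overlap, and single-cell RT-qPCR co-expression with spike-in
   calibration.

Every step consumes data a laboratory could supply, and every generator in
the package produces data with planted ground truth so the chain is testable
end to end.

## Synthetic generators

### Purified populations (`population_design`, `simulate_populations`)

Genes × samples log2 expression over the four populations with replicate
counts `c(MaSC = 7, MYO = 3, LumERneg = 3, LumERpos = 3)` — the unbalanced
few-replicate layout typical of sorted-population microarray studies, and
deliberately the hard case for permutation inference (only 120 distinct
relabellings of 7v3). Defaults: 1000 genes, of which 100 `masc_up` (elevated
in MaSC only; the recoverable signature), 100 `basal_shared` (elevated in
MaSC *and* MYO; decoys that the intersection must reject), 100 `luminal_up`,
and 700 null. Planted effects add `effect = 2` on the log2 scale (4-fold).
Baselines are uniform on [4, 10]. Per-gene replicate standard deviations are
drawn from a scaled inverse chi-square (`noise_sd = 0.35`, `var_df = 20`), so
dispersion varies across genes as it does on real arrays — without that
heterogeneity the fudge-factor tuning in SAM would be pointless. At these
defaults the planted effect is large relative to replicate noise, as it is
for the strongly enriched genes a derivation is expected to recover; the
recovery tests in the package measure sensitivity against exactly this
design.

### Tumour cohort (`cohort_design`, `simulate_cohort`)

Each tumour carries a latent activation `A ~ N(0, 1)`. The 50 signature
genes load on `A` with unit loading plus `N(0, 0.5²)` residual noise;
500 background genes (ten per signature gene) are independent noise with
baselines drawn from the same distribution, which gives the expression-matched
random-list null an honest matching universe. Event times follow a
proportional-hazards model with hazard `h0 · exp(beta · A)`
(`h0 = 0.02`/month, `beta = log 2`), simulated by inverse transform, with
independent exponential censoring (rate 0.01). Note the planted truth is at
the level of the *latent* activation; the hazard ratio between
score-dichotomised groups is an induced, attenuated quantity, which is why
the package's coverage checks estimate it from a very large cohort run
through the identical pipeline rather than from `exp(beta)`.

### Single-cell qPCR panel (`single_cell_design`, `simulate_single_cells`)

32 cells × 12 genes. Detected Ct values are Gaussian per gene (mean 25,
SD 2), clamped to [10, 40]; each well drops out (fails to amplify) with
probability 0.1. Spike transcripts at 8400, 900 and 90 copies follow the
calibration line `Ct = 38 − slope · log10(copies)` with
`slope = log2(10) ≈ 3.3219` cycles per decade, i.e. 100% amplification
efficiency, plus 0.2 cycles of replicate noise.

## SAM: the moderated permutation statistic

For the two-class comparison, each gene gets
`d = (mean2 − mean1) / (s + s0)` where `s` is the two-sample pooled
standard error and `s0` the fudge factor: the percentile of the `s`
distribution (grid 0–100 by 5) minimising the coefficient of variation of
the MAD of `d` across `s`-quantile windows. `s0` stabilises `d` for
low-variance genes, which otherwise dominate the ranking at small `n`.

Significance comes from column relabellings. When the number of distinct
relabellings is at most 10,000 (e.g. 20 for 3v3, 120 for 7v3) they are
enumerated **exhaustively**, making the permutation null deterministic;
otherwise `n_perm` random relabellings are drawn from the stated seed.
Two quantities are reported per gene:

- **Global q-value**: expected number of permuted `|d|` values at or above
  the gene's `|d|` (mean across permutations) divided by the observed count,
  clamped to [0, 1] and made monotone from most to least significant. This is
  the classic tail-area FDR; some SAM implementations use the median rather
  than the mean permuted count, which is slightly more conservative.
- **Local FDR**: the ratio of permuted to observed density of `d` in a
  sliding window centred on the gene's `d` *value*, with half-width
  `window_frac = 0.025` of the observed `d` range, scaled by an estimate of
  the null proportion `pi0` (the share of observed `d` values inside the
  interquartile range of the permuted values). The window is defined in
  value space rather than rank space for a specific reason: with few
  replicates per group the permutation set contains near-identity
  relabellings that leak any true effect into the null, and a rank window
  wide enough to be stable (say 101 genes) can bridge the gap between a
  cluster of true positives and the null bulk, assigning the whole cluster
  the leaked null mass. A value window cannot span empty stretches of the
  `d` axis, so an isolated cluster of strong genes keeps a local FDR near
  the leakage floor instead of inheriting the bulk density. The cost is
  that the estimate becomes noisy where the observed density is very low;
  the `pmax(observed count, 1)` guard and the gene's own membership in its
  window bound the estimate at 1.

The multiclass statistic replaces the numerator with
`sqrt(sum(1/n_k) · sum_k n_k (mean_k − grand mean)²)` and the denominator
with the pooled within-group standard error; for two groups it equals
`|d|` exactly, which the test suite asserts.

## Derivation gates

A gene enters the signature if, in **every** comparison of MaSC against a
reference population, it is up (`d > 0`), has local FDR < 0.05, and linear
fold change ≥ 1.5. The "top" refinement keeps signature genes with fold
change strictly > 2.5 and FDR < 0.05 both against the myoepithelial
population and against the pooled luminal populations. Probeset filtering
precedes derivation: probes mapping to no gene or to several genes are
removed, and where several probes map to one gene the probe with the highest
mean expression is kept.

## Activation scores and dichotomisation

The averaged score median-centres each gene across the cohort and averages
the signature genes per tumour. The relevance-network score builds the
correlation graph over signature genes (edges where `r > 0.3` and the
two-sided correlation test passes a Bonferroni-corrected `alpha = 0.05` over
candidate edges — positive edges only, since all signature genes are
up-genes), keeps the largest connected component, iteratively drops genes
anti-correlated with the component's mean z-scored profile, and averages the
z-scored expression of what remains. If fewer than three genes survive, the
method falls back to the averaged score with a warning rather than scoring
on an unsupported network.

Dichotomisation conventions: `top_tertile` marks "high" every tumour whose
score is at least the 66.67th-percentile nearest-rank cutoff, so ties at the
cutoff join the high group; `median` marks "high" only scores strictly above
the median, so ties go low. Both conventions are asserted in the tests.

## Survival analysis and the matched random-list null

Kaplan-Meier, log-rank and Cox fits delegate to the `survival` package
(`survfit`, `survdiff`, `coxph` with **Breslow** tie handling), with
independent oracles — a manual product-limit worksheet, a risk-set-table
log-rank statistic and a brute-force partial-likelihood maximisation — kept
in the test suite. Cox intervals are Wald 95% intervals; a monotone
likelihood (e.g. all events in one group) is flagged and the interval
reported as (0, ∞).

The matched random-list null asks whether the signature's stratification
could arise from any gene list with the same size and expression profile:
genes are binned into deciles of mean expression, each random list draws a
same-bin non-signature gene per signature gene (bins short of genes widen to
their neighbours with a message), and the full score → dichotomise →
log-rank pipeline is rerun per list. The empirical p-value is
`(1 + #[null ≥ observed]) / (n_lists + 1)`, never exactly zero.

## Subtypes, overlap, single cell

Nearest-centroid classification assigns each tumour the subtype whose
centroid its profile correlates with best (≥ 10 shared genes required; ties
broken by subtype name order with a message; winning correlations below
`r_min = 0.1` flagged low-confidence). Per-subtype score summaries test
high-score enrichment with an upper-tail hypergeometric, BH-adjusted across
subtypes.

Gene-list overlap uses the upper-tail hypergeometric
`P(X ≥ k)` with an **explicit universe** — there is no default universe,
because the p-value is meaningless without one.

Single-cell conventions: `1/Ct` is the monotone expression proxy, and an
undetected well maps to `1/Ct = 0` (non-amplification read as absence) —
the alternative `undetected = "missing"` keeps `NA`. Per-gene CV uses the
population (n-denominator) standard deviation. Spike linearity regresses
pooled spike Ct on log10 copies; efficiency is `10^(−1/slope) − 1`, so the
ideal slope `−log2(10) = −3.3219` gives exactly 1 (100%). Co-expression
contingencies classify each cell by detection of two genes and report
percentages to one decimal place.

## Problem sizes and limitations

The defaults are desk-scale: 1000 genes × 16 arrays for derivation
(seconds), 550 genes × 500 tumours with 1000 matched random lists for
prognosis (seconds), 32 cells × 12 genes for the single-cell panel
(instant). Known limitations:

- The generators plant additive, homoscedastic-within-gene effects; real
  arrays have correlated probes, batch structure and intensity-dependent
  variance that the inverse-chi-square model only sketches.
- With 7v3 replicates the exhaustive permutation null contains the identity
  and near-identity relabellings, so local FDR estimates for true positives
  have a floor of roughly the leaked mass; the value-window estimator keeps
  this floor below the 0.05 gate at the default effect size, but very small
  effects will be conservative.
- The cohort model induces proportional hazards in the latent activation,
  not in the dichotomised group, so group-level hazard ratios are
  attenuated relative to `exp(beta)`; this mirrors real signature studies
  and is why coverage is assessed against the induced quantity.
- The relevance-network score assumes all signature genes are up-genes;
  signed signatures would need a signed-edge extension.
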