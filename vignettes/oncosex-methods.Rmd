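---
title: "Methods and design notes for oncosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for oncosex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosex)
```

`oncosex` chains five analyses around one biological question — why some
cancers, melanoma prominently, show a female excess during the
reproductive years, and how an E-cadherin-loss / GRPR axis could drive
sex-dependent metastasis. This vignette records the models, their
assumptions, the defaults that matter, and the design decisions that
were genuinely open.

## The premenopausal variation index

Incidence input is an already age-standardized rate (ASR, cases per
100,000 person-years) per cancer, sex and age bracket; the package never
performs age standardization itself. For each cancer the women/men ratio
is formed per bracket, and the PV index contrasts the premenopausal mean
ratio with the flanking life periods:

$$\mathrm{PV} = \mu_{\text{premenopause}} -
  \tfrac{1}{2}(\mu_{\text{prepuberty}} + \mu_{\text{postmenopause}})$$

with period boundaries at 15 and 55 years (configurable via
`age_periods()`). Decisions taken here:

* **Period membership is by bracket midpoint.** Published grids use
  5-year brackets that do not align with 15/55; the midpoint rule is
  unambiguous and never splits a bracket.
* **Period means are unweighted** across brackets. The index is a
  contrast of mean ratios over time periods, not a population-weighted
  rate; weighting would re-introduce the age structure the ASR already
  removed.
* **The default scale is the raw ratio**, with `log2_ratio` selectable.
  Ratios are conventionally logged for display, and the log2 scale has
  the attractive antisymmetry that swapping the sexes negates PV; both
  are supported, and the classification thresholds (±0.2) are applied to
  whichever scale is requested.
* **Boundaries classify as unbiased**: the rule is strictly
  PV > 0.2 → female-biased, PV < −0.2 → male-biased.
* **Zero-rate brackets** make the ratio undefined; they stay on the grid
  as `NA` and are excluded from period means. Only a fully undefined
  period is an error, which names the period.

The quartic trend fit (`fit_polynomial_trend()`, degree 4 by default) is
a least-squares fit of the log2 ratio against bracket midpoint — a
representation convention, not a mechanistic model. The concordance
check is an automated surrogate for eyeballing each fitted curve: it
averages the fitted polynomial over the three periods on a fine grid and
asks whether the resulting contrast agrees in sign with PV (trivially
concordant when |PV| ≤ 0.2, where no direction is claimed). Because PV
may be computed on the raw scale while the curve is fitted on log2, a
deliberately crafted curve can make them disagree — the test suite
contains such a counterexample — which is precisely the situation the
flag exists to surface.

`bias_enrichment_test()` asks whether the number of female-biased calls
among `n` classified cancers is surprising. The test identity behind the
published figure is not derivable from its description, so the package
declares its null: each cancer falls in one of three classes, a
female-biased call has null probability `p0 = 1/3`, and the p-value is
the exact binomial tail `P(X ≥ k)`. This is a documented choice, not a
claim about how the original number was obtained.

## Expression analyses

Matrices are genes × samples with a declared kind (`counts`, `tpm`,
`log2tpm`); TPM columns must sum to $10^6$ within $10^{-6}$ relative.
TPM normalization and median-of-ratios size factors follow their
textbook formulas.

**Differential expression is a declared stand-in**: Welch's t on
log2(TPM + 1) with Benjamini–Hochberg adjustment, and the log2
fold change is the difference of group means on that scale. Full
count-model engines (shrinkage, dispersion estimation) are out of this
package's scope; downstream stages only require a defined fold change
and p-value per gene. The pseudocount of 1 bounds the influence of
zeros; the practical consequence, visible in the recovery analyses, is
that a planted fold change is slightly compressed for genes whose
baseline is near or below 1 TPM. The significance flag combines
|log2FC| > 1 (the conventional threshold) with q < 0.05.

**LOWESS.** `lowess_smooth()` is a tricube-weighted local *linear*
regression evaluated on an explicit uniform grid of `n_points`
(default 1860) over the data range, with the window holding
`ceiling(span * n)` nearest points (span default 0.3). The grid size
default matches the smoothing convention used for expression-over-age
displays in this literature; what that number parameterizes there is
unstated, so here it is documented as the evaluation-grid size and is
freely configurable. Degenerate windows (zero spread) fall back to the
weighted mean. The suite checks the smoother against
an independently coded textbook implementation.

**Correlation with a sample score** is plain Pearson; zero-variance
genes are reported as missing, never coerced to 0, so that a flat gene
cannot masquerade as "uncorrelated with the invasive score".

## Signatures, states and GSEA

Signature scores average log2(TPM + 1) over the marker genes present;
absent genes are messaged, never imputed. For cross-signature
comparison — in particular the predominant-state call over the four
melanoma cell-state signatures — genes are z-scored across samples
first; otherwise a handful of highly expressed markers would dominate
regardless of state. Whether the original state calls standardized
scores is unstated, so both modes exist and standardization is required
only where scores of different signatures are compared against each
other. Constant genes get z = 0. Exact score ties are broken by the
fixed order pigmentation < SMC < invasive < NCSC and flagged.

YAP activation is scored as the mean per-target ratio of mean case TPM
to mean reference TPM with an ε = 0.01 TPM pseudo-rate; a raw-ratio
reading of "average fold change" is the default with a log2 option.
Mouse data are handled through a shipped two-column orthologue alias
table (case convention as fallback) rather than a live orthology
service.

The GSEA statistic is the classic weighted running sum with
weight p = 1 on |metric| (p = 0 gives the unweighted Kolmogorov–Smirnov
walk). Null calibration uses 1,000 seeded permutations per set. Which
permutation scheme the original analyses used is unstated, so both
standards are exposed: gene-tag permutation (random same-size sets on
the fixed ranking) whenever only a ranking is supplied, and
phenotype-label permutation (metric recomputed per permutation) when a
two-group expression design is supplied. Phenotype permutation preserves
inter-gene correlation and is therefore conservative for small, coherent
sets in small cohorts — the test suite exercises it at 20 samples per
group for that reason. NES divides ES by the mean same-sign null ES;
p-values are same-sign tail frequencies with add-one continuity; FDR is
the standard pooled-normalized-null ratio across the queried collection,
capped at 1. Reporting keeps sets with NES > 1.7 and FDR < 0.05, both
strict. A set covering the entire ranking admits no misses; its ES is
the degenerate value 1 and it is flagged rather than assigned NES/FDR.

## Survival

Stratification on a gene's TPM uses low ≤ 0.1 (clear negativity, a
factor 10 below the positive threshold) and high > 1 (the conventional
limit for sufficient protein expression); the intermediate band is
excluded *and reported*. Kaplan–Meier estimation and the unweighted
log-rank test are delegated to the `survival` package behind this
module's interface; the tests verify them against a hand-rolled
product-limit oracle and a direct hypergeometric observed-minus-expected
computation. Censoring tied with events at the same time is counted
after the events (the standard convention). Greenwood-variance
confidence bands are not reported by default.

## Cohort statistics

Chi-square has no Yates correction by default (a flag restores it) and
warns when an expected count drops below 5. Fisher's exact test is
two-sided by hypergeometric enumeration with optional Bonferroni over a
declared family size. Mann–Whitney switches from exact enumeration to
the tie-corrected normal approximation at a combined sample size of 12 —
mouse group sizes straddle this boundary, and the enumeration remains
exact under ties, which the closed-form exact distribution is not.
Kruskal–Wallis uses the tie-corrected H; Dunn's all-pairs z follow-up
adjusts with the eponymous Bonferroni-style correction by default
(BH selectable); which pairs the original comparisons covered is
unstated, so all pairs is the default. Lesions classify as
macro-metastases strictly above 0.1 mm. Venn intersection upper-cases
symbols by default (capitalized-mouse and no-normalization modes
provided) and reports every non-empty membership region plus the full
intersection.

The packaged five-list fixture for the intersection analysis is
*synthetic*: the real lists come from external pathway databases, so the
shipped GMT reproduces only the membership structure — four driver genes
(BRAF, CCND1, CDH1, KRAS) common to all five lists — and says so in its
filename.

## What the generators emulate — and what they do not

All four generators draw from one master seed, with a per-generator
stream derived from (seed, generator name), so adding one call never
perturbs another's output and identical configurations are
byte-identical.

* **Incidence**: a shared age-increasing baseline ASR for both sexes,
  the female premenopausal brackets multiplied by a per-cancer
  `bias_amplitude`, log-normal noise (sdlog 0.05 by default — a few
  percent of rate, typical of the year-to-year wobble in registry
  ratios).
* **Expression**: log-normal on the log2 scale (sd 0.5 by default,
  within the range seen for within-group biological variability of
  bulk RNA-seq), a designated GRPR-like gene shifted by
  `planted_gene_log2fc` in one group only, and optional per-signature
  group shifts; TPM mode renormalizes columns to $10^6$, counts mode
  draws negative-binomial counts around scaled means. The planted gene's
  baseline defaults to $2^6$ TPM so the log2(TPM + 1) fold-change
  estimate is not compressed by the pseudocount.
* **Survival**: exponential event times with the planted hazard ratio
  between strata and independent uniform censoring — the simplest
  non-informative scheme.
* **Metastasis**: per-group Bernoulli incidence, negative-binomial
  lesion counts among positive mice, log-normal lesion diameters
  centred at 0.1 mm so the micro/macro boundary is genuinely exercised.

None of the distributional choices is an inference about the real
cohorts; the sources publish no noise model. What passing tests
demonstrate is therefore *estimator correctness* — planted parameters
are recovered at the stated tolerances, null calibrations hold — not
that real melanoma data satisfy log-normality, proportional hazards or
independent censoring. Batch effects, mutational landscapes and
read-level artefacts are deliberately absent.

## Validation problem sizes

The shipped validation (test suite plus `scripts/acceptance.R`) uses
sizes chosen to make Monte-Carlo tolerances tight at desk scale: 200
synthetic cancers for PV class recovery at noise sdlog 0.05; 50 samples
per group for fold-change (±0.3) and signature-shift (±0.2) recovery;
100 samples across four archetype groups for ≥95% state recovery; 1,000
null survival replicates at 100 subjects per stratum for the log-rank
size and 150 replicates per hazard ratio for power; 500 random 10-gene
sets with 1,000 permutations each for the GSEA null. Reproducing the
published epidemiological classification itself (13 of 24 cancers
female-biased) would additionally require the external GLOBOCAN 2020
download, which the package intentionally does not fetch; the published
counts enter only as worked-example inputs to the exact tests.

## Known limitations

* The DE stand-in makes no variance-shrinkage claims; its gene-level
  values will not numerically match count-model engines on real data.
* Phenotype-permutation GSEA needs enough samples per group for a
  usable null (the permutation space at 3–4 per group is tiny).
* PV on the raw-ratio scale is not antisymmetric under sex swap (the
  log2 option is).
* The orthologue table covers the shipped signatures, not the genome.
* Survival utilities assume right-censoring only; no competing risks,
  no Cox modelling.
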