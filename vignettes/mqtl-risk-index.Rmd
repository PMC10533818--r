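---
title: "Methylation at mQTLs as a breast-cancer risk index: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation at mQTLs as a breast-cancer risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlrisk)
```

## The problem and the model

Polygenic risk scores (PRS) summarize static, heritable breast-cancer risk
as a weighted sum of effect-allele dosages,

$$\mathrm{PRS}_j = \sum_i \hat\beta_i \, x_{ij},$$

with $\hat\beta_i$ a published per-SNP log odds ratio and
$x_{ij} \in \{0,1,2\}$ the dosage in subject $j$ (`compute_prs()`). They
cannot, by construction, register environmental or lifestyle exposure.
DNA methylation at methylation quantitative trait loci (mQTLs) — CpG sites
whose methylation level is coupled to the genotype of a risk SNP — sits at
the interface: genotype sets a baseline, while age, body-mass index, and
hormonal exposure move methylation around it. A weighted sum of beta
values at selected mQTL CpGs can therefore act as a risk index that
integrates heritable and non-heritable components:

$$\mathrm{index}_j = \frac{\sum_i w_i \beta_{ij} - \mu}{\sigma},$$

where the weights $w_i$ come from a penalized logistic regression of case
status on mQTL-CpG beta values, and $\mu$, $\sigma$ are the mean and SD of
$\sum_i w_i \beta_{ij}$ over the discovery subjects, so discovery scores
have mean 0 and SD 1 (`finalize_index()`, `compute_index()`). Because the
index is scaled after summation, the logistic intercept is absorbed and
does not appear in scoring.

Surrogate tissue matters: the tissue at risk (breast) is inaccessible for
screening, so the index is meant to be measured in accessible
epithelial-rich samples. The `variability` helpers (`cpg_sd()`,
`top_variable()`, `stratified_variability()`) quantify the premise —
CpGs that are variable in breast tissue remain variable in cervical or
buccal epithelium but are attenuated in immune-dominated samples, because
bulk methylation mixes epithelial and immune signals in proportion to the
immune-cell fraction.

## Training and model selection

`fit_penalized_classifier()` fits lasso (L1) or ridge (L2) logistic
regression over a descending lambda path with 10-fold cross-validation
(folds stratified by case status; `glmnet` under the hood). The chosen
lambda minimizes mean cross-validated binomial deviance — the common
default; a one-standard-error rule is deliberately not used, and a fixed
`lambda` can be supplied to override CV. Candidate models (typically one
lasso and one ridge) are compared on held-out internal-validation AUC
(`select_model()`); exact ties go to the sparser model. The winner's
penalty is refit on the full discovery set and scaled
(`finalize_index()`).

Two choices here were genuinely open:

* **Discovery split.** Training versus internal validation defaults to
  2:1, stratified by case status; the fraction is a configuration value
  (`cohort_config()`), not a constant, because reasonable splits between
  60 and 70 percent are all defensible.
* **Degenerate lasso refits.** On signal-free data the CV-minimizing
  lasso is occasionally the intercept-only model; its raw index is
  constant and cannot be scaled ($\sigma = 0$), so `finalize_index()`
  refuses it. `run_pipeline()` then refits with ridge, which always keeps
  every coefficient non-zero; the resulting index scores at chance level,
  which is the correct behaviour for a null cohort. Outside the pipeline
  the error is surfaced, because a silent fallback would mask a
  mis-specified analysis.

A note on interpretation: cross-validated lasso at the deviance-minimizing
lambda reliably *includes* the informative CpGs but also over-selects —
it is not model-selection consistent. Selected CpG sets should be read as
"contains the signal", not "is the signal"; the test-suite checks full
recall of planted CpGs and strong enrichment over the base rate, not
perfect selection precision.

## Risk groups and exact 2x2 inference

`median_split()` labels a subject *high* when the score is strictly above
the within-set median ("equal to or below" is low), and medians are always
computed within a set (discovery and validation separately), never pooled.
`combine_groups()` crosses the PRS and index labels into four groups with
low/low as reference.

Group odds ratios use **median-unbiased estimation under Fisher's
noncentral hypergeometric distribution** with mid-p corrections
(`median_unbiased_or()`): conditioning on both margins of the 2x2 table
leaves a single noncentrality parameter $\psi$ (the conditional odds
ratio); the estimate is the $\psi$ at which the mid-p tail probability —
$P(X < a) + \tfrac12 P(X = a)$ — equals one half. Because the two mid-p
tails sum to one exactly, this $\psi$ is unique, and is found by bisection
on $\log\psi$ to tolerance $10^{-8}$ within a bracket expanded around the
crude cross-product ratio. The 95% interval inverts the mid-p tails at
0.025 per side, and the p-value is the two-sided mid-p at $\psi = 1$.
Zero cells are legal: the estimate or an interval end is then 0 or
$\infty$. Two properties worth knowing:

* the mid-p estimate is *less extreme* than both the crude ratio and the
  conditional maximum-likelihood estimate (it shrinks toward the null) —
  this is expected behaviour, not a defect;
* feeding the published per-group counts for the combined risk groups
  through this machinery reproduces the published odds ratios and
  intervals to their printed precision (`reproduce_table1()`), which is
  the acceptance check the package ships.

`quantile_or_curve()` applies the same estimator across percentile bins of
one score or of the sum of two standardized scores.

## Genotype QC and the HWE exact test

`qc_filter()` removes subjects with call rate below 95% first, then SNPs
with missing rate above 5%, minor allele frequency below 1%, or an exact
Hardy-Weinberg test p below $5\times10^{-6}$ — in that order, each SNP
recorded with the first filter it fails. `hwe_exact_test()` conditions on
the observed allele counts and enumerates every compatible heterozygote
count; the two-sided p sums the probabilities of configurations no more
likely than the observed one (probability-mass ordering). Missing dosages
in scoring are imputed as twice the cohort effect-allele frequency.
Weights read against a VCF are harmonized to REF/ALT coding — effect
allele on ALT kept, on REF sign-flipped, strand flips resolved by
complementation — with ambiguous A/T and C/G SNPs used as-is under a
warning, because strand cannot be inferred for them without frequencies.

## Permutation null for index specificity

`permutation_null()` asks whether the mQTL CpG set is better than an
equally sized random set: each permutation samples the same number of CpGs
from the non-mQTL pool, retrains the lasso on the training split
(re-randomized CV folds from the permutation's child seed), and scores the
held-out validation set. The defaults retrain on the training split only,
mirroring how the real index was built. The result is an AUC distribution
whose median and central 95% band the real index should clear when its
CpGs carry specific information.

## The synthetic cohort generator

Every stage is testable without controlled-access data because
`generate_cohort()` emulates the statistical structure the analysis
assumes. Per CpG $i$, subject $j$, and tissue, the epithelial logit is

$$\ell_{ij} = b_i + \textstyle\sum_s e_{is} x_{js} + \delta_i\,\mathrm{case}_j
 + a_i\,\mathrm{age}^c_j + m_i\,\mathrm{BMI}^c_j + \varepsilon_{ij},
 \qquad \varepsilon_{ij} \sim N(0, \tau^2),$$

and the observed beta mixes epithelial and immune compartments:

$$\beta_{ij} = (1 - f_j)\,\mathrm{logistic}(\ell_{ij})
 + f_j\,\mathrm{logistic}(b^{\mathrm{imm}}_i).$$

Additive Gaussian noise on the logit scale keeps betas in $[0,1]$ without
truncation (a logit-normal methylation model); age and BMI are centred
within the cohort so baselines are population means; one master seed
expands deterministically into per-stage child seeds (`child_seeds()`).

Default conditions (fixed once, used by the test-suite):

| quantity | default | rationale |
|---|---|---|
| SNP panel | 50 SNPs, MAF ~ U(0.05, 0.5) | mQTL catalogues restrict to MAF > 5% |
| PRS weights | N(0, 0.1) | typical published log-OR magnitudes |
| mQTL CpGs | 120 unique, 130 SNP-CpG pairs | desk-scale mirror of an 822-pair / 704-CpG catalogue |
| background CpGs | 880 | permutation pool |
| mQTL effects | sign-random U(0.2, 0.8) logits/allele | visible but not dominant coupling |
| set sizes | 600 / 300 / 300 | train / internal validation / validation |
| case fraction | 1/3 | case-control enrichment typical of such designs |
| case effect | 0.15 logits on 30 mQTL CpGs | yields validation AUC around 0.7-0.8, the regime of interest |
| age / BMI effects | 0.01 / 0.02 logits per centred unit on 30 CpGs each | weak covariate structure |
| logit noise | SD 0.5 (cervical) | moderate residual variability |
| immune fraction | Beta(2, 6) cervical; Beta(50, 2) blood | epithelial-rich vs immune-dominated samples |

What the generator does **not** emulate: array chemistry, probe types,
batch or chip effects, detection failures, genotype imputation error,
population structure, and relatedness. Passing tests therefore show the
statistical machinery is correct under the assumed generative model, not
that the index would attain any particular performance on real arrays.
Real mQTL effect sizes are also not published in a usable form; the
defaults are chosen for testability, not field calibration.

## Numerical choices

* Bisection for $\psi$ on the log scale, tolerance $10^{-8}$; unreachable
  targets (observed count at the support edge) return 0 or $\infty$
  instead of failing.
* HWE probabilities are computed from log-factorials and renormalized on
  the support, exact to ~$10^{-13}$ for totals in the QC range.
* The paired Wilcoxon test enumerates the exact sign-flip null by dynamic
  programming over doubled midranks for $n \le 25$ (tied differences are
  legal, unlike the exact path of `stats::wilcox.test`); larger $n$ uses
  the normal approximation with continuity correction. Unpaired
  comparisons default to Welch's t-test.
* AUC is the Mann-Whitney concordance probability with ties counted 1/2;
  its CI is DeLong's. Score direction is fixed (higher = case-like) so a
  worse-than-chance model reports AUC < 0.5 rather than being silently
  flipped.
* `top_variable()` takes the `ceiling` of the percentile count (a "top
  1%" request at small n never returns an empty set) and breaks SD ties
  lexicographically by CpG id, making selections deterministic.
* Immune-fraction bins default to [0, 0.25), [0.25, 0.75), [0.75, 1];
  only the 25% cut is anchored in practice, so the breaks are
  configurable.

## Problem sizes in the shipped checks

The test-suite exercises the default cohort (1200 subjects, 1000 CpGs)
for signal recovery (10 seeds), null calibration (20 seeds), and a
100-permutation specificity null; oracle comparisons cover all 2x2 HWE
tables with up to 50 subjects and 200 random contingency tables with up
to 40 entries. These sizes were chosen so that a full run remains a
desk-scale computation while keeping the stochastic checks' sampling
error well inside their acceptance margins.

## Known limitations

* The index's real-world performance claims are outside what synthetic
  cohorts can establish; the package validates machinery, determinism,
  and exact inference, and can load published CpG weight tables when
  available.
* Covariate-adjusted (regression) odds ratios are out of scope; all 2x2
  inference is conditional and unadjusted.
* Cell-type deconvolution is consumed as an input (`immune_fraction`),
  never estimated.
* Genotype phasing, imputation, relatedness, and ancestry analyses are
  upstream of this package and assumed done.
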