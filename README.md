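# mqtlrisk

Breast-cancer risk stratification that combines a **polygenic risk score**
(PRS) with a **methylation risk index built on mQTL CpGs** — CpG sites
whose DNA methylation is coupled to the genotype of breast-cancer risk
SNPs. The PRS captures static heritable risk; methylation at the same
loci, measured in an accessible hormone-sensitive surrogate tissue
(cervical or buccal epithelium), additionally records non-heritable
exposure such as age and body-mass index. The package is written for
epigenomics and genetic-epidemiology analysts who want the full pipeline —
simulation, training, scoring, QC, exact inference, permutation
specificity — as tested, composable R functions.

## The statistics at the core

**Risk index.** A lasso (or ridge) logistic regression on mQTL-CpG beta
values yields weights $w_i$; the index for subject $j$ is

$$\mathrm{index}_j = \Big(\sum_i w_i \beta_{ij} - \mu\Big)\big/\sigma,$$

with $\mu,\sigma$ the mean and SD of $\sum_i w_i\beta_{ij}$ over the
discovery subjects, so discovery scores have mean 0 and SD 1. Lambda is
chosen by 10-fold cross-validated binomial deviance; lasso vs ridge is
decided on internal-validation AUC; the winner is refit on the whole
discovery set.

**PRS.** $\mathrm{PRS}_j = \sum_i \hat\beta_i x_{ij}$ over published
per-SNP log odds ratios and effect-allele dosages, after call-rate, MAF,
and exact Hardy-Weinberg QC.

**Risk groups and exact odds ratios.** Subjects are split at the
within-set median of each score (strictly above = high) and crossed into
four groups. Each group's odds ratio versus the low/low reference is the
**median-unbiased estimate under Fisher's noncentral hypergeometric
distribution with mid-p corrections**: the odds ratio at which the mid-p
tail probability equals 1/2, with 95% limits from mid-p tail inversion at
0.025 per side.

**Specificity.** A permutation null retrains the lasso on random
non-mQTL CpG sets of the same size and collects held-out AUCs; a specific
index should clear the null's 97.5th percentile.

## Worked example

Everything runs on a synthetic cohort whose generative model (genotypes
under Hardy-Weinberg, genotype-coupled logit-normal methylation,
covariate and case effects, epithelial/immune mixing) is itself part of
the package:

```r
library(mqtlrisk)

run <- run_pipeline(pipeline_config(seed = 7, n_perm = 100))
run
#> <wid_run> L1 index with 64 CpGs; internal AUC 0.778; validation AUC 0.787
#>   permutation null median AUC 0.500
```

The lasso was preferred over ridge on internal validation, kept 64 CpGs,
and the finalized index separates held-out cases from controls at AUC
0.79 — while the same training applied to random non-mQTL CpG subsets
stays at chance (median 0.50), i.e. the signal is specific to the planted
mQTL CpGs:

```r
glance(run$permutation)
#> # A tibble: 1 × 5
#>   n_perm n_cpgs median_auc band_low band_high
#>    <dbl>  <int>      <dbl>    <dbl>     <dbl>
#> 1    100    120        0.5    0.458     0.527
```

Combining the index with the PRS by median split gives the four risk
groups and their exact odds ratios versus low/low (validation set of this
simulated run):

```r
run$strata$validation
#> # A tibble: 4 × 7
#>   group     cases controls or_hat ci_low ci_high        p
#>   <fct>     <int>    <dbl>  <dbl>  <dbl>   <dbl>    <dbl>
#> 1 low/low       6       60   1    NA       NA    NA
#> 2 high/low     14       70   1.97  0.731    5.95  1.85e-1
#> 3 low/high     45       39  11.1   4.60    31.8   3.68e-9
#> 4 high/high    34       32  10.2   4.11    29.9   6.89e-8
```

Here the methylation index drives the stratification (the PRS in this
simulation is noise by construction), so "high index" rows carry the
elevated odds ratios; the mid-p p-values quantify each contrast against
the reference group.

The same exact-inference machinery applied to the published per-group
counts of the combined risk groups reproduces the published odds ratios
and intervals:

```r
reproduce_table1()
#> # A tibble: 8 × 8
#>   set        group     cases controls or_hat ci_low ci_high         p
#>   <chr>      <chr>     <int>    <int>  <dbl>  <dbl>   <dbl>     <dbl>
#> 1 discovery  low/low      16      301   1    NA       NA    NA
#> 2 discovery  high/low     23      221   1.95  1.01     3.86  4.69e- 2
#> 3 discovery  low/high     89      155  10.7   6.21    19.5   0
#> 4 discovery  high/high   184      132  25.9  15.3     46.6   0
#> 5 validation low/low      14       70   1    NA       NA    NA
#> 6 validation high/low     18       59   1.52  0.694    3.38  2.96e- 1
#> 7 validation low/high     24       53   2.24  1.07     4.87  3.29e- 2
#> 8 validation high/high    55       28   9.60  4.71    20.7   4.22e-11
```

rounding to two significant figures gives the published 1.9 / 11 / 26
(discovery) and 1.5 / 2.2 / 9.6 (validation).

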