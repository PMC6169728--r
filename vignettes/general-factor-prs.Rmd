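---
title: "Linking polygenic scores to a general factor of childhood psychopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking polygenic scores to a general factor of childhood psychopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genfactor)
library(dplyr)
```

## The scientific problem

Children who screen high on one psychiatric symptom dimension tend to screen
high on many. A long-standing account of this comorbidity is a *general
psychopathology factor* ("p factor"): a single latent dimension on which all
symptoms load, over and above dimension-specific factors. A complementary
question from psychiatric genetics is whether common-variant risk for one
disorder — ADHD, with SNP-heritability around 0.22, being the best-powered
childhood example — acts on that general liability or on specific symptom
dimensions.

`genfactor` implements the full analysis chain needed to ask that question in
a twin cohort with parent-rated 0/1/2 symptom items:

1. **PRS construction** from GWAS summary statistics with PLINK-equivalent
   semantics (standardized betas, QC filters, greedy LD clumping,
   no-mean-imputation scoring across p-value thresholds);
2. **ordinal moment estimation**: polychoric correlations among items,
   polyserial correlations between items and continuous covariates, Pearson
   among covariates;
3. **structural models**: a correlated-factors model and a general-factor
   (bifactor) model fitted by diagonally weighted least squares (DWLS), with
   every latent factor regressed on the PRS and covariates inside the same
   fit;
4. **inference** that respects the twin design: family-cluster sandwich
   standard errors and mean-adjusted (scaled) test statistics, including a
   scaled chi-square difference test of the nested model pair;
5. **psychometric summaries**: explained common variance (ECV), domain-wise
   loading summaries, and per-path variance explained $R^2 = \beta^2$.

Because individual-level cohort data of this kind are not public, the package
ships a synthetic twin-cohort generator whose generating model *is* the
fitted model family, which makes parameter recovery a meaningful correctness
check for the whole chain.

## The models

Let $y_i^*$ be the latent response underlying ordinal item $i$, discretized
by thresholds $\tau_{i1} < \tau_{i2}$ (three categories). With specific
factors $S_{f}$, an optional general factor $G$, and covariates $x$ (PRS,
sex, age, principal components):

$$y_i^* = \lambda_{g,i} G + \lambda_{s,i} S_{f(i)} + \varepsilon_i, \qquad
  F = \Gamma x + \zeta,$$

where $F$ stacks $G$ and the $S_f$. All latent variances are fixed at 1, so
loadings and regression coefficients are standardized; residual correlations
between $G$ and the $S_f$ are fixed at 0 while specific–specific residual
correlations are free. The correlated-factors model is the same structure
without $G$, and is therefore nested in the general-factor model.

Model-implied correlations are fitted to the sample moments by minimizing

$$F(\theta) = \sum_k \frac{(s_k - \sigma_k(\theta))^2}{w_k},$$

where $s$ collects the polychoric/polyserial/Pearson correlations and $w_k$
is each moment's asymptotic variance (the DWLS weights). The
covariate–covariate block is held fixed at its sample values and excluded
from the moment vector; thresholds are fixed from the univariate margins and
not counted. This bookkeeping convention is deliberate and fixed: with the
62-item / 9-covariate A-TAC design it yields model degrees of freedom 2287
(correlated factors) and 2216 (general factor), i.e. a difference of exactly
71 = 62 general loadings + 9 general-factor regression paths, matching the
published fit table for this design.

## Estimation choices

**Two-step polychorics.** Thresholds are estimated from the margins by
normal-quantile inversion and held fixed; the correlation then maximizes the
bivariate-normal orthant likelihood (Gauss–Legendre quadrature of the
single-integral identity for the bivariate normal CDF; 32 nodes give
rectangle probabilities accurate to ~1e-10 for $|\rho| \le 0.95$). This is
the standard practice behind ordinal SEM software. Estimates at the boundary
are clipped to $\pm 0.999$ with a warning.

**Polyserial as ordinal probit.** For an item against a continuous covariate
the continuous margin drops out of the likelihood, so the two-step ML
estimator is the ordinal-probit regression of the item on the standardized
covariate. A useful consequence: the estimator remains consistent for
$\mathrm{cor}(x, y^*)$ whenever $y^* \mid x$ is normal with linear mean,
even when $x$ itself is binary (sex) or bimodal (age measured at 9 or 12).

**Influence functions, not information matrices.** Each correlation's
asymptotic variance — and everything robust built on it — comes from
per-observation influence functions of the two-step estimator, including the
propagation of threshold-estimation error (numeric cross-derivatives of the
mean score). These influence columns are stored in the `mixed_cor` object,
so the fit can form both the naive and the family-clustered covariance of
the moment vector: the sandwich
$(\Delta'W\Delta)^{-1}\Delta'W\,\Gamma\,W\Delta(\Delta'W\Delta)^{-1}$ with
$\Gamma$ aggregated within families. A simulation check (500 replicates,
n = 2000) keeps the ratio of influence-function variance to replicate
variance inside [0.8, 1.25].

**Robust test statistics.** The model test statistic is mean-adjusted,
$T/c$ with $c = \mathrm{tr}(U\Gamma)/df$; CFI and RMSEA (with a 90% interval
by noncentrality inversion) are computed from the scaled statistics against
an independence baseline on the same moments. The nested comparison needs
more care: $T_r - T_f$ is asymptotically a weighted sum of chi-squares with
weights from the spectrum of $M = (U_r - U_f)\Gamma$, and for the
bifactor-vs-correlated comparison that spectrum is highly dispersed — when
the general loadings are truly zero the restricted model sits at a boundary
with (near-)singular information, and our null simulations showed a
mean-only scaled difference rejecting a true restricted model about 31% of
the time at the 5% level. The difference test therefore matches the first
*two* moments of the spectrum (Satterthwaite):
$\Delta T^* = (T_r - T_f)\,\mathrm{tr}(M)/\mathrm{tr}(M^2)$ referred to
$\chi^2$ with $df^* = \mathrm{tr}(M)^2/\mathrm{tr}(M^2)$ — the construction
behind robust DIFFTEST-style comparisons. Equivalence with proprietary
implementations is claimed only at the level of type-I error and power
calibration, which the test suite measures directly, not digit identity.

**Optimization.** The weighted residual vector is minimized by
Levenberg–Marquardt (`minpack.lm::nls.lm`) from neutral starting values
(loadings 0.5, residual correlations 0.2, regressions 0), with box bounds
(|loading| ≤ 0.995, |residual correlation| ≤ 0.95) and a smooth penalty
keeping latent residual variances positive. Sign indeterminacy is resolved
by constraining each factor's first loading to be positive (regression rows
and residual correlations flip with the factor). Non-convergence raises an
error carrying the diagnostics; implied item communalities above 1 raise a
Heywood warning.

## The synthetic cohort

`sim_config()` fixes the reference study conditions; `simulate_cohort()` is
fully deterministic given the seed.

* **Discovery GWAS**: `n_variants = 500` variants, 20% causal, standardized
  effects summing to SNP-heritability 0.22, effective n 51,000 (the scale of
  a 20k-case ADHD case–control meta-analysis). Per-variant
  $z = \sqrt{n_{eff}}\, b\sqrt{2p(1-p)} + N(0,1)$. Small configured
  fractions of indel, strand-ambiguous, and low-INFO records exercise the QC
  filters.
* **Twin genotypes**: parental haplotypes drawn from the allele frequency,
  Mendelian transmission; MZ pairs (deterministically the first
  `round(mz_fraction * n_families)` pairs, default a third) copy dosages;
  DZ co-twins share each parental allele with probability 1/2. An optional
  exchangeable block-LD mode exists solely to exercise clumping; realistic
  LD is out of scope.
* **Latent structure**: the true polygenic score (standardized) loads on the
  general factor with `gamma_gp = 0.10` and on the specific
  hyperactivity/impulsivity factor with `gamma_hi = 0.07` — the magnitudes
  reported for ADHD PRS in population twin data. Sex (0.15) and age (−0.05)
  act on the general factor. Each factor carries a family-shared residual
  with variance share 0.2; published sources give no generative value, and
  only the presence of clustering matters for the sandwich checks.
* **Items**: the default measurement design is a compact 4-scale × 4-item
  version of the questionnaire structure (inattention,
  hyperactivity/impulsivity, oppositional-defiant, depressive). General
  loadings decrease and specific loadings increase within each scale.
  Besides resembling published loading tables, this non-proportionality is
  load-bearing: when $\lambda_g \propto \lambda_s$ within every scale, the
  bifactor model with correlated specifics is empirically unidentified
  (general-factor variance can be traded against specific-factor
  correlations), and the compact design must avoid that degeneracy.
  Thresholds default to (0.8, 1.8): roughly 79/18/3% category prevalences,
  as seen for rare-ish parent-endorsed symptoms.
* **Flags**: four exclusion conditions at prevalence 0.002 each; an
  ICD-like ADHD register flag with logistic dependence on the endorsed
  ADHD symptom count; the case definition is register flag or ≥ 8 endorsed
  symptoms on either ADHD dimension.

What the generator does *not* emulate — realistic LD, ascertainment and
attrition, rater effects, item-specific method variance — bounds what
passing tests show: they demonstrate that the estimation chain recovers the
truth when the model family is correctly specified, not that the model is
correct for any particular questionnaire.

## Calibration and recovery checks

The test suite measures, at the reference conditions:

* recovery of `gamma_gp` and `gamma_hi` (200 replicates, 2000 families):
  median estimates land within ±0.03 of truth (0.102 and 0.065 against
  generating values 0.10 and 0.07) and 95% sandwich-interval coverage
  inside [92%, 98%] (measured 0.95 and 0.98);
* type-I calibration of every PRS path and of the scaled difference test
  under zero generating effects (200 replicates, 1000 families, 4 × 3
  items), against exact binomial bounds at the 5% level. Measured per-path
  rates are 0.055–0.085; one of the four paths exceeds the exact binomial
  band by a single rejection, consistent with the mild finite-sample tail
  inflation discussed under limitations (empirical sd-to-SE ratios are 1.0
  within Monte Carlo noise);
* oracle equivalence: polychoric two-step estimates against a brute-force
  likelihood grid (step 1e-3, rectangle probabilities from an independent
  implementation) within 2e-3; greedy clumping against an exhaustive
  reference on all instances up to 6 variants.

Problem sizes in the simulation checks (items per scale, families,
replicate counts) are the package's chosen reference conditions for a
laptop-scale test run; the same machinery runs unchanged at the full 62- or
99-item designs via `atac_design()` / `smfq_scared_design()`.

## Design decisions that were genuinely open

* **Standardized beta conversion**: $\beta_{std} = z/\sqrt{2p(1-p)(n_{eff} +
  z^2)}$, the standard summary-statistic conversion; the denominator is
  overridable.
* **Scoring semantics**: PLINK 1.9 `--score` defaults — average per allele
  over non-missing variants — combined with `no-mean-imputation`: missing
  genotypes contribute to neither numerator nor denominator.
* **Strand ambiguity** is defined as A/T or C/G allele pairs.
* **Clumping LD** is computed on the target panel (no external reference is
  assumed), window ±1000 kb on the same chromosome, $r^2 > 0.1$.
* **Seven p-value thresholds** default to 1e-5, 1e-4, 1e-3, 0.01, 0.1, 0.5,
  1 (the exact published set between 0.00001 and 1 is not enumerated in main
  text; the grid is configurable), with 0.5 as the main-analysis threshold.
* **Pairwise-complete moments** with a minimum pairwise n of 50; children
  missing more than 20% of a design's items are dropped from that run.
  Items with any category under 5 endorsements trigger a warning only — the
  published analyses dropped sparse panic-disorder items without stating a
  numeric rule, so automatic exclusion is left to the analyst.
* **Sparse-data repair**: if the assembled correlation matrix is not
  positive semi-definite, eigenvalues are floored at 1e-6 and the matrix
  rescaled to unit diagonal, with a logged message.
* **MZ deduplication** drops one twin per MZ pair by a seeded uniform
  choice; sex differences are assessed by stratified refits (sex removed
  from the covariates), not interaction terms.

## Known limitations

* The SMFQ/SCARED published design reports a nested-test df difference of
  107 where enumeration of the structure (99 loadings + 9 paths) gives 108;
  the discrepancy is unexplained in the source and df assertions are
  therefore made only for the A-TAC design.
* The difference test for bifactor-vs-correlated comparisons sits on a
  boundary of the parameter space when all general loadings are truly zero:
  the general loadings then have singular information (they enter the
  implied moments only through products), the bifactor fit absorbs sampling
  noise adaptively, and the mean of the raw difference statistic exceeds
  the tr(M) its linearized spectrum predicts. In the package's null
  simulations (200 replicates, 1000 families) the Satterthwaite-adjusted
  difference test rejects a true correlated-factors model about 27% of the
  time at the 5% level — better than the mean-only scaled difference (31%)
  but far from nominal, and no statistic built from the two fits' summary
  quantities can repair this. The same test *is* calibrated for regular
  interior nestings (e.g. fixing a single regression path at its true
  value; verified in the test suite), and it has essentially unit power
  when a general factor is present. Practical advice: treat a significant
  bifactor-vs-correlated difference test as descriptive support, not as a
  calibrated hypothesis test of the general factor's existence — a caution
  that applies equally to the proprietary difference-testing procedures
  this one mirrors.
* Full-information ML for ordinal data, Bayesian estimation, measurement
  invariance, and realistic LD simulation are out of scope.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(sim_config(n_families = 2000, seed = 1))
cfg <- analysis_config(
  factors = split(sim$truth$loading_plan$item, sim$truth$loading_plan$factor),
  covariates = c("prs", "sex", "age")
)
res <- run_analysis(sim$cohort, sim$panel, sim$sumstats, cfg)
res$ecv
latent_regressions(res$fits$general) |> dplyr::filter(covariate == "prs")
res$difftest
autoplot(res$fits$general)
```

The printed ECV, PRS paths, and difference test have the same layout as the
published tables this pipeline mirrors, so results from real cohort files
(`read_cohort()`, `read_genotype_vcf()` / `read_traw()`, `read_sumstats()`)
drop into the same reporting code.
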