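---
title: "Pedigree variance components for thyroid traits: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree variance components for thyroid traits: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyrovc)
```

## The model family

All three analyses in this package are Gaussian variance-components
models over small family blocks. Within a block of $n$ individuals with
kinship matrix $\Phi$ (so $2\Phi$ is the additive relationship matrix),
a trait vector $y$ follows

$$ y \sim \mathrm{MVN}\!\left(X\beta,\; \Sigma\right), \qquad
   \Sigma = \sum_k \theta_k V_k $$

where the structure matrices $V_k$ encode the model:

* **Univariate ACE**: $V = \{2\Phi,\, H,\, I\}$ with coefficients
  $(\sigma^2_g, \sigma^2_c, \sigma^2_e)$. $H$ is the shared-household
  indicator; households are equated with family blocks, which matches a
  survey design in which each sampled family is one household. The AE,
  CE and E submodels drop terms.
* **Sex-limitation**: $V$ splits $2\Phi$ by the sexes of each pair
  (male–male, female–female, male–female) plus sex-specific diagonals,
  with coefficients $(\sigma^2_{gM}, \sigma^2_{gF},
  \sigma_{gM}\sigma_{gF}\rho_{gMF}, \sigma^2_{eM}, \sigma^2_{eF})$.
  Unique environment never crosses individuals, so opposite-sex
  environmental covariance is zero by construction.
* **Bivariate**: two traits per individual, stacked trait-within-
  individual, $\Sigma = 2\Phi \otimes G + I \otimes E$ with 2×2
  genetic/environmental covariance matrices parameterized by SDs and the
  correlations $\rho_g, \rho_e$.

The total log-likelihood is the sum over blocks. One compiled routine
(`src/loglik.cpp`) evaluates every model: it Cholesky-factorizes each
block's $\Sigma$, accumulates the GLS cross-products, and profiles the
fixed effects $\beta$ out analytically — since $\beta$ enters linearly,
its profiled value is the exact ML estimate, and the outer optimization
runs only over the variance parameters. A non-positive-definite
$\Sigma$ (including PSD-singular cases with a zero Cholesky pivot, and
overflowed coefficients) returns a defined failure value that the
optimizer treats as an infinitely bad point rather than an error.

### Estimation choices

* **Full ML, not REML.** The analysis workflow compares nested models
  with identical fixed effects by likelihood-ratio tests; full ML makes
  those likelihoods directly comparable. The cost is the usual small
  downward bias in variance estimates, negligible at the ~2,300-subject
  design scale (the recovery suite bounds the h² bias below 0.02).
* **Parameterization.** Variances are optimized as log-variances,
  correlations through atanh (or a logistic map onto $[0,1]$ for
  $\rho_{gMF}$, whose default range treats 1 as the tested upper
  limit; $[-1,1]$ is available via `rho_bounds`). This keeps $\Sigma$
  positive definite along the search path. A variance component whose
  estimate collapses below $10^{-6}$ of the total is refit pinned to
  exactly zero and reported as a boundary solution.
* **Optimizer.** BFGS from up to three deterministic starts (balanced,
  A-heavy, E-heavy splits of the fixed-effects-residual variance;
  analogous splits for the other models), each polished by Nelder-Mead,
  relative tolerance $10^{-10}$. Fits are deterministic given the data.
* **Standard error of h².** Delta method on the variance-component
  covariance obtained from the numerically differentiated observed
  information (central differences on the natural scale), with $\beta$
  profiled. At a boundary ($\hat\sigma^2_g = 0$) no SE is reported.
* **LRT nulls.** Removing A or C, or pinning $\rho_{gMF} = 1$, places
  the null on the boundary of the parameter space, so the statistic is
  referred to the 50:50 mixture of a point mass at zero and
  $\chi^2_1$; the p-value convention is
  $p = 0.5\,P(\chi^2_1 > T)$, hence $p = 0.5$ at $T = 0$. The same
  boundary argument is applied to the A/C-removal tests by default
  (configurable to plain $\chi^2$), while the interior constraints
  ($\sigma_{gM} = \sigma_{gF}$; $\rho_g$, $\rho_e$, $\rho_p$ = 0) use
  plain $\chi^2_1$. Statistics are clamped at zero when a constrained
  fit marginally beats the full one within numerical tolerance.
* **The $\rho_p = 0$ constraint** is nonlinear in the parameters. It is
  imposed by eliminating $\rho_e$ through the decomposition
  $\rho_p = \rho_g\sqrt{h^2_1 h^2_2} +
  \rho_e\sqrt{(1-h^2_1)(1-h^2_2)}$, clamping the implied $\rho_e$ to
  $[-0.999, 0.999]$ with a smooth quadratic penalty when the
  elimination leaves that range. The fitted constrained models in the
  test suite reach $|\rho_p| < 0.02$.

## Kinship and pedigree handling

Kinship is computed by the recursive tabular method: individuals are
processed ancestors-first with
$\phi_{ii} = \tfrac12\,(1 + \phi(f_i, m_i))$ and
$\phi_{ij} = \tfrac12(\phi(f_i, j) + \phi(m_i, j))$. Founders are
assumed non-inbred and mutually unrelated (the standard default).
An individual with exactly one recorded parent is treated as having a
unique unobserved founder on the other side, which preserves half-sib
relationships without inventing links. The test suite checks the
recursion against a gene-dropping Monte-Carlo IBD oracle.

Blocks for the likelihood are connected components of the parent–child
graph, additionally uniting individuals who share a family id: a
household is one block even when its members are genetically unrelated
(a spouse pair), which keeps the shared-household C component
block-diagonal. Unobserved founders (e.g. the parents of a phenotyped
sib pair) are carried in the pedigree for the kinship recursion but
excluded from the analysis rows; the kinship matrix is computed on the
full family and then restricted to the analyzed individuals.

## Trait preparation

* **Inverse normal transform**: $\Phi^{-1}((r - c)/(n - 2c + 1))$ with
  the Blom offset $c = 3/8$ and average ranks for ties — the
  conventional choice where the method is named without an offset.
  Because the generator's latent traits are exactly Gaussian and the
  observed scales are monotone maps of them, the transform recovers the
  latent scale up to rank noise, so heritabilities pass through it
  essentially unchanged.
* **Exclusion cascade** (applied in order, each rule tallied): overt
  thyroid dysfunction, prior treatment, pregnancy, TPOAb ≥ 34.0 IU/mL,
  missing TSH/fT4/urinary iodine, then restriction to families with at
  least two remaining members. The euthyroid subgroup additionally
  drops any personal/family thyroid history, values outside the
  reference intervals (TSH 0.62–6.86 mIU/L, fT4 0.89–1.76 ng/dL —
  *closed* intervals: boundary values are retained, reading "within
  the reference range" inclusively), and rows with missing covariates.
* **Covariate screening**: forward–backward stepwise selection by LRT
  *inside* the AE polygenic model, entry and removal thresholds both
  0.10 (the screening default of the variance-components software this
  workflow is modeled on; both configurable). Complete-case rows over
  all candidates are fixed before screening so every compared fit sees
  identical data. Two candidate sets are built in: basic (age, age²,
  sex) and extended (age, sex, BMI, current smoking, log-UICR with the
  natural log, menopausal status with males coded as not menopausal).
  Both sets are supported because the source tables adjust with
  slightly different lists in different places.
* **UICR** is urinary iodine / urinary creatinine × 100 (µg iodine per
  g creatinine); non-positive creatinine yields a missing value, never
  zero. Units follow the defining formula.

## The synthetic-data generator

`scenario_presets()` fixes the study conditions: ~1,115 families with a
size mixture of 90% pairs / 8% trios / 2% quads (mean 2.12, ≈ 2,360
individuals — the emulated cohort has 2,250 from 1,115 families), a
53.4% male fraction, and composition "knhanes": two-member families are
parent–offspring (45%), full-sib (35%) or spouse (20%) pairs,
three-member families nuclear trios or a parent with two children,
four-member families two parents with two children. The true survey's
household-to-relationship mapping is not published, so this mixture is
a plausible household profile and is fully exposed in the scenario
object; `sibpair` and `nuclear` compositions are available for cleaner
designs.

Phenotypes are drawn per family block from the exact model covariance
(assembled with the same covariance operations the fitters use) via the
Cholesky square root — no allele-level simulation is needed for
Gaussian traits; the gene-dropping machinery lives in the test oracles
instead. Covariate effects default to age 0.011 per year (centered),
a small age² term, sex 0.2 SD, each contributing a few percent of
variance; age is uniform on 10–80 years (the survey's eligibility
range), ignoring generational age structure within families. Observed
scales are lognormal maps with medians matching the emulated cohort
(TSH 2.30 mIU/L, fT4 1.24 ng/dL), so the inverse-normal transform is
exercised non-trivially. TPOAb is drawn below the positivity cut by
default — the generator emulates the *post-exclusion* analysis sample —
and `include_excludable = TRUE` adds rows targeted by each exclusion
rule for testing the cascade. Every dataset uses a private RNG stream
seeded explicitly; the global RNG state is untouched.

Preset true parameters (variance ratios on the standardized latent
scale): total h² = 0.54/0.56 with $\rho_g = -0.150$, $\rho_e = -0.056$;
sex-limitation $\sigma^2_{gF}/\sigma^2_p = 0.75$ vs
$\sigma^2_{gM}/\sigma^2_p = 0.41$ with $\rho_{gMF} = 1$; a female-only
sibship design with $\rho_g = -0.347$, $\rho_e = 0.367$,
h² = (0.75, 0.52); and the two null presets (no G×S interaction; no
pleiotropy).

What the generator does *not* emulate: survey sampling weights and the
multistage design, assay noise and detection limits, age-dependent
variance, TPOAb biology, non-Gaussian trait tails beyond the lognormal
map, and within-family age correlation. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data features.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:
kinship against gene-dropping IBD simulation; every model likelihood
against a dense generic MVN log-density on random pedigrees (tolerance
$10^{-8}$); the E-only model against the closed-form ML residual
variance; the G×S model against its univariate collapse limit; the
bivariate model against the independence factorization and a dense
Kronecker oracle. Property checks cover order equivariance and positive
semidefiniteness of kinship, idempotence of the exclusion cascade,
monotonicity and standardization of the transform, determinism of the
generator, and agreement of empirical with analytic covariances.

Calibration and recovery run at deliberately chosen sizes: parameter
recovery at the full design scale (100 replicates × 1,115 families:
mean ĥ² within ±0.02 of truth, ≥ 90% coverage of ±2 SE intervals), and
null calibration of the sex-limitation tests on 500 replicates of a
300-family design (rejection rate of the interior test within
[0.03, 0.08] at α = 0.05; point-mass fraction of the boundary test
within [0.4, 0.6], counting statistics below $10^{-3}$ — i.e. zero at
the two-decimal precision such statistics are reported at — as zero).
Smaller illustrative simulations inside unit tests use reduced but
still-conclusive replicate counts.

## Known limitations

* Households are equated with family blocks; multi-household families
  or shared environments crossing households are not representable.
* The C component and the sex-limitation/bivariate structures are not
  combined (no sex-specific C, no bivariate C), mirroring the analysis
  workflow this package implements (AE was the adopted final model
  there).
* X-linked kinship, dominance, and more than two traits are out of
  scope.
* Stepwise screening inherits the known caveats of stepwise procedures
  (post-selection inference is not corrected); it is provided because
  it is the workflow's specified adjustment strategy.
* With no opposite-sex relative pairs in the data, $\rho_{gMF}$ is
  unidentified; the fitter warns and the estimate should be ignored
  (the constraint fits remain valid).
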