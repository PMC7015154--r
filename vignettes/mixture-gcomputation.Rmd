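---
title: "Estimating joint and independent chemical-mixture effects with a stacked ensemble and G-computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating joint and independent chemical-mixture effects with a stacked ensemble and G-computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children are exposed to many correlated environmental chemicals at once —
here, blood mercury (Hg), a simplified total PCB measure, and five
per-/polyfluoroalkyl substances (PFOS, PFOA, PFHxS, PFNA, PFDA), each
measured in maternal blood during pregnancy and in child blood at age 5.
Single-pollutant regressions answer the wrong question for such mixtures:
coefficients are unstable under collinearity and say nothing about the
effect of shifting the whole mixture. `mixglearn` implements a two-part
estimator for continuous neuropsychological outcomes:

1. **Prediction**: a SuperLearner — a library of regression algorithms
   combined by convex weights chosen to minimize 10-fold cross-validated
   squared error — provides a single prediction oracle
   $\hat{Y}(x, w)$ for the outcome given exposures $x$ and covariates $w$.
2. **Standardization (G-computation)**: effects are contrasts of
   sample-average counterfactual predictions. The per-exposure estimand
   (NACE, naive average causal effect) is
   $$\frac{1}{N}\sum_i \hat{Y}(X_{j} := Q_{75,j},\; X_{-j,i},\; W_i)
     - \frac{1}{N}\sum_i \hat{Y}(X_{j} := Q_{25,j},\; X_{-j,i},\; W_i),$$
   the outcome change (in SD units, since outcomes are standardized) for an
   interquartile-range increase of exposure $j$ with everything else held
   at observed values. The joint mixture effect sets every exposure of a
   timepoint to its own 75th/25th percentile simultaneously. Sweeping a
   percentile grid instead of two points gives a dose-response curve
   $\bar{f}_j(p)$; doing so per individual gives ICE (individual
   conditional expectation) curves, whose non-parallelism flags
   interaction or effect modification. We quantify parallelism as
   `ice_dispersion()`: the population SD (divisor $n$) across individuals
   of each curve's least-squares slope against the grid's exposure values.

Uncertainty comes from a nonparametric bootstrap of the *entire* pipeline
(default $B = 200$): raw rows are resampled, preprocessing (including
the counterfactual quantiles, by default) and the ensemble are redone, and
95% intervals are the 2.5th/97.5th percentiles of the replicate estimates.

## Preprocessing conventions

* Exposures are log10-transformed and mean-centered; quantiles for
  counterfactual assignments are computed on that transformed scale
  (type-7 interpolation), so $Q_{75}-Q_{25}$ is in the same units as the
  design matrix. For the quartiles at $n = 449$ the type-7 rank is an
  integer, so transformed-scale and raw-scale quantiles coincide exactly
  under log10; at interpolated ranks they agree only to first order —
  computing on one scale throughout avoids the ambiguity.
* Outcomes are standardized to mean 0, SD 1 with the **sample** SD
  ($n-1$ divisor), on the complete-case analysis sample. (Whether the
  source analysis standardized on the assessed or the analyzed sample is
  unstated; we chose the analysis sample and note it here.)
* Complete-case only — no imputation, matching the source design. The
  filter is order-preserving and idempotent, and reports per-column
  missingness counts.
* ΣPCB is `2 * (CB138 + CB153 + CB180)`, divided by total lipids when a
  lipid column is supplied.
* Covariate coding: sex and alcohol as single 0/1 indicators; parity, SES
  and smoking as two indicators each against the first level. The maternal
  model adjusts for {age, sex, maternal age, BMI, parity, Raven, SES,
  alcohol, smoking}; the age-5 model adds breastfeeding duration, birth
  weight, and the (log10-centered) maternal exposures. The joint contrast
  in the age-5 model shifts only the seven age-5 exposures, holding the
  maternal panel as covariates.

## The learner library

The supported registry is glm, gam (`mgcv`), elastic net (`glmnet`,
mixing 0.5, penalty by internal 5-fold CV at `lambda.min`), a degree-2
polynomial-basis lasso (`poly`, standing in for adaptive polynomial spline
regression), radial-basis kernel ridge regression (`svm_krr`, the
least-squares analogue of a support vector machine; bandwidth by the
median-distance heuristic), gradient-boosted shallow trees (`gbm`),
a bagged random forest (`random_forest`), and a single-hidden-layer
neural net with weight decay fitted by BFGS (`neural_net`). The tree,
kernel, polynomial and neural learners are implemented in the package
because the usual CRAN implementations are not available in the supported
stack; hyperparameter defaults (forest 100 trees / depth 8; boosting 200
trees / depth 3 / shrinkage 0.05; net 5 units / decay 0.01) are
conventional and exposed in the library configuration. None of these
defaults are source-study facts — the study names the algorithm families
but no settings.

Stacking weights solve $\min_\alpha \lVert y - Z\alpha\rVert^2$ on the
probability simplex, where $Z$ holds out-of-fold predictions. We solve the
simplex-constrained quadratic program directly (rather than non-negative
least squares followed by normalization) because the simplex solution
*guarantees* the ensemble's cross-validated MSE never exceeds the best
single learner's — an invariant the package asserts; the two solutions
coincide in practice. A learner that fails on a fold contributes its
training-mean prediction (with a warning); a learner that fails on the
full-data refit has its weight redistributed.

Two presets: `"full"` (all eight) and `"fast"` ({glm, elastic net,
random forest}, with a 40-tree depth-4 forest) for bootstrap loops and
simulation studies.

## The synthetic cohort

No cohort data are distributed, so the generator produces cohorts with the
documented statistical structure and a known truth manifest:

* **Exposures**: 7 pollutants x 2 timepoints, log10-normal margins coupled
  by a Gaussian copula. Spearman targets are mapped to latent-normal
  correlations by the exact sine transform $r = 2\sin(\pi\rho/6)$ and
  repaired to the nearest PSD correlation (eigenvalue clipping + diagonal
  rescaling) if needed. The default target matrix carries the published
  anchors — PFNA-PFDA 0.79 within both timepoints, PFOA-Hg -0.04 within
  age 5, ΣPCB 0.58 and PFHxS 0.09 between timepoints — embedded in a
  plausible block structure (PFAS cluster ~0.4-0.55, Hg-PCB 0.6,
  cross-chemical between-timepoint background 0.20, a value chosen so the
  stated matrix is already positive-definite and the anchors are not
  distorted by repair). Marginal medians/spreads are *plausible
  placeholders* for a North-Atlantic cohort, not published values (the
  published descriptive table is not reproduced here).
* **Covariates**: sex (49% boys), parity (75% with an older sibling),
  maternal age 29.5, Raven 48.6, 41% alcohol, 27% smoking — stated
  descriptives where available, plausible spreads otherwise. Exposures can
  optionally depend linearly (on the log10 scale) on standardized
  covariates; the default is independence, since no dependence strength is
  published.
* **Outcomes**: `Y = intercept + Σ_j β_j z_j + covariate terms +
  interactions + nonlinear terms + N(0, noise_sd²)`, where `z_j` is the
  centered log10 exposure scaled by its realized sample (type-7) IQR — so
  each `β_j` is *exactly* the per-IQR estimand on the generated sample,
  and `true_nace()` collapses to the configured coefficients for additive
  linear models (Monte-Carlo evaluation of the mean structure otherwise).
  The `"table3_linear"` preset sets maternal Hg to -0.15 and maternal PFOA
  to -0.14 SD per IQR with all other exposures null — the two headline
  effect sizes of the source analysis — plus modest covariate effects
  (Raven, SES, parity, smoking, alcohol, maternal age, sex) whose signs
  follow the published univariate associations; residual SD is 1. The
  covariate effects matter: with them the outcome has R² ≈ 12%, typical of
  neurodevelopmental cohorts; without them the prediction problem is so
  close to pure noise that penalized learners collapse to the mean.
  `"null"`, `"interaction"` (Hg x PFOS +0.1) and `"nonlinear"`
  (quadratic Hg +0.1) variants share the covariate structure.

What a green simulation test does **not** establish: the generator has
Gaussian copulas and log-normal margins by construction, no measurement
error, no missingness, no detection limits, and covariates independent of
exposures by default — real cohort data guarantee none of these.

## Numerical and design choices

* Percentiles: type 7 everywhere (quantiles, bootstrap CI).
* PD/ICE grid default: 5th-95th percentile by 5 — avoids extrapolating
  into the tails.
* Degenerate zero-IQR exposures return a 0 contrast with a warning rather
  than erroring, to keep batch runs alive.
* Seeding: one master seed; every component (copula draw, covariates,
  noise, folds, each learner on each fold, each bootstrap replicate)
  derives its own stream via a string-keyed hash, so runs are bit-for-bit
  reproducible and replicates are order-independent.
* Bootstrap refits everything per replicate, including fold assignment,
  stacking weights and (by default) the counterfactual quantiles;
  `refit_quantiles = FALSE` reuses the original-sample quantiles.
  Replicate failures are counted and reported, never silently dropped.

## Known limitations

* At the signal-to-noise ratio the source effect sizes imply
  (-0.15 SD per IQR against residual SD ~1 at n = 449), every regularized
  learner attenuates quantile-contrast effects toward zero (elastic net at
  `lambda.min` by roughly 25-45%, forests more), and any convex stack
  inherits a weighted share of that attenuation. Simulation recovery of
  the *ensemble* estimate is therefore biased toward the null even though
  the glm path is exactly unbiased; the package's acceptance suite
  measures this honestly rather than hiding it. Percentile-bootstrap
  intervals are centered on the attenuated estimate and inherit the same
  shift.
* The NACE is a marginal *association* summary of the fitted prediction
  function; a causal reading additionally requires exchangeability,
  consistency and positivity, and a doubly-robust (targeted) update is out
  of scope.
* No detection-limit handling, no measurement-error correction, no
  imputation (by design), no formal interaction tests — ICE dispersion is
  a descriptive screen only.

## A worked run

```{r, eval = FALSE}
library(mixglearn)

cohort <- simulate_cohort(n = 449, seed = 1, dgp = "table3_linear")
cfg <- pipeline_config(library = "fast", B = 200, seed = 1)
report <- run_analysis(as.data.frame(cohort), cfg, out_dir = "results")
report$effects        # per-exposure and joint contrasts with percentile CIs
report$risk_table     # cross-validated MSE and stacking weight per learner
```
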