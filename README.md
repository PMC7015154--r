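# mixglearn

Joint and independent effects of correlated chemical exposures on
continuous health outcomes, estimated by combining a **SuperLearner**
(a stacked ensemble with convex weights minimizing 10-fold cross-validated
squared error) with **G-computation** (contrasts of sample-average
counterfactual predictions), and a nonparametric **bootstrap of the whole
pipeline** for 95% percentile confidence intervals.

The package targets the setting of environmental-epidemiology mixture
studies: one row per child; right-skewed, mutually correlated exposure
concentrations (Hg, ΣPCB, and five PFAS, measured prenatally and at age
5); family/social covariates; and standardized neuropsychological outcome
scores. Its core estimand is the **NACE** per exposure *j*:

```
NACE_j = mean_i Ŷ(X_j := Q75_j, X_-j,i, W_i) - mean_i Ŷ(X_j := Q25_j, X_-j,i, W_i)
```

— the SD change in the outcome for an interquartile-range increase of
exposure *j*, everything else held at observed values. Setting *all*
exposures to their own Q75/Q25 simultaneously gives the joint mixture
effect; sweeping a percentile grid gives dose-response curves and
per-individual ICE curves (non-parallel curves flag interactions).

Because no cohort data ship with the package, a Gaussian-copula synthetic
cohort generator (`simulate_cohort()`) reproduces the documented
correlation structure (e.g. PFNA–PFDA Spearman 0.79, PFOA–Hg −0.04) and
plants known per-IQR effects, so estimator behavior is testable end to end.

## Worked example

```r
library(mixglearn)

cohort <- simulate_cohort(n = 449, seed = 1, dgp = "table3_linear")
cohort$truth$nace$hg_mat          # -0.15  (planted truth, SD per IQR)

cfg <- pipeline_config(library = "fast", B = 50, seed = 1,
                       targets = c("hg_mat", "pfoa_mat", "pcb_mat"))
report <- run_analysis(as.data.frame(cohort), cfg, out_dir = "results")
report
```

```
analysis_report: outcome 'y', maternal model, n = 449, B = 50 (0 failed)
                         target   point ci_low  ci_high n_failed
1                        hg_mat -0.0958 -0.256  0.03672        0
2                      pfoa_mat -0.0989 -0.245 -0.00857        0
3                       pcb_mat -0.0303 -0.111  0.02578        0
4 joint:hg_mat+pfoa_mat+pcb_mat -0.2282 -0.422 -0.03147        0
```

Reading this: the planted Hg and PFOA effects (−0.15 and −0.14 SD per
IQR) come back around −0.10 — sampling noise (SE ≈ 0.06 at this signal
size) plus the attenuation toward the null that every regularized library
member imposes at this signal-to-noise ratio, which the ensemble inherits;
the null ΣPCB effect sits near 0, and the joint contrast of the three
shifted exposures approximates the sum of the singles, as it should in an
additive world. The vignette and the acceptance suite quantify the
attenuation honestly. `report$risk_table` shows each learner's
cross-validated MSE and stacking weight; `report$pd` and `report$ice`
hold the dose-response and individual-curve tables written to
`results/`.

A command-line front end mirrors the R API:

```sh
inst/exec/mixglearn simulate --n 449 --seed 1 --out cohort.csv --truth truth.json
inst/exec/mixglearn run --input cohort.csv --out-dir results --library fast --b 200
```

## Learn more

The methods vignette (`vignettes/mixture-gcomputation.Rmd`) documents the
model, the preprocessing conventions, every learner and its defaults, the
synthetic-cohort design and its limits, and the known attenuation behavior
of stacked shrinkage learners at epidemiological signal-to-noise ratios.
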