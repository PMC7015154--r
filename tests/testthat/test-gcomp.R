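# G-computation estimators, checked against analytic oracles on glm-only
# fits (where the counterfactual algebra collapses to linear algebra).

glm_fit_on <- function(ds, seed = 9) {
  superlearner(ds, library = list(learner_spec("glm")), k = 5, seed = seed)
}

test_that("predict_counterfactual applies assignments and matches hand arithmetic", {
  tab <- tiny_table(n = 150, seed = 41, dgp = noiseless_dgp())
  ds <- make_analysis_dataset(tab, standardize = FALSE)
  fit <- glm_fit_on(ds)

  # identity scenarios
  p0 <- predict_counterfactual(fit, ds)
  expect_equal(p0, predict(fit, ds), tolerance = 1e-12)
  p_obs <- predict_counterfactual(fit, ds,
                                  list(hg_mat = ds$X[, "hg_mat"]))
  expect_equal(p_obs, p0, tolerance = 1e-12)

  # all exposures at their centered means (0) on a linear fit: the
  # covariate-only predictor, verified by row arithmetic on 3 rows
  assign0 <- as.list(setNames(rep(0, ncol(ds$X)), colnames(ds$X)))
  pc <- predict_counterfactual(fit, ds, assign0)
  cf <- fit$learners[[1]]$fit$coef
  for (i in 1:3) {
    manual <- cf[1] + sum(cf[colnames(ds$W)] * ds$W[i, ])
    expect_equal(pc[i], unname(manual), tolerance = 1e-8)
  }
  expect_error(predict_counterfactual(fit, ds, list(bogus = 1)), "unknown exposure")
  expect_error(predict_counterfactual(fit, ds, list(hg_mat = Inf)), "finite")
})

test_that("nace obeys its definitional identities and the linear-collapse oracle", {
  tab <- tiny_table(n = 200, seed = 42)
  ds <- make_analysis_dataset(tab)
  fit <- glm_fit_on(ds)

  est <- nace(fit, ds, "hg_mat")
  # linear collapse: beta_hat * (Q75 - Q25), an oracle independent of the
  # counterfactual prediction path
  cf <- fit$learners[[1]]$fit$coef
  iqr <- diff(vapply(c(25, 75), function(p) ds_quantile(ds, "hg_mat", p), numeric(1)))
  expect_equal(est$estimate, unname(cf["hg_mat"]) * iqr, tolerance = 1e-8)

  # nace = PD(75) - PD(25) when the grid holds both percentiles
  pd <- partial_dependence(fit, ds, "hg_mat", grid = c(25, 50, 75))
  expect_equal(est$estimate, pd$value[3] - pd$value[1], tolerance = 1e-10)

  # singleton joint contrast reduces exactly to the individual contrast
  j1 <- joint_nace(fit, ds, "hg_mat")
  expect_equal(j1$estimate, est$estimate, tolerance = 1e-12)

  # additive linear fit: joint equals the sum of the singles
  jall <- joint_nace(fit, ds)
  singles <- vapply(colnames(ds$X), function(e) nace(fit, ds, e)$estimate, numeric(1))
  expect_equal(jall$estimate, sum(singles), tolerance = 1e-8)
})

test_that("degenerate zero-IQR exposures yield a warned zero estimate", {
  tab <- tiny_table(n = 80, seed = 43)
  tab$flat_mat <- 5 # constant exposure column
  ds <- make_analysis_dataset(tab)
  fit <- glm_fit_on(ds)
  expect_warning(est <- nace(fit, ds, "flat_mat"), "zero width")
  expect_identical(est$estimate, 0)
})

test_that("partial dependence is affine for linear fits and flat for nulls", {
  tab <- tiny_table(n = 200, seed = 44, dgp = noiseless_dgp())
  ds <- make_analysis_dataset(tab, standardize = FALSE)
  fit <- glm_fit_on(ds)
  pd <- partial_dependence(fit, ds, "hg_mat")
  res <- resid(lm(pd$value ~ pd$x_value))
  expect_lt(max(abs(res)), 1e-6)
  # a null exposure gives a flat curve
  pd0 <- partial_dependence(fit, ds, "pfna_mat")
  expect_lt(diff(range(pd0$value)), 1e-8)
  expect_error(partial_dependence(fit, ds, "hg_mat", grid = c(10, 5)))
})

test_that("a quadratic signal bends the fitted dose-response the right way", {
  dgp <- outcome_dgp(nonlinear = list(hg_mat = list(type = "quadratic", coef = 0.3)),
                     noise_sd = 0.1)
  tab <- tiny_table(n = 300, seed = 45, dgp = dgp)
  ds <- make_analysis_dataset(tab, standardize = FALSE)
  fit <- superlearner(ds, library = list(learner_spec("poly")), k = 5, seed = 7)
  pd <- partial_dependence(fit, ds, "hg_mat", grid = seq(10, 90, 10))
  # convexity: positive mean second difference, matching the +0.3 DGP term,
  # itself checked against direct evaluation of the DGP formula
  d2 <- diff(diff(pd$value) / diff(pd$x_value)) / diff(pd$x_value[-1])
  expect_gt(mean(d2), 0)
  # direct DGP evaluation at the same grid shows the same convex shape
  iqr <- diff(vapply(c(25, 75), function(p) ds_quantile(ds, "hg_mat", p), numeric(1)))
  truth_curve <- 0.3 * (pd$x_value / iqr)^2
  expect_gt(cor(pd$value, truth_curve), 0.9)
})

test_that("ICE curves average to the PD curve and expose interactions", {
  tab_add <- tiny_table(n = 200, seed = 46, dgp = noiseless_dgp())
  ds_add <- make_analysis_dataset(tab_add, standardize = FALSE)
  fit_add <- glm_fit_on(ds_add)
  b_add <- ice(fit_add, ds_add, "hg_mat")
  pd_add <- partial_dependence(fit_add, ds_add, "hg_mat")
  expect_equal(b_add$pd, pd_add$value, tolerance = 1e-10)
  expect_equal(colMeans(b_add$curves), pd_add$value, tolerance = 1e-10)
  # additive linear fit: curves are parallel
  expect_lt(ice_dispersion(b_add), 1e-6)

  # matched interaction world, learner able to represent products
  dgp_int <- outcome_dgp(beta_per_iqr = c(hg_mat = -0.15),
                         interactions = list(list("hg_mat", "pfos_mat", 0.3)),
                         noise_sd = 0.1)
  dgp_lin <- outcome_dgp(beta_per_iqr = c(hg_mat = -0.15), noise_sd = 0.1)
  tab_int <- tiny_table(n = 250, seed = 47, dgp = dgp_int)
  tab_lin <- tiny_table(n = 250, seed = 47, dgp = dgp_lin)
  lib <- list(learner_spec("poly"))
  ds_i <- make_analysis_dataset(tab_int, standardize = FALSE)
  ds_l <- make_analysis_dataset(tab_lin, standardize = FALSE)
  disp_i <- ice_dispersion(ice(superlearner(ds_i, lib, k = 5, seed = 3), ds_i, "hg_mat"))
  disp_l <- ice_dispersion(ice(superlearner(ds_l, lib, k = 5, seed = 3), ds_l, "hg_mat"))
  expect_gt(disp_i, disp_l)
})

test_that("ice_dispersion is the population SD of per-curve slopes", {
  # two individuals with slopes 0 and 1 over unit-spaced x values
  bundle <- structure(list(exposure = "e", grid = c(25, 75),
                           x_values = c(0, 1),
                           curves = rbind(c(0, 0), c(0, 1)),
                           pd = c(0, 0.5)),
                      class = "ice_bundle")
  expect_equal(ice_dispersion(bundle), 0.5)
  flat <- bundle; flat$curves <- rbind(c(1, 2), c(0, 1)) # parallel
  expect_equal(ice_dispersion(flat), 0)
})

test_that("estimates are invariant to row permutation of the cohort", {
  tab <- tiny_table(n = 120, seed = 48)
  set.seed(480)
  perm <- sample(nrow(tab))
  ds1 <- make_analysis_dataset(tab)
  ds2 <- make_analysis_dataset(tab[perm, ])
  f1 <- glm_fit_on(ds1); f2 <- glm_fit_on(ds2)
  expect_equal(nace(f1, ds1, "hg_mat")$estimate,
               nace(f2, ds2, "hg_mat")$estimate, tolerance = 1e-8)
  expect_equal(joint_nace(f1, ds1)$estimate, joint_nace(f2, ds2)$estimate,
               tolerance = 1e-8)
})
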