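test_that("make_folds yields near-equal, reproducible folds", {
  f <- make_folds(10, 10, seed = 1)
  expect_equal(sort(unique(f$assignment)), 1:10)
  expect_true(all(table(f$assignment) == 1))
  f449 <- make_folds(449, 10, seed = 2)
  expect_true(all(table(f449$assignment) %in% c(44L, 45L)))
  expect_equal(make_folds(449, 10, seed = 2)$assignment, f449$assignment)
  expect_error(make_folds(5, 6), "more folds")
})

test_that("cross_validate produces honest out-of-fold predictions", {
  set.seed(3)
  n <- 120
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * x[, 1] - x[, 2]        # noiseless linear signal
  sch <- make_folds(n, 5, seed = 7)
  Z <- cross_validate(learner_library("glm"), x, y, sch)
  expect_lt(mean((y - Z[, 1])^2), 1e-16)

  # mean-only learner: CV MSE is essentially var(y) (= 1 for standardized y)
  ym <- as.numeric(scale(rnorm(n)))
  Zm <- cross_validate(learner_library("mean"), x, ym, sch)
  expect_equal(mean((ym - Zm[, 1])^2), 1, tolerance = 0.15)

  # identical specs give identical columns
  lib2 <- list(learner_spec("glm", seed_offset = 1), learner_spec("glm", seed_offset = 1))
  Z2 <- cross_validate(lib2, x, y, sch)
  expect_identical(Z2[, 1], Z2[, 2])
})

test_that("solve_weights matches the simplex grid oracle and stays on the simplex", {
  set.seed(11)
  # perfect first column
  y <- rnorm(60)
  Z <- cbind(y, rnorm(60), rnorm(60))
  w <- solve_weights(Z, y)
  expect_simplex(w)
  expect_gt(w[1], 0.99)

  # duplicated perfect columns: mass splits but predictions unchanged
  Zd <- cbind(y, y, rnorm(60))
  wd <- solve_weights(Zd, y)
  expect_simplex(wd)
  expect_equal(drop(Zd %*% wd), y, tolerance = 1e-6)

  # random problems vs exhaustive grid search
  for (rep in 1:5) {
    n <- 50
    f <- rnorm(n)
    Z3 <- cbind(f + rnorm(n, sd = 0.5), f + rnorm(n, sd = 0.8), rnorm(n))
    yy <- f + rnorm(n, sd = 0.3)
    wq <- solve_weights(Z3, yy)
    expect_simplex(wq)
    oracle <- grid_search_weights(Z3, yy)
    expect_lte(mse_of(Z3, yy, wq), oracle$mse + 0.02)
    # CV-risk dominance over single learners
    expect_lte(mse_of(Z3, yy, wq), min(colMeans((yy - Z3)^2)) + 1e-8)
  }
})

test_that("superlearner satisfies its stacking invariants", {
  tab <- tiny_table(n = 150, seed = 21)
  ds <- make_analysis_dataset(tab)
  fit <- superlearner(ds, library = list(learner_spec("glm"),
                                         learner_spec("elastic_net")),
                      k = 5, seed = 31)
  expect_simplex(fit$weights)
  expect_lte(fit$ensemble_cv_mse, min(fit$cv_mse) + 1e-8)
  rt <- risk_table(fit)
  expect_equal(nrow(rt), 3)
  expect_equal(sum(rt$weight, na.rm = TRUE), 1, tolerance = 1e-8)

  # glm-only: single learner carries weight 1 and predicts alone
  fit1 <- superlearner(ds, library = list(learner_spec("glm")), k = 5, seed = 31)
  expect_equal(unname(fit1$weights), 1)
  p1 <- predict(fit1, ds)
  pl <- mixglearn:::predict_learner(fit1$learners[[1]], mixglearn:::ds_design(ds))
  expect_equal(p1, pl, tolerance = 1e-12)

  # refit determinism
  fit2 <- superlearner(ds, library = list(learner_spec("glm"),
                                          learner_spec("elastic_net")),
                       k = 5, seed = 31)
  expect_equal(fit$weights, fit2$weights)
  expect_equal(predict(fit, ds), predict(fit2, ds), tolerance = 1e-12)
})

test_that("predictions are convex combinations and respect the column contract", {
  tab <- tiny_table(n = 120, seed = 5)
  ds <- make_analysis_dataset(tab)
  lib <- learner_library(c("glm", "random_forest"),
                         hyperparameters = list(random_forest = list(ntree = 20L)))
  fit <- superlearner(ds, lib, k = 5, seed = 13)
  x <- mixglearn:::ds_design(ds)
  preds <- vapply(fit$learners, mixglearn:::predict_learner, numeric(nrow(x)), x = x)
  ens <- predict(fit, x)
  expect_true(all(ens >= apply(preds, 1, min) - 1e-10))
  expect_true(all(ens <= apply(preds, 1, max) + 1e-10))
  # duplicate row -> duplicate prediction
  x2 <- rbind(x[1, , drop = FALSE], x[1, , drop = FALSE])
  expect_equal(diff(predict(fit, x2)), 0)
  expect_error(predict(fit, x[, 1:3]), "columns")

  # serialization round-trip preserves predictions
  tf <- tempfile(fileext = ".rds")
  saveRDS(fit, tf)
  expect_equal(predict(readRDS(tf), x), ens, tolerance = 1e-12)
})

test_that("noiseless linear data recovers DGP betas through the glm refit", {
  tab <- tiny_table(n = 300, seed = 17, dgp = noiseless_dgp())
  ds <- make_analysis_dataset(tab, standardize = FALSE)
  fit <- superlearner(ds, library = list(learner_spec("glm")), k = 5, seed = 3)
  cf <- fit$learners[[1]]$fit$coef
  iqr_hg <- diff(vapply(c(25, 75), function(p) ds_quantile(ds, "hg_mat", p), numeric(1)))
  expect_equal(unname(cf["hg_mat"]) * iqr_hg, -0.15, tolerance = 1e-6)
  expect_equal(unname(cf["pcb_mat"]), 0, tolerance = 1e-6)
})

test_that("every registered learner fits and predicts finitely", {
  tab <- tiny_table(n = 100, seed = 23)
  ds <- make_analysis_dataset(tab)
  x <- mixglearn:::ds_design(ds)
  for (id in c("glm", "gam", "elastic_net", "poly", "svm_krr",
               "gbm", "random_forest", "neural_net", "mean")) {
    hp <- switch(id, gbm = list(ntree = 30L), random_forest = list(ntree = 15L),
                 neural_net = list(maxit = 50L), list())
    set.seed(1)
    f <- mixglearn:::fit_learner(learner_spec(id, hp), x, ds$Y)
    p <- mixglearn:::predict_learner(f, x)
    expect_true(all(is.finite(p)), label = id)
    expect_length(p, nrow(x))
  }
  # aliases resolve to the local implementations
  expect_equal(learner_spec("svm")$id, "svm_krr")
  expect_equal(learner_spec("poly_mars")$id, "poly")
})

test_that("on linear data the linear learners dominate the stack across seeds", {
  wins <- 0L
  for (s in 1:10) {
    tab <- tiny_table(n = 300, seed = 100 + s)
    ds <- make_analysis_dataset(tab)
    lib <- learner_library("full", hyperparameters = list(
      gbm = list(ntree = 40L), random_forest = list(ntree = 25L, max_depth = 4L),
      neural_net = list(maxit = 60L)))
    fit <- superlearner(ds, lib, k = 5, seed = 1000 + s)
    top <- names(which.max(fit$weights))
    if (top %in% c("glm", "elastic_net")) wins <- wins + 1L
  }
  expect_gt(wins, 5)
})
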