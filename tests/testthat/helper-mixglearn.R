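# Shared fixtures and independent oracles for the test suite.

# small maternal-panel cohort as a raw analysis table
tiny_table <- function(n = 150, seed = 1, dgp = "table3_linear", ...) {
  as.data.frame(simulate_cohort(n = n, seed = seed, dgp = dgp, ...))
}

# exhaustive simplex grid search (step 0.01) for 3-learner stacking problems;
# independent oracle for solve_weights
grid_search_weights <- function(Z, y, step = 0.01) {
  a1 <- seq(0, 1, by = step)
  grid <- expand.grid(a1 = a1, a2 = a1)
  grid <- grid[grid$a1 + grid$a2 <= 1 + 1e-12, ]
  grid$a3 <- pmax(0, 1 - grid$a1 - grid$a2)
  A <- t(as.matrix(grid))           # 3 x G
  mse <- colMeans((y - Z %*% A)^2)
  list(weights = A[, which.min(mse)], mse = min(mse))
}

mse_of <- function(Z, y, a) mean((y - drop(Z %*% a))^2)

# noiseless linear DGP over the maternal panel with known betas
noiseless_dgp <- function(betas = c(hg_mat = -0.15, pfoa_mat = -0.14)) {
  outcome_dgp(beta_per_iqr = betas,
              beta_cov = c(raven = 0.04, ses_high = 0.3),
              noise_sd = 0)
}

expect_simplex <- function(w, tol = 1e-8) {
  expect_true(all(w >= -tol))
  expect_equal(sum(w), 1, tolerance = tol)
}
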