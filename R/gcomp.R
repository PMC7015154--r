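# G-computation on the fitted ensemble: quantile-based counterfactual
# contrasts (NACE), partial-dependence (dose-response) curves over percentile
# grids, and individual conditional expectation curves.

#' Ensemble predictions under a counterfactual exposure assignment
#'
#' Overwrites the assigned exposure columns with fixed values (analysis
#' scale: centered log10) for every row, leaving all other exposures and
#' covariates at their observed values, and returns the ensemble prediction
#' for each of the n individuals.
#'
#' @param fit a `superlearner_fit`.
#' @param ds the `analysis_dataset` the fit was trained on.
#' @param assignments named numeric: exposure -> fixed value (may be empty,
#'   giving predictions at the observed data).
#' @export
predict_counterfactual <- function(fit, ds, assignments = numeric()) {
  X <- ds$X
  if (length(assignments)) {
    bad <- setdiff(names(assignments), colnames(X))
    if (length(bad)) stop_structural("unknown exposure(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(unlist(assignments))))
      stop_structural("counterfactual values must be finite")
    for (nm in names(assignments)) X[, nm] <- assignments[[nm]]
  }
  predict(fit, cbind(X, ds$W))
}

new_effect_estimate <- function(target, low_pct, high_pct, estimate) {
  structure(list(target = target, low_pct = low_pct, high_pct = high_pct,
                 estimate = estimate, scale_note = "SD per IQR"),
            class = "effect_estimate")
}

#' @export
#' @method print effect_estimate
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %+.4f (Q%g vs Q%g contrast, %s)\n",
              x$target, x$estimate, x$high_pct, x$low_pct, x$scale_note))
  invisible(x)
}

#' Naive average causal effect of one exposure
#'
#' Sample-average prediction with the exposure set to its `high_pct`
#' percentile for everyone, minus the sample average with it set to the
#' `low_pct` percentile (defaults: 75 vs 25, i.e. per-IQR).
#'
#' @param fit,ds fitted ensemble and its dataset.
#' @param exposure exposure column name.
#' @param low_pct,high_pct contrast percentiles (low < high).
#' @return an `effect_estimate`.
#' @export
nace <- function(fit, ds, exposure, low_pct = 25, high_pct = 75) {
  stopifnot(low_pct < high_pct)
  qlo <- ds_quantile(ds, exposure, low_pct)
  qhi <- ds_quantile(ds, exposure, high_pct)
  if (qhi == qlo) {
    warning("exposure '", exposure, "' has zero width between percentiles; effect set to 0")
    return(new_effect_estimate(exposure, low_pct, high_pct, 0))
  }
  est <- mean(predict_counterfactual(fit, ds, stats::setNames(qhi, exposure))) -
         mean(predict_counterfactual(fit, ds, stats::setNames(qlo, exposure)))
  new_effect_estimate(exposure, low_pct, high_pct, est)
}

#' Joint mixture contrast
#'
#' All exposures in the set are simultaneously fixed at their own
#' `high_pct` percentiles, then at their own `low_pct` percentiles; the
#' difference of sample-average predictions is the joint per-IQR effect.
#'
#' @param fit,ds fitted ensemble and its dataset.
#' @param exposures character vector (default: every exposure in the model).
#' @param low_pct,high_pct contrast percentiles.
#' @return an `effect_estimate` with target `"joint:<e1+e2+...>"`.
#' @export
joint_nace <- function(fit, ds, exposures = colnames(ds$X),
                       low_pct = 25, high_pct = 75) {
  stopifnot(length(exposures) >= 1, low_pct < high_pct)
  qhi <- vapply(exposures, function(e) ds_quantile(ds, e, high_pct), numeric(1))
  qlo <- vapply(exposures, function(e) ds_quantile(ds, e, low_pct), numeric(1))
  degenerate <- qhi == qlo
  if (all(degenerate)) {
    warning("all exposures degenerate between percentiles; joint effect set to 0")
    return(new_effect_estimate(paste0("joint:", paste(exposures, collapse = "+")),
                               low_pct, high_pct, 0))
  }
  est <- mean(predict_counterfactual(fit, ds, qhi)) -
         mean(predict_counterfactual(fit, ds, qlo))
  new_effect_estimate(paste0("joint:", paste(exposures, collapse = "+")),
                      low_pct, high_pct, est)
}

#' Partial-dependence (dose-response) curve over a percentile grid
#'
#' `f_bar(p)` = sample-average prediction with the exposure set to its p-th
#' percentile for all individuals.
#'
#' @param fit,ds fitted ensemble and its dataset.
#' @param exposure exposure column name.
#' @param grid strictly increasing percentiles in `[0, 100]` (default 5..95
#'   by 5, avoiding extrapolation at the extremes).
#' @return `pd_curve`: data.frame with percentile, exposure value (analysis
#'   scale) and the averaged prediction.
#' @export
partial_dependence <- function(fit, ds, exposure, grid = seq(5, 95, by = 5)) {
  stopifnot(all(grid >= 0 & grid <= 100), !is.unsorted(grid, strictly = TRUE))
  qv <- vapply(grid, function(p) ds_quantile(ds, exposure, p), numeric(1))
  vals <- vapply(seq_along(grid), function(i)
    mean(predict_counterfactual(fit, ds, stats::setNames(qv[i], exposure))),
    numeric(1))
  structure(data.frame(exposure = exposure, percentile = grid,
                       x_value = qv, value = vals),
            class = c("pd_curve", "data.frame"))
}

#' Individual conditional expectation curves
#'
#' One curve per individual: the prediction as the exposure sweeps the
#' percentile grid while that individual's other exposures and covariates
#' stay at their observed values. Column means reproduce the
#' partial-dependence curve (asserted to 1e-10).
#'
#' @inheritParams partial_dependence
#' @return `ice_bundle`: list with the n x G `curves` matrix, the grid, the
#'   grid's exposure values and the implied PD values.
#' @export
ice <- function(fit, ds, exposure, grid = seq(5, 95, by = 5)) {
  stopifnot(all(grid >= 0 & grid <= 100), !is.unsorted(grid, strictly = TRUE))
  qv <- vapply(grid, function(p) ds_quantile(ds, exposure, p), numeric(1))
  curves <- vapply(seq_along(grid), function(i)
    predict_counterfactual(fit, ds, stats::setNames(qv[i], exposure)),
    numeric(nrow(ds$X)))
  if (nrow(ds$X) == 1L) curves <- matrix(curves, nrow = 1L)
  pd <- colMeans(curves)
  structure(list(exposure = exposure, grid = grid, x_values = qv,
                 curves = curves, pd = pd),
            class = "ice_bundle")
}

#' Slope dispersion of an ICE bundle
#'
#' Least-squares slope of each individual curve against the grid's exposure
#' values, summarized by the population standard deviation (divisor n)
#' across individuals. Parallel curves give 0; interactions inflate it.
#'
#' @param bundle an [ice()] result with at least two grid points.
#' @export
ice_dispersion <- function(bundle) {
  stopifnot(inherits(bundle, "ice_bundle"), length(bundle$grid) >= 2L)
  x <- bundle$x_values
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(0)
  slopes <- drop(bundle$curves %*% xc) / denom
  sqrt(mean((slopes - mean(slopes))^2))
}

#' Tidy tables for effects, PD and ICE results
#'
#' @param effects list of `effect_estimate`s.
#' @export
effects_table <- function(effects) {
  do.call(rbind, lapply(effects, function(e)
    data.frame(target = e$target, low_pct = e$low_pct, high_pct = e$high_pct,
               estimate = e$estimate)))
}

#' @rdname effects_table
#' @param bundle an `ice_bundle`.
#' @export
ice_table <- function(bundle) {
  n <- nrow(bundle$curves)
  data.frame(id = rep(seq_len(n), times = length(bundle$grid)),
             exposure = bundle$exposure,
             percentile = rep(bundle$grid, each = n),
             value = as.numeric(bundle$curves))
}
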