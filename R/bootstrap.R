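# End-to-end orchestration: point analysis, nonparametric bootstrap of the
# whole pipeline (resample raw rows -> preprocess -> refit the ensemble ->
# G-computation) and percentile confidence intervals.

#' Pipeline configuration
#'
#' @param outcome outcome column; `timepoint` `"maternal"` or `"age5"`.
#' @param library learner preset name or list of [learner_spec()]s.
#' @param k CV folds; `grid` PD/ICE percentile grid; `low_pct`,`high_pct`
#'   contrast percentiles; `B` bootstrap replicates (default 200);
#'   `seed` master seed.
#' @param targets exposures to contrast (default: every exposure in the
#'   model); `joint` also estimate the joint mixture contrast.
#' @param standardize standardize the outcome on the analysis sample.
#' @param refit_quantiles recompute counterfactual quantiles inside each
#'   bootstrap replicate (default TRUE; FALSE reuses the original sample's).
#' @export
pipeline_config <- function(outcome = "y", timepoint = "maternal",
                            library = "fast", k = 10L,
                            grid = seq(5, 95, by = 5),
                            low_pct = 25, high_pct = 75,
                            B = 200L, seed = 1L,
                            targets = NULL, joint = TRUE,
                            standardize = TRUE, refit_quantiles = TRUE) {
  stopifnot(B >= 1L, low_pct < high_pct, k >= 2L)
  structure(list(outcome = outcome, timepoint = timepoint, library = library,
                 k = as.integer(k), grid = grid, low_pct = low_pct,
                 high_pct = high_pct, B = as.integer(B),
                 seed = as.integer(seed), targets = targets, joint = joint,
                 standardize = standardize, refit_quantiles = refit_quantiles),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (JSON)
#' @param config a [pipeline_config()]; `path` file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config_as_plain(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# strip S3 classes so a config (whose library may hold learner_spec objects)
# serializes cleanly; as_learner_library() re-inflates on the way back in
config_as_plain <- function(config) {
  out <- unclass(config)
  if (!is.character(out$library))
    out$library <- lapply(out$library, unclass)
  out
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Resample raw cohort rows with replacement
#' @param table data.frame with at least two rows; `seed` integer.
#' @export
resample_table <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 2L) stop("need at least 2 rows to resample")
  idx <- with_seed(seed, sample.int(n, n, replace = TRUE))
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one full pass: preprocess -> ensemble -> contrasts
run_point <- function(config, table, seed, quantile_ds = NULL) {
  ds <- make_analysis_dataset(table, outcome = config$outcome,
                              timepoint = config$timepoint,
                              standardize = config$standardize)
  if (!is.null(quantile_ds)) ds$quantiles <- quantile_ds$quantiles
  fit <- superlearner(ds, library = config$library, k = config$k, seed = seed)
  targets <- config$targets %||% colnames(ds$X)
  effects <- lapply(targets, function(e)
    nace(fit, ds, e, config$low_pct, config$high_pct))
  if (isTRUE(config$joint))
    effects <- c(effects, list(joint_nace(fit, ds, targets,
                                          config$low_pct, config$high_pct)))
  est <- vapply(effects, `[[`, numeric(1), "estimate")
  names(est) <- vapply(effects, `[[`, character(1), "target")
  list(ds = ds, fit = fit, effects = effects, estimates = est)
}

#' Run one bootstrap replicate of the full pipeline
#'
#' Resamples the raw table, redoes preprocessing (including, by default, the
#' counterfactual quantiles), refits the ensemble and recomputes every
#' configured contrast.
#'
#' @param config a [pipeline_config()]; `table` the raw cohort table;
#'   `replicate_seed` the replicate's seed (drives both the resample and the
#'   refit); `quantile_ds` optional original-dataset quantiles to reuse when
#'   `config$refit_quantiles` is FALSE.
#' @return named vector of effect estimates.
#' @export
run_replicate <- function(config, table, replicate_seed, quantile_ds = NULL) {
  boot_tab <- resample_table(table, seed = derive_seed(replicate_seed, "rows"))
  if (!isTRUE(config$refit_quantiles) && is.null(quantile_ds))
    stop("quantile_ds required when refit_quantiles is FALSE")
  run_point(config, boot_tab, seed = derive_seed(replicate_seed, "fit"),
            quantile_ds = if (!isTRUE(config$refit_quantiles)) quantile_ds)$estimates
}

#' Percentile bootstrap confidence interval
#'
#' Type-7 quantiles of the replicate distribution at the requested levels
#' (default 2.5% and 97.5%).
#'
#' @param replicates numeric vector of replicate estimates.
#' @param levels two percentiles on the 0-100 scale.
#' @export
percentile_ci <- function(replicates, levels = c(2.5, 97.5)) {
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) < 2L) stop("need at least 2 finite replicates")
  ci <- pctile(replicates, levels)
  c(low = ci[1], high = ci[2])
}

#' Bootstrap the full analysis
#'
#' Point estimates on the original sample plus `B` full-pipeline replicates
#' and percentile CIs per target. Replicate failures are counted and
#' reported, never silently dropped.
#'
#' @param table raw cohort data.frame.
#' @param config a [pipeline_config()].
#' @return `bootstrap_result`: data.frame (target, point, ci_low, ci_high,
#'   n_failed) with the replicate matrix in attribute `"replicates"` and the
#'   point-run objects in attribute `"point_run"`.
#' @export
bootstrap_effects <- function(table, config = pipeline_config()) {
  point <- run_point(config, table, seed = derive_seed(config$seed, "point"))
  reps <- vector("list", config$B)
  failed <- character(0)
  for (b in seq_len(config$B)) {
    rs <- derive_seed(config$seed, sprintf("replicate:%d", b))
    reps[[b]] <- tryCatch(
      run_replicate(config, table, rs,
                    quantile_ds = if (!isTRUE(config$refit_quantiles)) point$ds),
      error = function(e) {
        failed <<- c(failed, sprintf("replicate %d: %s", b, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(reps, is.null, logical(1))
  R <- do.call(rbind, reps[ok])
  if (is.null(R) || nrow(R) < 2L)
    stop("bootstrap failed: fewer than 2 successful replicates")
  out <- do.call(rbind, lapply(names(point$estimates), function(tg) {
    ci <- percentile_ci(R[, tg])
    data.frame(target = tg, point = point$estimates[[tg]],
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               n_failed = sum(!ok))
  }))
  rownames(out) <- NULL
  if (length(failed)) warning(sum(!ok), " bootstrap replicate(s) failed",
                              call. = FALSE)
  structure(out, replicates = R, failures = failed, point_run = point,
            class = c("bootstrap_result", "data.frame"))
}

#' Run the complete analysis and write its outputs
#'
#' Drives the whole pipeline on a cohort table (or CSV path): bootstrap
#' effect estimates with percentile CIs, partial-dependence and ICE tables
#' for every target exposure, the learner risk/weight table, and a
#' machine-readable JSON summary. Deterministic given `config$seed`.
#'
#' @param table data.frame or path to a cohort CSV.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed); when given,
#'   writes `effects.csv`, `pd_curves.csv`, `ice_curves.csv`,
#'   `risk_table.csv` and `summary.json`.
#' @return `analysis_report` list with all result tables.
#' @export
run_analysis <- function(table, config = pipeline_config(), out_dir = NULL) {
  if (is.character(table)) table <- utils::read.csv(table)
  res <- bootstrap_effects(table, config)
  point <- attr(res, "point_run")
  targets <- config$targets %||% colnames(point$ds$X)
  pd_tabs <- list(); ice_tabs <- list(); dispersion <- numeric(0)
  for (e in targets) {
    bundle <- ice(point$fit, point$ds, e, grid = config$grid)
    pd_tabs[[e]] <- data.frame(exposure = e, percentile = bundle$grid,
                               x_value = bundle$x_values, value = bundle$pd)
    ice_tabs[[e]] <- ice_table(bundle)
    dispersion[[e]] <- ice_dispersion(bundle)
  }
  pd_tab <- do.call(rbind, pd_tabs); rownames(pd_tab) <- NULL
  ice_tab <- do.call(rbind, ice_tabs); rownames(ice_tab) <- NULL
  rt <- risk_table(point$fit)
  report <- list(
    config = config_as_plain(config),
    effects = as.data.frame(res),
    pd = pd_tab, ice = ice_tab, ice_dispersion = as.list(dispersion),
    risk_table = rt,
    n = point$ds$meta$n,
    n_failed_replicates = res$n_failed[1])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$effects, file.path(out_dir, "effects.csv"), row.names = FALSE)
    utils::write.csv(pd_tab, file.path(out_dir, "pd_curves.csv"), row.names = FALSE)
    utils::write.csv(ice_tab, file.path(out_dir, "ice_curves.csv"), row.names = FALSE)
    utils::write.csv(rt, file.path(out_dir, "risk_table.csv"), row.names = FALSE)
    summ <- c(report["config"],
              list(effects = report$effects, n = report$n,
                   n_failed_replicates = report$n_failed_replicates,
                   ice_dispersion = report$ice_dispersion))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  }
  structure(report, class = "analysis_report")
}

#' @export
#' @method print analysis_report
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: outcome '%s', %s model, n = %d, B = %d (%d failed)\n",
              x$config$outcome, x$config$timepoint, x$n, x$config$B,
              x$n_failed_replicates))
  print(x$effects, digits = 3)
  invisible(x)
}
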