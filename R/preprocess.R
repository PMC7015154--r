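# Preprocessing: simplified total-PCB construction, log10 transform and
# centering of exposures, outcome standardization, complete-case filtering,
# covariate coding, and the per-exposure quantile table used for
# counterfactual assignments.

#' Simplified total PCB concentration
#'
#' Twice the sum of the three major congeners CB-138, CB-153, CB-180; when a
#' total-lipid value is supplied the result is expressed per gram of lipid.
#'
#' @param cb138,cb153,cb180 congener concentrations (>= 0, vectorized).
#' @param lipids optional total lipid concentration (g/L, > 0).
#' @export
sum_pcb <- function(cb138, cb153, cb180, lipids = NULL) {
  if (any(c(cb138, cb153, cb180) < 0, na.rm = TRUE))
    stop("congener concentrations must be non-negative")
  out <- 2 * (cb138 + cb153 + cb180)
  if (!is.null(lipids)) {
    if (any(lipids <= 0, na.rm = TRUE)) stop("lipid concentrations must be positive")
    out <- out / lipids
  }
  out
}

#' Log10-transform and mean-center an exposure matrix
#'
#' @param raw strictly positive matrix.
#' @return centered log10 matrix with the centering constants in attribute
#'   `"centers"` (so [inverse_transform_exposures()] can invert it).
#' @export
transform_exposures <- function(raw) {
  raw <- as.matrix(raw)
  bad <- which(!(raw > 0), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive exposure at row %d, column %s",
                 bad[1, 1], colnames(raw)[bad[1, 2]] %||% bad[1, 2]))
  lx <- log10(raw)
  ctr <- colMeans(lx)
  structure(sweep(lx, 2, ctr), centers = ctr)
}

#' Invert [transform_exposures()]
#' @param x centered log10 matrix carrying a `"centers"` attribute (or with
#'   `centers` supplied explicitly).
#' @param centers numeric vector of column centers.
#' @export
inverse_transform_exposures <- function(x, centers = attr(x, "centers")) {
  stopifnot(!is.null(centers))
  10^sweep(as.matrix(x), 2, centers, "+")
}

#' Standardize an outcome to mean 0, SD 1
#'
#' Uses the sample SD (n - 1 divisor) of the supplied (analysis-sample)
#' vector. Attributes `"center"`/`"scale"` carry the constants.
#'
#' @param y numeric vector with positive variance.
#' @export
standardize_outcome <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("outcome has zero variance")
  m <- mean(y)
  structure((y - m) / s, center = m, scale = s)
}

#' Complete-case filter
#'
#' Drops rows with any missing value in the required columns; row order is
#' preserved and per-column missingness counts are attached as attribute
#' `"dropped_by_column"`.
#'
#' @param table data.frame.
#' @param required_columns character vector of columns that must be non-missing.
#' @return list with `table` (filtered) and `kept` (original row indices).
#' @export
complete_case <- function(table, required_columns) {
  missing_cols <- setdiff(required_columns, names(table))
  if (length(missing_cols))
    stop("required columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  sub <- table[required_columns]
  miss <- vapply(sub, function(v) is.na(v), logical(nrow(table)))
  if (nrow(table) == 1L) miss <- matrix(miss, nrow = 1L)
  keep <- !apply(miss, 1, any)
  if (!any(keep)) stop("no complete cases remain")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_by_column") <- colSums(miss)
  list(table = out, kept = which(keep))
}

#' Type-7 percentile
#'
#' Linear interpolation between order statistics (the default rule in most
#' statistical software); `p` is on the 0-100 scale.
#'
#' @param x nonempty numeric vector; `p` percentile(s) in `[0, 100]`.
#' @export
pctile <- function(x, p) {
  if (!length(x)) stop("empty vector")
  stopifnot(all(p >= 0 & p <= 100))
  stats::quantile(x, p / 100, type = 7, names = FALSE)
}

# covariate sets per timepoint model
MATERNAL_COVARIATES <- c("age_months", "sex", "maternal_age", "bmi", "parity",
                         "raven", "ses", "alcohol", "smoking")
AGE5_EXTRA_COVARIATES <- c("breastfeeding", "birth_weight")

#' Code the covariate table as a numeric design matrix
#'
#' Binary factors (sex, alcohol) become single 0/1 indicators; three-level
#' factors (parity, SES, smoking) become two indicators against the first
#' level; continuous columns pass through.
#'
#' @param covariates data.frame.
#' @param columns which columns to code (default: all present).
#' @export
code_covariates <- function(covariates, columns = names(covariates)) {
  pieces <- lapply(columns, function(nm) {
    v <- covariates[[nm]]
    if (is.null(v)) stop("covariate not found: ", nm)
    if (is.factor(v) || is.character(v)) {
      v <- as.factor(v)
      lev <- levels(v)
      m <- vapply(lev[-1], function(l) as.numeric(v == l), numeric(length(v)))
      if (length(v) == 1L) m <- matrix(m, nrow = 1L)
      colnames(m) <- paste0(nm, "_", gsub("[^0-9A-Za-z]+", ".", lev[-1]))
      m
    } else {
      m <- matrix(as.numeric(v), ncol = 1L)
      colnames(m) <- nm
      m
    }
  })
  do.call(cbind, pieces)
}

#' Build the analysis-ready dataset
#'
#' Applies the complete-case rule, log10-transforms and centers the model's
#' exposures, codes covariates for the requested timepoint model (the age-5
#' model additionally adjusts for log10-centered maternal exposures,
#' breastfeeding and birth weight), standardizes the outcome on the analysis
#' sample, and tabulates per-exposure percentiles on the transformed scale.
#'
#' @param table one-row-per-child data.frame (e.g.
#'   `as.data.frame(simulate_cohort(...))`).
#' @param outcome outcome column name.
#' @param timepoint `"maternal"` or `"age5"` — which exposure set is the
#'   mixture of interest.
#' @param exposure_cols optional explicit exposure column names (default:
#'   `<pollutant>_mat` or `<pollutant>_5y` panel names found in the table).
#' @param covariate_cols optional explicit covariate column names.
#' @param standardize standardize the outcome (default TRUE).
#' @param id_col optional id column name.
#' @return an `analysis_dataset`: list with `Y`, `X` (centered log10
#'   exposures), `W` (coded covariates), `quantiles` (percentile table rows
#'   1..99 per exposure), `meta`.
#' @export
make_analysis_dataset <- function(table, outcome = "y",
                                  timepoint = c("maternal", "age5"),
                                  exposure_cols = NULL, covariate_cols = NULL,
                                  standardize = TRUE, id_col = "id") {
  timepoint <- match.arg(timepoint)
  suffix <- if (timepoint == "maternal") "_mat" else "_5y"
  if (is.null(exposure_cols))
    exposure_cols <- grep(paste0(suffix, "$"), names(table), value = TRUE)
  if (!length(exposure_cols)) stop("no exposure columns found for model ", timepoint)
  if (is.null(covariate_cols)) {
    covariate_cols <- intersect(MATERNAL_COVARIATES, names(table))
    if (timepoint == "age5")
      covariate_cols <- c(covariate_cols,
                          intersect(AGE5_EXTRA_COVARIATES, names(table)))
  }
  adj_exposures <- if (timepoint == "age5")
    grep("_mat$", names(table), value = TRUE) else character(0)

  required <- c(outcome, exposure_cols, covariate_cols, adj_exposures)
  cc <- complete_case(table, required)
  tab <- cc$table

  X <- transform_exposures(as.matrix(tab[exposure_cols]))
  W <- code_covariates(tab, covariate_cols)
  if (length(adj_exposures))
    W <- cbind(W, transform_exposures(as.matrix(tab[adj_exposures])))
  y <- tab[[outcome]]
  Y <- if (standardize) standardize_outcome(y) else y

  qgrid <- 1:99
  quantiles <- vapply(exposure_cols, function(e) pctile(X[, e], qgrid),
                      numeric(length(qgrid)))
  rownames(quantiles) <- qgrid

  structure(list(
    Y = as.numeric(Y), X = X, W = W, quantiles = quantiles,
    meta = list(outcome = outcome, timepoint = timepoint,
                n = nrow(tab), kept = cc$kept,
                ids = if (id_col %in% names(tab)) tab[[id_col]] else cc$kept,
                exposures = exposure_cols,
                y_center = attr(Y, "center"), y_scale = attr(Y, "scale"),
                x_centers = attr(X, "centers"),
                dropped_by_column = attr(tab, "dropped_by_column"))),
    class = "analysis_dataset")
}

#' Percentile of an exposure on the analysis (centered log10) scale
#' @param ds an `analysis_dataset`; `exposure` column name; `p` percentile.
#' @export
ds_quantile <- function(ds, exposure, p) {
  if (!exposure %in% colnames(ds$X)) stop_structural("unknown exposure: ", exposure)
  pctile(ds$X[, exposure], p)
}

#' @export
#' @method print analysis_dataset
print.analysis_dataset <- function(x, ...) {
  cat(sprintf("analysis_dataset: n = %d, outcome '%s' (%s model), %d exposures, %d covariate columns\n",
              x$meta$n, x$meta$outcome, x$meta$timepoint,
              ncol(x$X), ncol(x$W)))
  invisible(x)
}

# design matrix handed to learners
ds_design <- function(ds, X = ds$X) cbind(X, ds$W)
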