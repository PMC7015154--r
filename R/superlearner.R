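# Stacked ensemble: K-fold cross-validated predictions from the learner
# library, convex stacking weights minimizing cross-validated squared error,
# and a full-data refit used as the prediction oracle for G-computation.

#' K-fold cross-validation scheme
#'
#' Random permutation split into k near-equal folds (sizes differ by at most
#' one); the same assignment is reused for every learner.
#'
#' @param n rows; `k` folds (2..n); `seed` integer.
#' @return `cv_scheme` with the fold label of every row.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k > n) stop("more folds than observations")
  stopifnot(k >= 2L)
  assignment <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  structure(list(k = as.integer(k), assignment = assignment, seed = seed),
            class = "cv_scheme")
}

#' Cross-validated prediction matrix
#'
#' For each fold, every learner is trained on the complement and predicts the
#' held-out rows. A learner that errors on a fold contributes its training
#' mean for that fold's rows (with a warning) so the matrix stays complete.
#'
#' @param library list of [learner_spec()]s.
#' @param x design matrix; `y` outcome; `scheme` a [make_folds()] result.
#' @return n x L matrix `Z` of out-of-fold predictions; attribute
#'   `"failures"` counts per-learner fold failures.
#' @export
cross_validate <- function(library, x, y, scheme) {
  stopifnot(length(library) >= 1L, nrow(x) == length(y))
  L <- length(library)
  n <- nrow(x)
  Z <- matrix(NA_real_, n, L)
  failures <- integer(L)
  for (f in seq_len(scheme$k)) {
    hold <- scheme$assignment == f
    xtr <- x[!hold, , drop = FALSE]; ytr <- y[!hold]
    xte <- x[hold, , drop = FALSE]
    for (l in seq_len(L)) {
      sd_l <- derive_seed(scheme$seed,
                          sprintf("cv:%s:%d:%d", library[[l]]$id,
                                  library[[l]]$seed_offset, f))
      err <- FALSE
      pred <- tryCatch(
        with_seed(sd_l, {
          fit <- fit_learner(library[[l]], xtr, ytr)
          predict_learner(fit, xte)
        }),
        error = function(e) {
          warning(sprintf("learner '%s' failed on fold %d: %s",
                          library[[l]]$id, f, conditionMessage(e)),
                  call. = FALSE)
          err <<- TRUE
          rep(mean(ytr), sum(hold))
        })
      if (err || any(!is.finite(pred))) {
        failures[l] <- failures[l] + 1L
        pred[!is.finite(pred)] <- mean(ytr)
      }
      Z[hold, l] <- pred
    }
  }
  if (anyNA(Z)) stop("cross-validation left unpredicted rows")
  colnames(Z) <- vapply(library, `[[`, character(1), "id")
  structure(Z, failures = failures)
}

#' Convex stacking weights from cross-validated predictions
#'
#' Solves `min ||y - Z a||^2` over the probability simplex (`a >= 0`,
#' `sum a = 1`) as a quadratic program; the simplex constraint guarantees
#' the ensemble's cross-validated MSE never exceeds the best single
#' learner's. Degenerate problems fall back to unit weight on the learner
#' with the lowest cross-validated MSE.
#'
#' @param Z n x L matrix of out-of-fold predictions.
#' @param y outcome vector.
#' @return weight vector on the simplex (named by Z's columns).
#' @export
solve_weights <- function(Z, y) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(y), all(is.finite(Z)))
  L <- ncol(Z)
  if (L == 1L) return(stats::setNames(1, colnames(Z)))
  D <- crossprod(Z) + 1e-8 * diag(L)
  d <- crossprod(Z, y)
  A <- cbind(rep(1, L), diag(L))
  b0 <- c(1, rep(0, L))
  alpha <- tryCatch(
    quadprog::solve.QP(D, d, A, b0, meq = 1)$solution,
    error = function(e) NULL)
  if (is.null(alpha) || all(alpha <= 0)) {
    mse <- colMeans((y - Z)^2)
    alpha <- as.numeric(seq_len(L) == which.min(mse))
  }
  alpha[alpha < 0] <- 0
  alpha <- alpha / sum(alpha)
  stats::setNames(alpha, colnames(Z))
}

#' Fit the full SuperLearner
#'
#' Runs [make_folds()], [cross_validate()] and [solve_weights()], then refits
#' every learner on the full analysis sample. A learner that fails on the
#' full data has its weight redistributed proportionally among the others.
#'
#' @param data an `analysis_dataset`, or a design matrix if `y` is given.
#' @param library learner library (list of [learner_spec()]s or a preset
#'   name for [learner_library()]).
#' @param y outcome vector (unneeded when `data` is an `analysis_dataset`).
#' @param k folds (default 10); `seed` master seed for folds and learners.
#' @return `superlearner_fit` with weights, per-learner and ensemble
#'   cross-validated MSE, refit learners, and the CV scheme.
#' @export
superlearner <- function(data, library = "fast", y = NULL, k = 10L, seed = 1L) {
  if (inherits(data, "analysis_dataset")) {
    x <- ds_design(data)
    y <- data$Y
  } else x <- as.matrix(data)
  library <- as_learner_library(library)
  scheme <- make_folds(nrow(x), k, seed = derive_seed(seed, "folds"))
  Z <- cross_validate(library, x, y, scheme)
  alpha <- solve_weights(Z, y)
  cv_mse <- colMeans((y - Z)^2)
  ens_mse <- mean((y - drop(Z %*% alpha))^2)

  fits <- vector("list", length(library))
  ok <- rep(TRUE, length(library))
  for (l in seq_along(library)) {
    sd_l <- derive_seed(seed, sprintf("full:%s:%d", library[[l]]$id,
                                      library[[l]]$seed_offset))
    fits[[l]] <- tryCatch(
      with_seed(sd_l, fit_learner(library[[l]], x, y)),
      error = function(e) {
        warning(sprintf("learner '%s' failed on full data: %s",
                        library[[l]]$id, conditionMessage(e)), call. = FALSE)
        NULL
      })
    ok[l] <- !is.null(fits[[l]])
  }
  if (!any(ok)) stop("every learner failed on the full data")
  if (!all(ok)) {
    alpha[!ok] <- 0
    if (sum(alpha) == 0) alpha[ok][which.min(cv_mse[ok])] <- 1
    alpha <- alpha / sum(alpha)
  }
  structure(list(
    weights = alpha, cv_mse = cv_mse, ensemble_cv_mse = ens_mse,
    cv_predictions = Z, learners = fits,
    library = library, scheme = scheme,
    cols = colnames(x), seed = seed),
    class = "superlearner_fit")
}

#' Predict from a fitted SuperLearner
#'
#' Convex combination of the refit learners' predictions.
#'
#' @param object a `superlearner_fit`; `newdata` matrix with the training
#'   columns (an `analysis_dataset` is also accepted).
#' @param ... unused.
#' @export
predict.superlearner_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "analysis_dataset")) newdata <- ds_design(newdata)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!all(object$cols %in% colnames(newdata)))
      stop_structural("prediction columns do not match training columns")
    newdata <- newdata[, object$cols, drop = FALSE]
  } else if (ncol(newdata) != length(object$cols)) {
    stop_structural("prediction columns do not match training columns")
  }
  out <- numeric(nrow(newdata))
  for (l in seq_along(object$learners)) {
    if (object$weights[l] == 0 || is.null(object$learners[[l]])) next
    out <- out + object$weights[l] * predict_learner(object$learners[[l]], newdata)
  }
  out
}

#' Per-learner risk/weight table
#'
#' One row per learner (cross-validated MSE and stacking weight) plus an
#' ensemble row, the tabular form of the usual SuperLearner risk figure.
#'
#' @param fit a `superlearner_fit`.
#' @param file optional CSV path to write the table to.
#' @export
risk_table <- function(fit, file = NULL) {
  tab <- data.frame(
    learner = c(vapply(fit$library, `[[`, character(1), "id"), "super_learner"),
    cv_mse = c(fit$cv_mse, fit$ensemble_cv_mse),
    weight = c(fit$weights, NA_real_))
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}

#' @export
#' @method print superlearner_fit
print.superlearner_fit <- function(x, ...) {
  cat("superlearner_fit:", length(x$library), "learners, k =", x$scheme$k, "\n")
  print(risk_table(x), digits = 4)
  invisible(x)
}
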