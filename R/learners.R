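# Learner library for the stacked ensemble. Eight algorithm families are
# registered; glm, gam and elastic_net sit on stats/mgcv/glmnet, while the
# tree ensembles, the RBF kernel machine, the polynomial learner and the
# neural net are implemented locally (see trees.R and below) because the
# usual CRAN packages for them are not part of the supported stack.
#
# Every learner is fit through fit_learner(spec, x, y) and queried through
# predict_learner(fit, x); both work on plain numeric matrices.

LEARNER_IDS <- c("glm", "gam", "elastic_net", "poly", "svm_krr",
                 "gbm", "random_forest", "neural_net", "mean")

#' Declare a learner for the SuperLearner library
#'
#' @param id one of `"glm"`, `"gam"`, `"elastic_net"`, `"poly"` (degree-2
#'   polynomial basis with lasso selection, standing in for adaptive
#'   polynomial spline regression), `"svm_krr"` (radial-basis kernel ridge
#'   regression, the least-squares analogue of a support vector machine),
#'   `"gbm"`, `"random_forest"`, `"neural_net"`, or the benchmark `"mean"`.
#' @param hyperparameters named list overriding the learner's defaults.
#' @param seed_offset integer folded into the fold seed so stochastic
#'   learners get reproducible independent streams.
#' @return a `learner_spec` object.
#' @export
learner_spec <- function(id, hyperparameters = list(), seed_offset = 0L) {
  # field-standard aliases for the local implementations
  id <- switch(id, poly_mars = "poly", svm = "svm_krr", id)
  id <- match.arg(id, LEARNER_IDS)
  stopifnot(is.list(hyperparameters))
  structure(list(id = id, hyperparameters = hyperparameters,
                 seed_offset = as.integer(seed_offset)),
            class = "learner_spec")
}

#' Build a learner library
#'
#' @param ids character vector of learner ids, or a preset name:
#'   `"full"` = all eight algorithms, `"fast"` = glm + elastic net + random
#'   forest (the reduced library used inside bootstrap loops).
#' @param hyperparameters optional named list (by learner id) of overrides.
#' @return list of `learner_spec` objects.
#' @export
learner_library <- function(ids = "fast", hyperparameters = list()) {
  if (length(ids) == 1L && ids %in% c("full", "fast")) {
    preset <- ids
    ids <- switch(preset,
      full = c("glm", "gam", "elastic_net", "poly", "svm_krr",
               "gbm", "random_forest", "neural_net"),
      fast = c("glm", "elastic_net", "random_forest"))
    if (preset == "fast" && is.null(hyperparameters$random_forest))
      # lighter forest so bootstrap loops stay tractable
      hyperparameters$random_forest <- list(ntree = 40L, max_depth = 4L,
                                            min_node = 10L)
  }
  lapply(seq_along(ids), function(i)
    learner_spec(ids[i], hyperparameters[[ids[i]]] %||% list(),
                 seed_offset = i))
}

# normalize any acceptable library representation (preset string, vector of
# ids, list of learner_spec, list of plain lists from a deserialized config)
as_learner_library <- function(library) {
  if (is.character(library)) return(learner_library(library))
  stopifnot(is.list(library), length(library) >= 1L)
  lapply(library, function(s) {
    if (inherits(s, "learner_spec")) s
    else learner_spec(s$id, s$hyperparameters %||% list(),
                      s$seed_offset %||% 0L)
  })
}

fit_learner <- function(spec, x, y) {
  hp <- spec$hyperparameters
  fit <- switch(spec$id,
    mean = list(mu = mean(y)),
    glm = fit_ols(x, y),
    gam = fit_gam_learner(x, y, hp),
    elastic_net = fit_enet(x, y, hp),
    poly = fit_poly(x, y, hp),
    svm_krr = fit_krr(x, y, hp),
    gbm = fit_gbt(x, y,
                  ntree = hp$ntree %||% 200L,
                  shrinkage = hp$shrinkage %||% 0.05,
                  max_depth = hp$max_depth %||% 3L),
    random_forest = fit_forest(x, y,
                               ntree = hp$ntree %||% 100L,
                               mtry = hp$mtry %||% max(1L, floor(ncol(x) / 3)),
                               max_depth = hp$max_depth %||% 8L,
                               min_node = hp$min_node %||% 5L),
    neural_net = fit_mlp(x, y,
                         size = hp$size %||% 5L,
                         decay = hp$decay %||% 0.01,
                         maxit = hp$maxit %||% 200L))
  structure(list(id = spec$id, fit = fit, cols = colnames(x)),
            class = "mixg_learner")
}

predict_learner <- function(object, x) {
  if (!is.null(object$cols) && !is.null(colnames(x))) {
    if (!all(object$cols %in% colnames(x)))
      stop_structural("prediction columns do not match training columns")
    x <- x[, object$cols, drop = FALSE]
  }
  f <- object$fit
  switch(object$id,
    mean = rep(f$mu, nrow(x)),
    glm = drop(cbind(1, x) %*% f$coef),
    gam = {
      nd <- as.data.frame(x)
      names(nd) <- paste0("V", seq_len(ncol(x))) # training-formula names
      as.numeric(mgcv::predict.gam(f, newdata = nd))
    },
    elastic_net = drop(stats::predict(f, newx = x, s = "lambda.min")),
    poly = predict_poly(f, x),
    svm_krr = predict_krr(f, x),
    gbm = predict_gbt(f, x),
    random_forest = predict_forest(f, x),
    neural_net = predict_mlp(f, x))
}

# -- ordinary least squares (rank-deficiency tolerant) ------------------------

fit_ols <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = cf)
}

# -- generalized additive model ----------------------------------------------

fit_gam_learner <- function(x, y, hp) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  kk <- hp$k %||% 4L
  terms <- vapply(seq_len(ncol(x)), function(j) {
    nu <- length(unique(df[[j]]))
    if (nu > 2L * kk) sprintf("s(V%d, k = %d)", j, kk) else sprintf("V%d", j)
  }, character(1))
  df$.y <- y
  fit <- mgcv::gam(stats::reformulate(terms, response = ".y"), data = df,
                   method = "GCV.Cp")
  fit$mixg_names <- names(df)
  fit
}

# -- elastic net (internal CV over the penalty) ------------------------------

fit_enet <- function(x, y, hp) {
  glmnet::cv.glmnet(x, y,
                    alpha = hp$alpha %||% 0.5,
                    nfolds = hp$nfolds %||% 5L,
                    nlambda = hp$nlambda %||% 50L,
                    standardize = TRUE)
}

# -- degree-2 polynomial basis + lasso selection -----------------------------

poly_basis <- function(x, degree = 2L) {
  p <- ncol(x)
  out <- list(x)
  nm <- colnames(x) %||% paste0("x", seq_len(p))
  names_out <- nm
  if (degree >= 2L) {
    out[[2]] <- x^2
    names_out <- c(names_out, paste0(nm, "^2"))
    if (p >= 2L) {
      pairs <- utils::combn(p, 2L)
      inter <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
      out[[3]] <- inter
      names_out <- c(names_out, paste0(nm[pairs[1, ]], ":", nm[pairs[2, ]]))
    }
  }
  b <- do.call(cbind, out)
  colnames(b) <- names_out
  b
}

fit_poly <- function(x, y, hp) {
  degree <- hp$degree %||% 2L
  # standardize before expansion: squared/product terms of raw-scale columns
  # (e.g. birth weight in grams) otherwise stall the lasso solver
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  b <- poly_basis(scale(x, ctr, scl), degree)
  # alpha = 1 (lasso) selects terms adaptively; alpha = 0 gives a
  # selection-free ridge on the full basis
  fit <- glmnet::cv.glmnet(b, y, alpha = hp$alpha %||% 1,
                           nfolds = hp$nfolds %||% 5L,
                           nlambda = hp$nlambda %||% 50L)
  list(degree = degree, ctr = ctr, scl = scl, fit = fit)
}

predict_poly <- function(f, x) {
  b <- poly_basis(scale(x, f$ctr, f$scl), f$degree)
  drop(stats::predict(f$fit, newx = b, s = "lambda.min"))
}

# -- radial-basis kernel ridge regression ------------------------------------
# Inputs are standardized internally; the bandwidth defaults to the median
# pairwise distance heuristic on (a subsample of) the training rows.

fit_krr <- function(x, y, hp) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  n <- nrow(xs)
  sub <- if (n > 200L) xs[sample.int(n, 200L), , drop = FALSE] else xs
  d2 <- as.numeric(stats::dist(sub))^2
  sigma2 <- stats::median(d2[d2 > 0])
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- ncol(x)
  gamma <- 1 / sigma2
  K <- exp(-gamma * sq_dist(xs, xs))
  lambda <- hp$lambda %||% 0.1
  ybar <- mean(y)
  alpha <- solve(K + lambda * diag(n), y - ybar)
  list(xtrain = xs, ctr = ctr, scl = scl, gamma = gamma,
       alpha = alpha, ybar = ybar)
}

sq_dist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

predict_krr <- function(f, x) {
  xs <- scale(x, f$ctr, f$scl)
  drop(exp(-f$gamma * sq_dist(xs, f$xtrain)) %*% f$alpha) + f$ybar
}

# -- single-hidden-layer neural net with weight decay ------------------------
# tanh hidden units, linear output, penalized least squares via BFGS with
# analytic gradients; inputs standardized, outcome centered/scaled.

fit_mlp <- function(x, y, size = 5L, decay = 0.01, maxit = 200L) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yy <- (y - ym) / ys
  p <- ncol(xs); n <- nrow(xs); H <- size
  npar <- H * (p + 1L) + H + 1L
  unpack <- function(w) {
    W1 <- matrix(w[seq_len(H * p)], p, H)
    b1 <- w[H * p + seq_len(H)]
    W2 <- w[H * p + H + seq_len(H)]
    b2 <- w[npar]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  obj <- function(w) {
    q <- unpack(w)
    A <- tanh(sweep(xs %*% q$W1, 2, q$b1, "+"))
    r <- drop(A %*% q$W2) + q$b2 - yy
    mean(r^2) + decay * sum(w^2)
  }
  grad <- function(w) {
    q <- unpack(w)
    Z <- sweep(xs %*% q$W1, 2, q$b1, "+")
    A <- tanh(Z)
    r <- drop(A %*% q$W2) + q$b2 - yy
    gW2 <- drop(crossprod(A, r)) * 2 / n
    gb2 <- 2 * mean(r)
    D <- (r %o% q$W2) * (1 - A^2)      # n x H
    gW1 <- crossprod(xs, D) * 2 / n
    gb1 <- colSums(D) * 2 / n
    c(as.numeric(gW1), gb1, gW2, gb2) + 2 * decay * w
  }
  w0 <- stats::runif(npar, -0.5, 0.5)
  opt <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-8))
  list(w = opt$par, H = H, p = p, ctr = ctr, scl = scl, ym = ym, ys = ys)
}

predict_mlp <- function(f, x) {
  xs <- scale(x, f$ctr, f$scl)
  H <- f$H; p <- f$p
  W1 <- matrix(f$w[seq_len(H * p)], p, H)
  b1 <- f$w[H * p + seq_len(H)]
  W2 <- f$w[H * p + H + seq_len(H)]
  b2 <- f$w[H * (p + 1L) + H + 1L]
  A <- tanh(sweep(xs %*% W1, 2, b1, "+"))
  (drop(A %*% W2) + b2) * f$ys + f$ym
}
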