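# Internal helpers: seed derivation, validation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Hashes `key` with a small multiplicative string hash and folds it into
#' `master` so that every pipeline stage (folds, learners, resamples, ...)
#' gets its own independent, deterministic stream. Result is always a
#' non-negative value below 2^31 so it is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param key character scalar naming the substream.
#' @return integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(master) %% 2147483647 + 2 * h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_structural <- function(...) stop(..., call. = FALSE)

assert_matrix_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_structural("expected a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop_structural("matrix is not symmetric")
  invisible(TRUE)
}
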