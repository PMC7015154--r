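# Minimal CART-style regression trees plus bagged-forest and gradient-boosting
# ensembles built on them. Self-contained so the learner library does not
# depend on tree packages; splits use the usual variance-reduction criterion
# computed with cumulative sums so a tree fit stays fast in pure R.

# Grow one regression tree. Nodes are accumulated in parallel vectors; child
# indices always exceed the parent index so prediction can route rows in one
# forward pass.
grow_tree <- function(x, y, max_depth = 3L, min_node = 10L, mtry = ncol(x)) {
  n <- nrow(x)
  p <- ncol(x)
  mtry <- max(1L, min(as.integer(mtry), p))
  # each feature is sorted once; nodes subset the sorted order through a
  # membership mask, avoiding a per-node order() call
  ords <- lapply(seq_len(p), function(j) order(x[, j]))
  nodes_cap <- 2L^(max_depth + 1L)
  var_ <- rep(NA_integer_, nodes_cap); split_ <- rep(NA_real_, nodes_cap)
  left_ <- rep(NA_integer_, nodes_cap); right_ <- rep(NA_integer_, nodes_cap)
  pred_ <- rep(NA_real_, nodes_cap)
  used <- 0L

  best_split <- function(member, m) {
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    tot <- sum(y[member])
    best <- NULL; best_gain <- 0
    base <- tot^2 / m
    i <- seq_len(m - 1L)
    for (j in feats) {
      oj <- ords[[j]]
      oj <- oj[member[oj]]
      xs <- x[oj, j]
      if (xs[1] == xs[m]) next
      ok <- xs[i] < xs[i + 1L]
      if (!any(ok)) next
      cs <- cumsum(y[oj])[-m]
      gain <- cs^2 / i + (tot - cs)^2 / (m - i) - base
      gain[!ok] <- -Inf
      b <- which.max(gain)
      if (gain[b] > best_gain + 1e-12) {
        best_gain <- gain[b]
        best <- list(var = j, split = (xs[b] + xs[b + 1L]) / 2,
                     left = oj[seq_len(b)], right = oj[-seq_len(b)])
      }
    }
    best
  }

  build <- function(rows, depth) {
    used <<- used + 1L
    id <- used
    pred_[id] <<- mean(y[rows])
    if (depth < max_depth && length(rows) >= min_node) {
      member <- logical(n)
      member[rows] <- TRUE
      sp <- best_split(member, length(rows))
      if (!is.null(sp)) {
        var_[id] <<- sp$var
        split_[id] <<- sp$split
        left_[id] <<- build(sp$left, depth + 1L)
        right_[id] <<- build(sp$right, depth + 1L)
      }
    }
    id
  }
  build(seq_len(n), 0L)
  keep <- seq_len(used)
  list(var = var_[keep], split = split_[keep], left = left_[keep],
       right = right_[keep], pred = pred_[keep])
}

predict_tree <- function(tree, x) {
  n <- nrow(x)
  node <- rep(1L, n)
  repeat {
    internal <- !is.na(tree$var[node])
    if (!any(internal)) break
    idx <- which(internal)
    nd <- node[idx]
    goes_left <- x[cbind(idx, tree$var[nd])] <= tree$split[nd]
    node[idx] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
  }
  tree$pred[node]
}

# Bagged forest with per-node feature subsampling (mtry), i.e. a basic
# random forest for regression.
fit_forest <- function(x, y, ntree = 100L, mtry = max(1L, floor(ncol(x) / 3)),
                       max_depth = 8L, min_node = 5L) {
  n <- nrow(x)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[rows, , drop = FALSE], y[rows],
                            max_depth = max_depth, min_node = min_node,
                            mtry = mtry)
  }
  list(trees = trees)
}

predict_forest <- function(fit, x) {
  preds <- vapply(fit$trees, predict_tree, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) mean(preds) else rowMeans(preds)
}

# Stage-wise gradient boosting with shallow trees and shrinkage; squared
# error loss, so each stage fits the current residuals.
fit_gbt <- function(x, y, ntree = 200L, shrinkage = 0.05, max_depth = 3L,
                    min_node = 10L, subsample = 0.8) {
  n <- nrow(x)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", ntree)
  for (m in seq_len(ntree)) {
    rows <- if (subsample < 1) sample.int(n, max(2L, floor(subsample * n))) else seq_len(n)
    tr <- grow_tree(x[rows, , drop = FALSE], resid[rows],
                    max_depth = max_depth, min_node = min_node)
    step <- shrinkage * predict_tree(tr, x)
    resid <- resid - step
    trees[[m]] <- tr
  }
  list(f0 = f0, shrinkage = shrinkage, trees = trees)
}

predict_gbt <- function(fit, x) {
  out <- rep(fit$f0, nrow(x))
  for (tr in fit$trees) out <- out + fit$shrinkage * predict_tree(tr, x)
  out
}
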