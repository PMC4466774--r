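#' @title Regression trees for boosting stages
#' @name trees
#' @description A small CART-style regression tree used as the stage learner
#'   inside gradient boosting: axis-aligned binary splits chosen to minimize
#'   the summed squared error of the two children (variance reduction), with
#'   each split searched over a random subset of the markers and leaves
#'   predicting the mean of their targets. Genotype codes take few distinct
#'   values, so candidate thresholds are midpoints between consecutive
#'   observed values.
NULL

# run expr with a deterministic RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Tree learner contract
#'
#' Shared configuration of the stage trees used by boosting and of the
#' random-forest learners: a depth cap, the fraction of markers sampled when
#' searching each split, and a seed that makes fitting deterministic.
#'
#' @param max_depth maximum tree depth (root = depth 0).
#' @param max_features fraction in (0, 1] of markers considered per split.
#' @param seed integer seed controlling feature subsampling.
#' @export
tree_contract <- function(max_depth = 5L, max_features = 0.6, seed = 1L) {
  if (max_features <= 0 || max_features > 1)
    stop("max_features must be in (0, 1]")
  if (max_depth < 0) stop("max_depth must be >= 0")
  structure(list(max_depth = as.integer(max_depth),
                 max_features = max_features, seed = as.integer(seed)),
            class = "tree_contract")
}

# best SSE split of one feature column; NULL if the column admits no split
.best_split_col <- function(xcol, targets) {
  ord <- order(xcol)
  xs <- xcol[ord]; ts <- targets[ord]
  n <- length(ts)
  cut_ok <- which(xs[-n] < xs[-1L])          # boundaries between distinct values
  if (length(cut_ok) == 0L) return(NULL)
  c1 <- cumsum(ts); c2 <- cumsum(ts^2)
  i <- cut_ok
  sse_left <- c2[i] - c1[i]^2 / i
  sse_right <- (c2[n] - c2[i]) - (c1[n] - c1[i])^2 / (n - i)
  sse <- sse_left + sse_right
  best <- which.min(sse)
  list(threshold = (xs[i[best]] + xs[i[best] + 1L]) / 2, sse = sse[best])
}

.grow_tree <- function(X, targets, rows, depth, contract) {
  t_here <- targets[rows]
  leaf <- list(leaf = TRUE, value = mean(t_here), n = length(rows))
  if (depth >= contract$max_depth || length(rows) < 2L ||
      stats::var(t_here) == 0) return(leaf)
  p <- ncol(X)
  n_feat <- max(1L, ceiling(contract$max_features * p))
  feats <- if (n_feat >= p) seq_len(p) else sample.int(p, n_feat)
  best <- NULL
  for (f in feats) {
    sp <- .best_split_col(X[rows, f], t_here)
    if (!is.null(sp) && (is.null(best) || sp$sse < best$sse)) {
      best <- sp; best$feature <- f
    }
  }
  if (is.null(best)) return(leaf)           # all sampled columns constant
  go_left <- X[rows, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = .grow_tree(X, targets, rows[go_left], depth + 1L, contract),
       right = .grow_tree(X, targets, rows[!go_left], depth + 1L, contract))
}

#' Fit a regression tree
#'
#' @param X numeric genotype matrix (n x p).
#' @param targets numeric response vector of length n (trait values,
#'   residuals or lambda-gradients depending on the caller).
#' @param contract a [tree_contract()].
#' @return A `regression_tree` (nested list of split/leaf nodes).
#' @export
fit_regression_tree <- function(X, targets, contract = tree_contract()) {
  X <- unclass(as.matrix(X)); targets <- as.numeric(targets)
  if (nrow(X) != length(targets)) stop("nrow(X) must match length(targets)")
  if (nrow(X) < 1L) stop("empty training set")
  root <- .with_seed(contract$seed,
                     .grow_tree(X, targets, seq_len(nrow(X)), 0L, contract))
  structure(list(root = root, p = ncol(X), contract = contract),
            class = "regression_tree")
}

.predict_node <- function(node, X, rows, out) {
  if (node$leaf) { out[rows] <- node$value; return(out) }
  go_left <- X[rows, node$feature] <= node$threshold
  out <- .predict_node(node$left, X, rows[go_left], out)
  .predict_node(node$right, X, rows[!go_left], out)
}

#' @export
predict.regression_tree <- function(object, X_new, ...) {
  X_new <- unclass(as.matrix(X_new))
  if (ncol(X_new) != object$p)
    stop(sprintf("marker count mismatch: tree trained on %d, got %d",
                 object$p, ncol(X_new)))
  .predict_node(object$root, X_new, seq_len(nrow(X_new)), numeric(nrow(X_new)))
}
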