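#' @title Boosted tree ensembles: GBRT and LambdaMART
#' @name ensemble_models
#' @description Stage-wise tree ensembles `h(x) = h0 + sum_s w_s h_s(x)`.
#'   GBRT fits each stage tree to the current squared-loss residuals, with an
#'   exact line-search stage weight shrunk by the learning rate. LambdaMART
#'   replaces the residuals by lambda-gradients: per-individual sums of
#'   pairwise push strengths that combine the NDCG change from swapping two
#'   individuals with a logistic derivative of their score difference, so the
#'   ensemble climbs NDCG@k directly even though NDCG itself is piecewise
#'   constant in the scores.
NULL

.new_ensemble <- function(base_value, stages, lr, kind, extra = list()) {
  structure(c(list(base_value = base_value, stages = stages,
                   learning_rate = lr, kind = kind), extra),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("tree_ensemble (%s): base %.4g + %d stage(s), learning rate %g\n",
              x$kind, x$base_value, length(x$stages), x$learning_rate))
  invisible(x)
}

#' Predict from a tree ensemble
#'
#' @param object a `tree_ensemble` from [fit_gbrt()] or [fit_lambdamart()].
#' @param X_new genotype matrix with the training marker count.
#' @param ... unused.
#' @export
predict.tree_ensemble <- function(object, X_new, ...) {
  X_new <- unclass(as.matrix(X_new))
  out <- rep(object$base_value, nrow(X_new))
  for (st in object$stages)
    out <- out + st$weight * predict(st$tree, X_new)
  out
}

#' Gradient-boosted regression trees (squared loss)
#'
#' Starts from the constant base model `h0 = mean(y)` and, at each stage,
#' fits a tree to the residuals of the ensemble so far. The stage weight is
#' the exact squared-loss line search `<e, t> / <t, t>` multiplied by the
#' learning rate, so training MSE is non-increasing for `lr <= 1`.
#'
#' @param X training genotype matrix (n x p).
#' @param y training trait values.
#' @param n_stages number of boosting stages M (0 gives the base model).
#' @param learning_rate shrinkage in (0, 1]; 0.1 is a good rule of thumb.
#' @param contract a [tree_contract()]; stage s uses the derived seed
#'   `contract$seed + s`.
#' @return A `tree_ensemble`.
#' @export
fit_gbrt <- function(X, y, n_stages = 300L, learning_rate = 0.1,
                     contract = tree_contract()) {
  X <- unclass(as.matrix(X)); y <- as.numeric(y)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  if (n_stages < 0) stop("n_stages must be >= 0")
  base <- mean(y)
  preds <- rep(base, length(y))
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    e <- y - preds
    ctr <- contract; ctr$seed <- contract$seed + s
    tree <- fit_regression_tree(X, e, ctr)
    t_pred <- predict(tree, X)
    denom <- sum(t_pred^2)
    alpha_s <- if (denom > 0) sum(e * t_pred) / denom else 0
    w <- learning_rate * alpha_s
    preds <- preds + w * t_pred
    stages[[s]] <- list(tree = tree, weight = w)
  }
  .new_ensemble(base, stages, learning_rate, "gbrt")
}

# discounts truncated at position k: d(i) = 1/log2(i+1) for i <= k, else 0
.truncated_discounts <- function(n, k, spec) {
  d <- numeric(n)
  d[seq_len(k)] <- spec$discount_fun(seq_len(k))
  d
}

#' NDCG change from swapping two ranked individuals
#'
#' Absolute change of NDCG@k caused by exchanging the ranks of individuals
#' `i` and `j` in the ranking `perm`. Only the two swapped positions change,
#' so the change equals `|(g_i - g_j) (d(pos_j) - d(pos_i))| / idealDCG@k`
#' with the discount set to zero beyond position k. It is exactly 0 when
#' both individuals rank below k or when their gains are equal, and
#' symmetric in i and j. The normalization by the ideal DCG makes stage
#' gradients scale-free across traits.
#'
#' @param y nonnegative reference trait values.
#' @param perm current score-induced ranking (see [induced_permutation()]).
#' @param i,j distinct individual indices (not ranks).
#' @param k NDCG position cutoff.
#' @param spec a [gain_discount_spec()].
#' @export
delta_ndcg_swap <- function(y, perm, i, j, k, spec = gain_discount_spec()) {
  y <- as.numeric(y)
  n <- length(y)
  if (k < 1L || k > n) stop(sprintf("k = %d outside 1..n = %d", k, n))
  if (i == j) stop("i and j must differ")
  if (min(y) < 0) stop("NDCG requires nonnegative reference values")
  ideal <- dcg_at_k(y, induced_permutation(y), k, spec)
  if (ideal == 0) return(0)
  pos <- integer(n); pos[perm] <- seq_len(n)
  d <- .truncated_discounts(n, k, spec)
  g <- spec$gain_fun(y)
  abs((g[i] - g[j]) * (d[pos[j]] - d[pos[i]])) / ideal
}

#' Lambda-gradient of NDCG@k
#'
#' For every strict preference pair `(i, j)` (meaning `y_i > y_j`) the pair
#' contribution is
#' `lambda_ij = |DeltaNDCG_ij| * 1 / (1 + exp(s_i - s_j))`,
#' the NDCG swap change weighted by the derivative of a logistic pairwise
#' loss of the score difference `o_ij = s_i - s_j`. The preferred individual
#' i receives an upward push `+lambda_ij` and j the matching downward push
#' `-lambda_ij` (antisymmetry), so the per-individual gradients
#' `lambda_i = sum_j lambda_ij` always sum to zero. Pairs with both
#' individuals ranked below k contribute nothing.
#'
#' @param y nonnegative reference trait values, not constant.
#' @param s current predicted scores.
#' @param k NDCG position cutoff.
#' @param spec a [gain_discount_spec()].
#' @return A `lambda_state`: list with `lambda` (n-vector), `pairs` (the
#'   preference pairs), `pair_lambda` (per-pair push strengths) and `k`.
#' @export
lambda_gradient <- function(y, s, k, spec = gain_discount_spec()) {
  y <- as.numeric(y); s <- as.numeric(s)
  .check_lengths(y, s)
  if (min(y) < 0) stop("NDCG requires nonnegative reference values")
  pairs <- pair_partition(y, y)$preference
  if (nrow(pairs) == 0L) stop("constant trait: no preference pairs")
  n <- length(y)
  perm <- induced_permutation(s)
  pos <- integer(n); pos[perm] <- seq_len(n)
  d <- .truncated_discounts(n, k, spec)
  g <- spec$gain_fun(y)
  ideal <- dcg_at_k(y, induced_permutation(y), k, spec)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  dn <- if (ideal > 0)
    abs((g[i] - g[j]) * (d[pos[j]] - d[pos[i]])) / ideal else numeric(length(i))
  rho <- 1 / (1 + exp(s[i] - s[j]))
  lij <- dn * rho
  lam <- numeric(n)
  acc <- rowsum(c(lij, -lij), group = c(i, j))
  lam[as.integer(rownames(acc))] <- acc[, 1L]
  structure(list(lambda = lam, pairs = pairs, pair_lambda = lij, k = k),
            class = "lambda_state")
}

#' LambdaMART: boosted trees driven by lambda-gradients
#'
#' Builds a tree ensemble whose stage targets are the lambda-gradients of
#' NDCG@k at the current scores. Stage trees enter with weight equal to the
#' learning rate; the lambda surrogate has no primitive objective to
#' line-search. Scores start at 0: only score differences matter for
#' ranking, so a constant base adds nothing.
#'
#' @inheritParams fit_gbrt
#' @param k NDCG position cutoff being optimized.
#' @return A `tree_ensemble` with `kind = "lambdamart"`.
#' @export
fit_lambdamart <- function(X, y, k = 10L, n_stages = 300L, learning_rate = 0.1,
                           contract = tree_contract()) {
  X <- unclass(as.matrix(X)); y <- as.numeric(y)
  if (min(y) < 0)
    stop("NDCG requires nonnegative trait values; apply shift_nonnegative() first")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  k <- min(as.integer(k), length(y))
  scores <- numeric(length(y))
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    lam <- lambda_gradient(y, scores, k)$lambda
    ctr <- contract; ctr$seed <- contract$seed + s
    tree <- fit_regression_tree(X, lam, ctr)
    scores <- scores + learning_rate * predict(tree, X)
    stages[[s]] <- list(tree = tree, weight = learning_rate)
  }
  .new_ensemble(0, stages, learning_rate, "lambdamart", extra = list(k = k))
}

#' Random-forest regression baseline
#'
#' Bagged randomized trees via the ranger package (the standard engine for
#' this learner); single-threaded so a seed fully determines the forest.
#'
#' @param X training genotype matrix.
#' @param y training trait values.
#' @param num_trees forest size (default 300).
#' @param max_depth depth cap (0 = unlimited, ranger convention).
#' @param max_features fraction of markers tried per split.
#' @param seed integer seed.
#' @return An `rf_model` wrapping the ranger fit.
#' @export
fit_rf_regressor <- function(X, y, num_trees = 300L, max_depth = 0L,
                             max_features = 0.6, seed = 1L) {
  X <- unclass(as.matrix(X))
  colnames(X) <- paste0("m", seq_len(ncol(X)))
  fit <- ranger::ranger(x = as.data.frame(X), y = as.numeric(y),
                        num.trees = num_trees, max.depth = max_depth,
                        mtry = max(1L, ceiling(max_features * ncol(X))),
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, p = ncol(X)), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, X_new, ...) {
  X_new <- unclass(as.matrix(X_new))
  if (ncol(X_new) != object$p)
    stop(sprintf("marker count mismatch: forest trained on %d, got %d",
                 object$p, ncol(X_new)))
  colnames(X_new) <- paste0("m", seq_len(ncol(X_new)))
  as.numeric(predict(object$fit, data = as.data.frame(X_new),
                     num.threads = 1L)$predictions)
}
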