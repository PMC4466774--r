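#' @title Kernel models: RKHS regression and RankSVM
#' @name kernel_models
#' @description Dual (kernelized) models over marker genotypes. Kernel ridge
#'   regression (RKHS regression; equivalent to ridge/GBLUP with a linear
#'   kernel) solves `(K + lambda I) alpha = y` in closed form. Kernel RankSVM
#'   minimizes a pairwise squared-hinge objective over strict preference
#'   pairs, so the fitted scores only need to order individuals correctly,
#'   not approximate their trait values. Both predict through
#'   `h(x) = sum_i alpha_i kappa(x, x_i)`, an n-dimensional problem that side
#'   steps the n << p marker regime.
NULL

#' RBF kernel width from sigma
#'
#' The RBF bandwidth is parameterized as `gamma = 1 / (4 * p * sigma^2)`,
#' which makes a unit grid over `sigma` span useful widths regardless of the
#' marker count p.
#'
#' @param sigma positive scale parameter.
#' @param p number of markers.
#' @export
gamma_from_sigma <- function(sigma, p) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (p < 1) stop("p must be >= 1")
  1 / (4 * p * sigma^2)
}

#' Kernel specification
#'
#' @param kind `"linear"` (`K = A B'`) or `"rbf"`
#'   (`K_ij = exp(-gamma * ||a_i - b_j||^2)`).
#' @param sigma RBF scale; `gamma` is derived via [gamma_from_sigma()] using
#'   the marker count at kernel-computation time.
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(sigma)) sigma <- 0.5
    if (sigma <= 0) stop("sigma must be > 0")
  } else {
    sigma <- NULL
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' Kernel matrix between two genotype matrices
#'
#' @param A,B numeric matrices with the same number of columns (markers);
#'   rows are individuals. `B` defaults to `A` (training kernel).
#' @param spec a [kernel_spec()].
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
compute_kernel <- function(A, B = A, spec = kernel_spec("linear")) {
  A <- unclass(as.matrix(A)); B <- unclass(as.matrix(B))
  if (ncol(A) != ncol(B))
    stop(sprintf("marker count mismatch: %d vs %d", ncol(A), ncol(B)))
  if (spec$kind == "linear") return(A %*% t(B))
  gamma <- gamma_from_sigma(spec$sigma, ncol(A))
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clipped at 0 for roundoff
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

.new_dual_model <- function(alpha, X_train, spec, lambda, kind, offset = 0,
                            extra = list()) {
  structure(c(list(alpha = as.numeric(alpha), X_train = unclass(as.matrix(X_train)),
                   spec = spec, lambda = lambda, kind = kind, offset = offset),
              extra),
            class = "dual_kernel_model")
}

#' @export
print.dual_kernel_model <- function(x, ...) {
  cat(sprintf("dual_kernel_model (%s): n=%d training individuals, %s kernel, lambda=%g\n",
              x$kind, length(x$alpha), x$spec$kind, x$lambda))
  invisible(x)
}

#' Kernel ridge (RKHS) regression
#'
#' Solves `(K + lambda I) alpha = y`. With a linear kernel `K = X X'` the
#' fitted function equals primal ridge regression
#' `beta = (X'X + lambda I)^-1 X' y` through the representer identity
#' `beta = X' alpha`.
#'
#' @param K square training kernel matrix (n x n, positive semidefinite).
#' @param y trait values of the n training individuals.
#' @param lambda regularization parameter, `> 0`.
#' @return Numeric `alpha` of length n (class `kernel_ridge_alpha` aside,
#'   plain vector).
#' @export
fit_kernel_ridge <- function(K, y, lambda) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("training kernel must be square")
  y <- as.numeric(y)
  if (length(y) != nrow(K)) stop("length(y) must match nrow(K)")
  if (lambda <= 0) stop("lambda must be > 0")
  as.numeric(solve(K + diag(lambda, nrow(K)), y))
}

#' Train an RKHS regression model end to end
#'
#' Computes the training kernel from genotypes and solves the dual system.
#' As in BLUP, the population mean is fitted as a fixed intercept: the dual
#' system is solved on the centered trait and the mean added back at
#' prediction time. Without this, any constant offset in the trait (for
#' instance the shift that makes it nonnegative) would have to be absorbed
#' by marker effects and would distort the fit.
#'
#' @param X training genotype matrix (n x p).
#' @param y trait values.
#' @inheritParams fit_kernel_ridge
#' @param spec a [kernel_spec()].
#' @param intercept fit the trait mean as a fixed effect (default TRUE).
#' @return A `dual_kernel_model`.
#' @export
fit_rkhs <- function(X, y, lambda = 1, spec = kernel_spec("linear"),
                     intercept = TRUE) {
  y <- as.numeric(y)
  mu <- if (intercept) mean(y) else 0
  K <- compute_kernel(X, X, spec)
  alpha <- fit_kernel_ridge(K, y - mu, lambda)
  .new_dual_model(alpha, X, spec, lambda, "rkhs", offset = mu)
}

#' Predict from a dual kernel model
#'
#' @param object a `dual_kernel_model` from [fit_rkhs()] or [fit_ranksvm()].
#' @param X_new candidate genotype matrix (m x p, same markers as training).
#' @param ... unused.
#' @return Numeric scores `K(X_new, X_train) %*% alpha`.
#' @export
predict.dual_kernel_model <- function(object, X_new, ...) {
  K_cross <- compute_kernel(X_new, object$X_train, object$spec)
  as.numeric(K_cross %*% object$alpha) + object$offset
}

#' Predict from dual coefficients and a cross kernel
#'
#' @param alpha dual coefficients over the n training individuals.
#' @param K_cross m x n kernel matrix between candidates and training
#'   individuals.
#' @export
predict_dual <- function(alpha, K_cross) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != length(alpha))
    stop(sprintf("K_cross has %d columns but alpha has length %d",
                 ncol(K_cross), length(alpha)))
  as.numeric(K_cross %*% alpha)
}

# preference pairs as an index matrix; scores enter only through s_i - s_j
.ranksvm_margins <- function(alpha, K, pairs) {
  s <- as.numeric(K %*% alpha)
  1 - s[pairs[, 1L]] + s[pairs[, 2L]]
}

#' RankSVM squared-hinge objective
#'
#' `f(alpha) = (lambda/2) alpha' K alpha
#'   + sum_{(i,j) in P} max(0, 1 - alpha'K_i + alpha'K_j)^2`,
#' the kernelized pairwise ranking objective with squared hinge loss. It is
#' strictly convex, so the minimizer is unique. At `alpha = 0` every pair
#' contributes exactly 1, so `f(0) = |P|`.
#'
#' @param alpha dual coefficient vector of length n.
#' @param K n x n training kernel.
#' @param pairs integer two-column matrix of strict preference pairs `(i, j)`
#'   with `y_i > y_j` (e.g. `pair_partition(y, y)$preference`).
#' @param lambda regularization parameter (already scaled by `|P|` if the
#'   `lambda = |P| * lambda_tilde` convention is used).
#' @export
ranksvm_objective <- function(alpha, K, pairs, lambda) {
  if (nrow(pairs) == 0L) stop("empty preference set")
  h <- pmax(0, .ranksvm_margins(alpha, K, pairs))
  (lambda / 2) * sum(alpha * (K %*% alpha)) + sum(h^2)
}

#' RankSVM objective gradient
#'
#' `grad f(alpha) = lambda K alpha
#'   + 2 sum_{(i,j) in P} max(0, 1 - alpha'K_i + alpha'K_j) (K_j - K_i)`.
#' The pair sum collapses to `K %*% u` where `u` accumulates the hinge
#' activations on each index, so one evaluation costs `O(n^2 + |P|)`.
#'
#' @inheritParams ranksvm_objective
#' @export
ranksvm_gradient <- function(alpha, K, pairs, lambda) {
  if (nrow(pairs) == 0L) stop("empty preference set")
  n <- nrow(K)
  h <- pmax(0, .ranksvm_margins(alpha, K, pairs))
  active <- h > 0
  u <- numeric(n)
  if (any(active)) {
    i <- pairs[active, 1L]; j <- pairs[active, 2L]; ha <- h[active]
    acc <- rowsum(c(ha, -ha), group = c(j, i))
    u[as.integer(rownames(acc))] <- acc[, 1L]
  }
  as.numeric(lambda * (K %*% alpha) + 2 * (K %*% u))
}

#' Fit kernel RankSVM
#'
#' Minimizes the squared-hinge ranking objective over strict preference
#' pairs of the training trait, with `lambda = |P| * lambda_tilde`, by
#' limited-memory BFGS started at `alpha = 0`. The objective is strictly
#' convex, so the solution is unique and two runs from identical inputs are
#' identical. The solver stops at a projected-gradient tolerance of
#' `1e-5 * n` or after `max_iter` iterations.
#'
#' @param X training genotype matrix (n x p).
#' @param y training trait values; must not be constant (no preference pairs
#'   otherwise).
#' @param lambda_tilde per-pair regularization parameter.
#' @param spec a [kernel_spec()].
#' @param max_iter L-BFGS iteration cap (default 500).
#' @return A `dual_kernel_model` with extra fields `pairs`, `objective` and
#'   `convergence`.
#' @export
fit_ranksvm <- function(X, y, lambda_tilde = 1e-3, spec = kernel_spec("linear"),
                        max_iter = 500L) {
  X <- unclass(as.matrix(X)); y <- as.numeric(y)
  pairs <- pair_partition(y, y)$preference
  if (nrow(pairs) == 0L) stop("constant trait: no preference pairs to rank")
  K <- compute_kernel(X, X, spec)
  lambda <- nrow(pairs) * lambda_tilde
  n <- nrow(K)
  opt <- stats::optim(
    par = numeric(n),
    fn = function(a) ranksvm_objective(a, K, pairs, lambda),
    gr = function(a) ranksvm_gradient(a, K, pairs, lambda),
    method = "L-BFGS-B",
    control = list(maxit = as.integer(max_iter), pgtol = 1e-5 * n,
                   factr = 1e1))
  .new_dual_model(opt$par, X, spec, lambda, "ranksvm",
                  extra = list(lambda_tilde = lambda_tilde, pairs = pairs,
                               objective = opt$value,
                               convergence = opt$convergence))
}
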