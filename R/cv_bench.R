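#' @title Cross-validation benchmarking protocol
#' @name cv_bench
#' @description The evaluation protocol used throughout the package:
#'   randomized 80/20 train/test splits repeated 10 times, with every method
#'   seeing identical splits, and nested 5-fold cross-validation inside each
#'   training split that selects hyper-parameters maximizing the same
#'   measure later used for evaluation. Results aggregate into per-dataset
#'   score tables, a cross-dataset average-rank table of methods, and a
#'   measure-agreement matrix of Spearman correlations.
NULL

#' Cross-validation configuration
#'
#' @param train_fraction fraction of individuals used for model estimation
#'   (default 0.8).
#' @param outer_iterations number of randomized splits (default 10).
#' @param inner_folds folds of the nested tuning CV (default 5).
#' @param tuning_measure measure maximized during tuning (minimized for
#'   `"mse"`); should match the measure of interest at evaluation time.
#' @param seed master seed; the split sequence is a function of
#'   `(n, seed, iteration)` only, so all methods share splits.
#' @export
cv_config <- function(train_fraction = 0.8, outer_iterations = 10L,
                      inner_folds = 5L, tuning_measure = "mean-ndcg@10",
                      seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (outer_iterations < 1L) stop("outer_iterations must be >= 1")
  if (inner_folds < 2L) stop("inner_folds must be >= 2")
  structure(list(train_fraction = train_fraction,
                 outer_iterations = as.integer(outer_iterations),
                 inner_folds = as.integer(inner_folds),
                 tuning_measure = tuning_measure, seed = as.integer(seed)),
            class = "cv_config")
}

#' One randomized train/test split
#'
#' Deterministic in `(n, seed, iteration)`: disjoint, exhaustive, with
#' `round(fraction * n)` training individuals.
#'
#' @param n number of individuals (>= 5).
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @param iteration outer iteration index (>= 1).
#' @return List with sorted integer vectors `train` and `test`.
#' @export
random_split <- function(n, fraction = 0.8, seed = 1L, iteration = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n < 5L) stop("need at least 5 individuals to split")
  n_train <- round(fraction * n)
  train <- .with_seed(.derive_seed(seed, 10L, iteration),
                      sort(sample.int(n, n_train)))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Define a benchmark method
#'
#' A method is a name, a tuning grid (named list of candidate values, empty
#' or singleton lists mean no tuning) and `fit(X, y, params)` /
#' `predict_scores(model, X)` closures.
#'
#' @param name method label.
#' @param fit function `(X, y, params) -> model`.
#' @param predict_scores function `(model, X) -> numeric scores`.
#' @param grid named list of hyper-parameter value vectors.
#' @export
gs_method <- function(name, fit, predict_scores, grid = list()) {
  structure(list(name = name, fit = fit, predict_scores = predict_scores,
                 grid = grid), class = "gs_method")
}

.grid_table <- function(grid) {
  if (length(grid) == 0L) return(data.frame(.dummy = 1))
  expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' RKHS (kernel ridge) regression method
#'
#' Regularization (and RBF scale) selected on the tuning grid; the default
#' lambda grid is 15 log-spaced values between 1e-6 and 1e6 and the default
#' sigma grid is 0.1, 0.2, ..., 1.0.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param lambda_grid candidate regularization values.
#' @param sigma_grid candidate RBF scales (rbf only).
#' @export
gs_method_rkhs <- function(kernel = "linear",
                           lambda_grid = 10^seq(-6, 6, length.out = 15),
                           sigma_grid = seq(0.1, 1, by = 0.1)) {
  grid <- list(lambda = lambda_grid)
  if (kernel == "rbf") grid$sigma <- sigma_grid
  gs_method(
    name = paste0("rkhs-", kernel),
    fit = function(X, y, params) {
      spec <- if (kernel == "rbf") kernel_spec("rbf", sigma = params$sigma)
              else kernel_spec("linear")
      fit_rkhs(X, y, lambda = params$lambda, spec = spec)
    },
    predict_scores = function(model, X) predict(model, X),
    grid = grid)
}

#' Kernel RankSVM method
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param lambda_tilde_grid candidate per-pair regularization values
#'   (default: 15 log-spaced between 1e-6 and 1e6).
#' @param sigma_grid candidate RBF scales (rbf only).
#' @param max_iter L-BFGS iteration cap.
#' @export
gs_method_ranksvm <- function(kernel = "linear",
                              lambda_tilde_grid = 10^seq(-6, 6, length.out = 15),
                              sigma_grid = seq(0.1, 1, by = 0.1),
                              max_iter = 500L) {
  grid <- list(lambda_tilde = lambda_tilde_grid)
  if (kernel == "rbf") grid$sigma <- sigma_grid
  gs_method(
    name = paste0("ranksvm-", kernel),
    fit = function(X, y, params) {
      spec <- if (kernel == "rbf") kernel_spec("rbf", sigma = params$sigma)
              else kernel_spec("linear")
      fit_ranksvm(X, y, lambda_tilde = params$lambda_tilde, spec = spec,
                  max_iter = max_iter)
    },
    predict_scores = function(model, X) predict(model, X),
    grid = grid)
}

#' GBRT method
#'
#' @param n_stages trees in the ensemble (default 300).
#' @param lr_grid learning-rate candidates.
#' @param depth_grid depth candidates.
#' @param max_features per-split marker fraction.
#' @param seed tree seed.
#' @export
gs_method_gbrt <- function(n_stages = 300L,
                           lr_grid = c(0.001, 0.01, 0.1, 1.0),
                           depth_grid = c(3L, 5L, 10L),
                           max_features = 0.6, seed = 1L) {
  gs_method(
    name = "gbrt",
    fit = function(X, y, params)
      fit_gbrt(X, y, n_stages = n_stages, learning_rate = params$lr,
               contract = tree_contract(params$depth, max_features, seed)),
    predict_scores = function(model, X) predict(model, X),
    grid = list(lr = lr_grid, depth = depth_grid))
}

#' LambdaMART method
#'
#' @inheritParams gs_method_gbrt
#' @param k NDCG position optimized.
#' @export
gs_method_lambdamart <- function(k = 10L, n_stages = 300L,
                                 lr_grid = c(0.001, 0.01, 0.1, 1.0),
                                 depth_grid = c(3L, 5L, 10L),
                                 max_features = 0.6, seed = 1L) {
  gs_method(
    name = "lambdamart",
    fit = function(X, y, params)
      fit_lambdamart(X, y, k = k, n_stages = n_stages,
                     learning_rate = params$lr,
                     contract = tree_contract(params$depth, max_features, seed)),
    predict_scores = function(model, X) predict(model, X),
    grid = list(lr = lr_grid, depth = depth_grid))
}

#' Random-forest regression method
#'
#' @inheritParams gs_method_gbrt
#' @param num_trees forest size.
#' @export
gs_method_rf <- function(num_trees = 300L, depth_grid = c(3L, 5L, 10L),
                         max_features = 0.6, seed = 1L) {
  gs_method(
    name = "rf",
    fit = function(X, y, params)
      fit_rf_regressor(X, y, num_trees = num_trees, max_depth = params$depth,
                       max_features = max_features, seed = seed),
    predict_scores = function(model, X) predict(model, X),
    grid = list(depth = depth_grid))
}

#' McRank method
#'
#' @param variant `"ordinal"` or `"multiclass"`.
#' @param bins_grid candidate bin counts (default 3..20).
#' @param num_trees forest size of the probability classifiers.
#' @param max_features per-split marker fraction.
#' @param seed classifier seed.
#' @export
gs_method_mcrank <- function(variant = c("ordinal", "multiclass"),
                             bins_grid = 3:20, num_trees = 300L,
                             max_features = 0.6, seed = 1L) {
  variant <- match.arg(variant)
  fitter <- if (variant == "ordinal") fit_ordinal_mcrank else fit_multiclass_mcrank
  gs_method(
    name = paste0("mcrank-", variant),
    fit = function(X, y, params)
      fitter(X, y, B = params$bins,
             classifier = rf_classifier(num_trees = num_trees,
                                        max_features = max_features,
                                        seed = seed)),
    predict_scores = function(model, X) mcrank_score(model, X),
    grid = list(bins = bins_grid))
}

#' Nested hyper-parameter tuning
#'
#' Evaluates every grid point by k-fold cross-validation on the training
#' split and returns the point with the best mean value of the tuning
#' measure (highest, or lowest for `"mse"`). Ties break toward the earlier
#' grid point; a grid point whose fit fails on any fold scores as worst.
#'
#' @param method a [gs_method()].
#' @param X,y training genotypes and trait.
#' @param folds number of inner folds.
#' @param measure tuning measure name (see [evaluate_measure()]).
#' @param seed seed for the fold assignment.
#' @return List with `params` (named list), `score`, and the full `table`
#'   of grid points and mean scores.
#' @export
inner_tune <- function(method, X, y, folds = 5L, measure = "mean-ndcg@10",
                       seed = 1L) {
  X <- unclass(as.matrix(X)); y <- as.numeric(y)
  tab <- .grid_table(method$grid)
  if (nrow(tab) == 1L)
    return(list(params = as.list(tab[1L, , drop = FALSE]), score = NA_real_,
                table = cbind(tab, mean_score = NA_real_)))
  n <- length(y)
  fold_id <- .with_seed(.derive_seed(seed, 20L),
                        sample(rep(seq_len(folds), length.out = n)))
  maximize <- .measure_maximize(measure)
  mean_scores <- numeric(nrow(tab))
  for (gidx in seq_len(nrow(tab))) {
    params <- as.list(tab[gidx, , drop = FALSE])
    fold_scores <- rep(NA_real_, folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      sc <- tryCatch({
        model <- method$fit(X[tr, , drop = FALSE], y[tr], params)
        s_hat <- method$predict_scores(model, X[!tr, , drop = FALSE])
        evaluate_measure(measure, y[!tr], s_hat)
      }, error = function(e) NA_real_)
      fold_scores[f] <- sc
    }
    if (anyNA(fold_scores)) {
      mean_scores[gidx] <- if (maximize) -Inf else Inf
      message(sprintf("grid point %d of method '%s' failed on a fold; scored as worst",
                      gidx, method$name))
    } else {
      mean_scores[gidx] <- mean(fold_scores)
    }
  }
  best <- if (maximize) which.max(mean_scores) else which.min(mean_scores)
  list(params = as.list(tab[best, , drop = FALSE]),
       score = mean_scores[best],
       table = cbind(tab, mean_score = mean_scores))
}

#' Run the benchmark protocol on one dataset
#'
#' For every outer iteration: draw the shared 80/20 split, tune each method
#' on the training split (nested CV, tuning measure from `cfg`), refit on
#' the whole training split, and score the test predictions with every
#' requested measure. A method failure on a split is recorded as missing
#' and excluded from averages with a warning.
#'
#' @param dataset a `gs_dataset` (see [align()]) or `simulated_dataset`.
#' @param methods list of [gs_method()] objects.
#' @param measures character vector of measure names.
#' @param cfg a [cv_config()].
#' @return A `benchmark_result`: list with `scores` (long data.frame:
#'   method, trait, measure, iteration, score), `averages` (method x
#'   measure means), `chosen` (hyper-parameters per method/trait/iteration)
#'   and `config`.
#' @export
run_benchmark <- function(dataset, methods,
                          measures = c("pearson", "tau", "ndcg@1", "ndcg@5",
                                       "ndcg@10", "mean-ndcg@10"),
                          cfg = cv_config()) {
  if (inherits(dataset, "simulated_dataset")) dataset <- dataset$dataset
  X <- unclass(as.matrix(dataset$markers))
  n <- nrow(X)
  names(methods) <- vapply(methods, `[[`, "", "name")
  rows <- list(); chosen <- list()
  for (it in seq_len(cfg$outer_iterations)) {
    sp <- random_split(n, cfg$train_fraction, cfg$seed, it)
    for (trait_name in names(dataset$traits)) {
      y <- as.numeric(dataset$traits[[trait_name]])
      for (method in methods) {
        res <- tryCatch({
          tune <- inner_tune(method, X[sp$train, , drop = FALSE], y[sp$train],
                             folds = cfg$inner_folds,
                             measure = cfg$tuning_measure,
                             seed = .derive_seed(cfg$seed, 30L, it))
          model <- method$fit(X[sp$train, , drop = FALSE], y[sp$train],
                              tune$params)
          s_hat <- method$predict_scores(model, X[sp$test, , drop = FALSE])
          list(scores = vapply(measures, function(m)
            evaluate_measure(m, y[sp$test], s_hat), numeric(1)),
            params = tune$params)
        }, error = function(e) {
          warning(sprintf("method '%s' failed on iteration %d: %s",
                          method$name, it, conditionMessage(e)))
          NULL
        })
        sc <- if (is.null(res)) rep(NA_real_, length(measures)) else res$scores
        rows[[length(rows) + 1L]] <- data.frame(
          method = method$name, trait = trait_name, measure = measures,
          iteration = it, score = as.numeric(sc))
        if (!is.null(res))
          chosen[[length(chosen) + 1L]] <- data.frame(
            method = method$name, trait = trait_name, iteration = it,
            params = paste(names(res$params),
                           vapply(res$params, format, ""),
                           sep = "=", collapse = ";"))
      }
    }
  }
  scores <- do.call(rbind, rows)
  averages <- stats::aggregate(score ~ method + measure, data = scores,
                               FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  structure(list(scores = scores, averages = averages,
                 chosen = if (length(chosen)) do.call(rbind, chosen) else NULL,
                 config = cfg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over", x$config$outer_iterations, "iterations\n")
  wide <- stats::reshape(x$averages, idvar = "method", timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^score\\.", "", names(wide))
  print(format(wide, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Average-rank table of methods across datasets
#'
#' Within each dataset and measure, methods are ranked by their average
#' score (rank 1 = best; ties get average ranks; for `"mse"` smaller is
#' better). Ranks are averaged across datasets and methods sorted
#' ascending — the cross-dataset league table.
#'
#' @param results list of `benchmark_result`s, one per dataset; every method
#'   must appear in every result.
#' @param measure measure to rank on.
#' @return data.frame with columns `method` and `avg_rank`, sorted.
#' @export
rank_methods <- function(results, measure = "mean-ndcg@10") {
  if (inherits(results, "benchmark_result")) results <- list(results)
  method_sets <- lapply(results, function(r) sort(unique(r$averages$method)))
  if (length(unique(vapply(method_sets, paste, "", collapse = "|"))) != 1L)
    stop("every method must be present in every benchmark result")
  ranks <- vapply(results, function(r) {
    avg <- r$averages[r$averages$measure == measure, ]
    if (nrow(avg) == 0L) stop("measure not present in a benchmark result: ", measure)
    avg <- avg[order(avg$method), ]
    v <- avg$score
    if (.measure_maximize(measure)) rank(-v) else rank(v)
  }, numeric(length(method_sets[[1L]])))
  out <- data.frame(method = method_sets[[1L]],
                    avg_rank = rowMeans(as.matrix(ranks)))
  out[order(out$avg_rank, out$method), , drop = FALSE]
}

#' Measure-agreement matrix
#'
#' For each pair of measures, the Spearman correlation between the two
#' per-method average-score vectors, computed within each dataset and
#' averaged across datasets. Requires at least 3 methods (rank correlation
#' over fewer methods is degenerate). The diagonal is 1 by convention.
#'
#' @param results list of `benchmark_result`s.
#' @param measures measures to compare (default: all shared measures).
#' @return Symmetric numeric matrix of averaged Spearman correlations.
#' @export
measure_agreement <- function(results, measures = NULL) {
  if (inherits(results, "benchmark_result")) results <- list(results)
  if (is.null(measures)) measures <- unique(results[[1L]]$averages$measure)
  n_methods <- length(unique(results[[1L]]$averages$method))
  if (n_methods < 3L) stop("measure agreement needs at least 3 methods")
  M <- length(measures)
  out <- matrix(1, M, M, dimnames = list(measures, measures))
  for (a in seq_len(M - 1L)) for (b in seq((a + 1L), M)) {
    rhos <- vapply(results, function(r) {
      avg <- r$averages
      va <- avg$score[avg$measure == measures[a]][order(avg$method[avg$measure == measures[a]])]
      vb <- avg$score[avg$measure == measures[b]][order(avg$method[avg$measure == measures[b]])]
      # orient mse so that larger = better before comparing rankings
      if (!.measure_maximize(measures[a])) va <- -va
      if (!.measure_maximize(measures[b])) vb <- -vb
      spearman_rho(va, vb)
    }, numeric(1))
    out[a, b] <- out[b, a] <- mean(rhos)
  }
  out
}
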