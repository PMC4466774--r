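test_that("random splits are disjoint, exhaustive and seed-deterministic", {
  sp <- random_split(10, 0.8, seed = 3, iteration = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)

  expect_identical(random_split(50, 0.8, 7, 4), random_split(50, 0.8, 7, 4))
  expect_false(identical(random_split(50, 0.8, 7, 4),
                         random_split(50, 0.8, 7, 5)))
  expect_error(random_split(50, 1.2, 1), "fraction")
  expect_error(random_split(3, 0.8, 1), "at least 5")
})

test_that("inner_tune returns singleton grids untouched and breaks ties first", {
  d <- toy_marker_data(n = 30, p = 5)
  m <- gs_method_rkhs(lambda_grid = 0.5)
  tuned <- inner_tune(m, d$X, d$y, folds = 3, measure = "pearson")
  expect_equal(tuned$params$lambda, 0.5)

  # two grid points that fit identical models -> earlier point wins
  tie_method <- gs_method(
    "tie", grid = list(a = c(1, 2)),
    fit = function(X, y, params) mean(y),
    predict_scores = function(model, X) rep(model, nrow(X)) + seq_len(nrow(X)))
  tuned2 <- inner_tune(tie_method, d$X, d$y, folds = 3, measure = "pa",
                       seed = 5)
  expect_equal(tuned2$params$a, 1)
  expect_equal(tuned2$table$mean_score[1], tuned2$table$mean_score[2])
})

test_that("inner_tune selects the dominant grid point when the truth is in it", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(200 + seed)
    n <- 60; p <- 10
    X <- matrix(rbinom(n * p, 2, 0.4), n, p)
    y <- as.numeric(X %*% rnorm(p)) + rnorm(n, sd = 0.05)
    m <- gs_method_rkhs(lambda_grid = c(1e-2, 1e6))  # tiny vs absurd shrinkage
    tuned <- inner_tune(m, X, y, folds = 5, measure = "pearson", seed = seed)
    if (tuned$params$lambda == 1e-2) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("failing grid points are scored as worst, not fatal", {
  d <- toy_marker_data(n = 30, p = 5)
  flaky <- gs_method(
    "flaky", grid = list(a = c(1, 2)),
    fit = function(X, y, params) {
      if (params$a == 2) stop("boom")
      mean(y)
    },
    predict_scores = function(model, X) rep(model, nrow(X)) + seq_len(nrow(X)))
  expect_message(tuned <- inner_tune(flaky, d$X, d$y, folds = 3, measure = "pa"),
                 "failed on a fold")
  expect_equal(tuned$params$a, 1)
})

test_that("run_benchmark stores per-iteration scores and their means", {
  d <- toy_marker_data(n = 40, p = 6)
  ds <- align(marker_matrix(d$X, sprintf("s%02d", 1:40), sprintf("m%d", 1:6)),
              trait_vector(stats::setNames(d$y - min(d$y), sprintf("s%02d", 1:40)),
                           "yield"))
  cfg <- cv_config(outer_iterations = 2, inner_folds = 3,
                   tuning_measure = "pearson", seed = 11)
  res <- run_benchmark(ds, list(gs_method_rkhs(lambda_grid = 1)),
                       measures = c("pearson", "ndcg@5"), cfg = cfg)
  expect_equal(nrow(res$scores), 2 * 2)   # 2 iterations x 2 measures
  for (msr in c("pearson", "ndcg@5")) {
    stored <- res$scores$score[res$scores$measure == msr]
    expect_length(stored, 2)
    expect_equal(res$averages$score[res$averages$measure == msr], mean(stored))
  }
  # full-protocol determinism
  res2 <- run_benchmark(ds, list(gs_method_rkhs(lambda_grid = 1)),
                        measures = c("pearson", "ndcg@5"), cfg = cfg)
  expect_identical(res$scores, res2$scores)
})

test_that("oracle and antioracle bracket a real method on rank measures", {
  set.seed(131)
  sim <- simulate_dataset(sim_config(n = 60, p = 15, n_qtl = 5,
                                     heritability = 0.8, seed = 17))
  X <- sim$dataset$markers
  y <- as.numeric(sim$dataset$traits[[1]])
  methods <- list(oracle_method(X, y, 1),
                  gs_method_rkhs(lambda_grid = 1),
                  oracle_method(X, y, -1))
  cfg <- cv_config(outer_iterations = 3, inner_folds = 3,
                   tuning_measure = "tau", seed = 23)
  res <- run_benchmark(sim, methods, measures = c("tau", "pa", "ndcg@5"),
                       cfg = cfg)
  sc <- res$scores
  for (msr in c("tau", "pa", "ndcg@5")) for (it in 1:3) {
    v <- function(m) sc$score[sc$method == m & sc$measure == msr &
                              sc$iteration == it]
    expect_gte(v("oracle"), v("rkhs-linear"))
    expect_gte(v("rkhs-linear"), v("antioracle"))
  }
  # oracle is perfect, antioracle pessimal, on every split
  expect_equal(sc$score[sc$method == "oracle" & sc$measure == "tau"], rep(1, 3))
  expect_equal(sc$score[sc$method == "oracle" & sc$measure == "ndcg@5"], rep(1, 3))
  expect_equal(sc$score[sc$method == "antioracle" & sc$measure == "pa"], rep(0, 3))
})

test_that("a failing method is recorded as missing with a warning", {
  d <- toy_marker_data(n = 30, p = 5)
  ds <- align(marker_matrix(d$X, sprintf("s%02d", 1:30), sprintf("m%d", 1:5)),
              trait_vector(stats::setNames(d$y - min(d$y), sprintf("s%02d", 1:30)),
                           "t"))
  dead <- gs_method("dead", fit = function(X, y, params) stop("nope"),
                    predict_scores = function(model, X) NULL)
  cfg <- cv_config(outer_iterations = 2, inner_folds = 2,
                   tuning_measure = "pa", seed = 2)
  warns <- capture_warnings(
    res <- run_benchmark(ds, list(dead), measures = "pa", cfg = cfg))
  expect_length(warns, 2)                  # one warning per failed iteration
  expect_match(warns, "failed on iteration", all = TRUE)
  expect_true(all(is.na(res$scores$score)))
})

test_that("rank_methods averages within-dataset ranks with tie handling", {
  mk_res <- function(scores) {
    structure(list(averages = data.frame(
      method = names(scores), measure = "tau", score = as.numeric(scores)),
      config = cv_config()), class = "benchmark_result")
  }
  r1 <- mk_res(c(a = 0.9, b = 0.5, c = 0.1))
  r2 <- mk_res(c(a = 0.2, b = 0.8, c = 0.2))
  tab <- rank_methods(list(r1, r2), measure = "tau")
  # dataset 1 ranks: a=1 b=2 c=3; dataset 2: b=1, a=c tied at 2.5
  expect_equal(tab$avg_rank[tab$method == "a"], mean(c(1, 2.5)))
  expect_equal(tab$avg_rank[tab$method == "b"], mean(c(2, 1)))
  expect_equal(tab$avg_rank[tab$method == "c"], mean(c(3, 2.5)))
  expect_equal(tab$method[1], "b")      # sorted ascending by average rank
  # single dataset: ranking equals the within-dataset ordering
  expect_equal(rank_methods(list(r1), "tau")$method, c("a", "b", "c"))
  r3 <- mk_res(c(a = 1, b = 0.5, d = 0.2))
  expect_error(rank_methods(list(r1, r3), "tau"), "every method")
})

test_that("measure agreement is the averaged Spearman of method scores", {
  mk_res <- function(t1, t2) {
    structure(list(averages = rbind(
      data.frame(method = names(t1), measure = "m1", score = as.numeric(t1)),
      data.frame(method = names(t2), measure = "m2", score = as.numeric(t2))),
      config = cv_config()), class = "benchmark_result")
  }
  # m2 is a monotone transform of m1 -> perfect agreement
  r <- mk_res(c(a = 0.1, b = 0.5, c = 0.9), c(a = 1, b = 25, c = 81))
  M <- measure_agreement(list(r), c("m1", "m2"))
  expect_equal(M["m1", "m2"], 1)
  expect_equal(diag(M), c(m1 = 1, m2 = 1))
  expect_true(isSymmetric(M))
  # hand-set three-method scores: rho computed by ranking then Pearson
  r2 <- mk_res(c(a = 3, b = 1, c = 2), c(a = 10, b = 30, c = 20))
  expect_equal(measure_agreement(list(r2), c("m1", "m2"))["m1", "m2"],
               cor(rank(c(3, 1, 2)), rank(c(10, 30, 20))))
  # averaged across datasets
  expect_equal(measure_agreement(list(r, r2), c("m1", "m2"))["m1", "m2"],
               mean(c(1, -1)))
  two <- structure(list(averages = data.frame(
    method = c("a", "b"), measure = "m1", score = c(1, 2)),
    config = cv_config()), class = "benchmark_result")
  expect_error(measure_agreement(list(two), "m1"), "at least 3 methods")
})
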