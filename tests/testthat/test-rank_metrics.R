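test_that("mse and pearson behave per definition", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  y <- c(3.5, 2.8, 1.2); s <- c(10.3, 3.7, 0.1)
  expect_equal(mse(y, s), mean((y - s)^2))   # direct arithmetic
  expect_equal(pearson(y, 2 * y + 5), 1)
  expect_equal(pearson(y, -y), -1)
  expect_error(pearson(c(1, 1, 1), y), "constant")
  expect_error(mse(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("a perfectly ranked but non-collinear prediction has r < 1, tau = 1", {
  y <- c(3.5, 2.8, 1.2); s <- c(10.3, 3.7, 0.1)
  expect_equal(round(pearson(y, s), 2), 0.92)
  expect_equal(kendall_tau(y, s), 1)
  expect_equal(pairwise_accuracy(y, s), 1)
})

test_that("pair partition matches exhaustive enumeration", {
  pp <- pair_partition(c(2, 1), c(5, 3))
  expect_equal(c(pp$n_pref, pp$n_conc, pp$n_disc, pp$n_tied), c(1, 1, 0, 0))
  pp <- pair_partition(c(2, 1), c(3, 3))
  expect_equal(pp$n_tied, 1)

  y <- c(1, 2, 3, 4); s <- c(2, 1, 4, 3)
  pp <- pair_partition(y, s)
  expect_equal(c(pp$n_pref, pp$n_conc, pp$n_disc), c(6, 4, 2))
  expect_equal(pairwise_accuracy(y, s), 4 / 6)
  expect_equal(kendall_tau(y, s), (4 - 2) / 6)

  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    y <- rnorm(n); s <- sample(c(rnorm(n - 2), s1 <- rnorm(1), s1))
    pp <- pair_partition(y, s)
    ref <- naive_pair_counts(y, s)
    expect_equal(c(pp$n_pref, pp$n_conc, pp$n_disc, pp$n_tied),
                 c(ref$P, ref$C, ref$D, ref$T))
    # partition is exhaustive and disjoint
    expect_equal(pp$n_conc + pp$n_disc + pp$n_tied, pp$n_pref)
  }
  expect_error(pairwise_accuracy(c(1, 1), c(1, 2)), "constant reference")
})

test_that("tau equals 2*pa - 1 on tie-free scores, and agrees with cor()", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    y <- random_tie_free(n); s <- random_tie_free(n)
    pa <- pairwise_accuracy(y, s)
    tau <- kendall_tau(y, s)
    # the identity is exact on the integer pair counts ...
    pp <- pair_partition(y, s)
    expect_identical(pp$n_conc - pp$n_disc, 2L * pp$n_conc - pp$n_pref)
    # ... and holds to machine precision after the division
    expect_equal(tau, 2 * pa - 1, tolerance = 1e-14)
    # tie-free tau-a coincides with the standard statistic
    expect_equal(tau, cor(y, s, method = "kendall"))
  }
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(kendall_tau(c(3.5, 2.8, 1.2), c(10.3, 3.7, 0.1)), 1)
})

test_that("pairwise accuracy on a binary reference equals the ROC AUC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (rep in 1:10) {
    n <- 40
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- rnorm(n) + y
    auc <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(pairwise_accuracy(y, s), auc, tolerance = 1e-12)
  }
})

test_that("induced permutation sorts decreasingly with stable tie-break", {
  expect_equal(induced_permutation(c(1, 3, 2)), c(2, 3, 1))
  expect_equal(induced_permutation(c(7, 7, 1)), c(1, 2, 3))
  expect_equal(induced_permutation(5), 1L)
  set.seed(3)
  s <- rnorm(25)
  p <- induced_permutation(s)
  expect_true(all(diff(s[p]) <= 0))
  expect_setequal(p, seq_along(s))
})

test_that("DCG matches hand arithmetic and honors gain/discount options", {
  y <- c(3, 2, 1)
  expect_equal(dcg_at_k(y, 1:3, 3), 3 + 2 / log2(3) + 1 / 2)
  expect_equal(dcg_at_k(y, 1:3, 1), 3)                         # d(1) = 1
  expect_equal(dcg_at_k(c(0, 0, 0), 1:3, 3), 0)
  expect_equal(dcg_at_k(y, 1:3, 3, gain_discount_spec("exponential", "none")),
               (2^3 - 1) + (2^2 - 1) + (2^1 - 1))
  set.seed(9)
  for (rep in 1:10) {
    yy <- runif(6); perm <- sample(6); k <- sample(6, 1)
    expect_equal(dcg_at_k(yy, perm, k), naive_dcg(yy, perm, k))
    expect_equal(dcg_at_k(yy, perm, k, gain_discount_spec("exponential", "log2")),
                 naive_dcg(yy, perm, k, gain = "exponential"))
  }
  expect_error(dcg_at_k(y, 1:3, 4), "outside")
})

test_that("NDCG matches hand arithmetic, is bounded, and flags misuse", {
  y <- c(3, 2, 1)
  expect_equal(ndcg_at_k(y, y, 3), 1)
  expect_equal(ndcg_at_k(y, c(1, 3, 2), 3), 4.13093 / 4.76186, tolerance = 1e-5)
  # equal-gain swap at the top leaves NDCG at 1
  expect_equal(ndcg_at_k(c(3, 3, 1), c(1, 2, 0), 3), 1)
  expect_error(ndcg_at_k(c(-1, 2, 3), c(1, 2, 3), 2), "shift_nonnegative")
  expect_warning(z <- ndcg_at_k(c(0, 0, 0), c(1, 2, 3), 2), "ideal DCG is zero")
  expect_equal(z, 0)
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(3:15, 1)
    yy <- runif(n); ss <- rnorm(n); k <- sample(n, 1)
    v <- ndcg_at_k(yy, ss, k)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("Mean NDCG averages the per-position values", {
  y <- c(3, 2, 1); s <- c(1, 3, 2)
  expect_equal(mean_ndcg_at_k(y, s, 1), ndcg_at_k(y, s, 1))
  expect_equal(mean_ndcg_at_k(y, y, 3), 1)
  expect_equal(mean_ndcg_at_k(y, s, 3),
               mean(c(ndcg_at_k(y, s, 1), ndcg_at_k(y, s, 2),
                      ndcg_at_k(y, s, 3))))
})

test_that("rank measures are invariant to strictly monotone score transforms", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    y <- runif(n); s <- rnorm(n)
    s2 <- exp(2 * s) + 3          # strictly increasing transform
    expect_equal(pairwise_accuracy(y, s), pairwise_accuracy(y, s2))
    expect_equal(kendall_tau(y, s), kendall_tau(y, s2))
    k <- sample(n, 1)
    expect_equal(ndcg_at_k(y, s, k), ndcg_at_k(y, s2, k))
    expect_equal(mean_ndcg_at_k(y, s, k), mean_ndcg_at_k(y, s2, k))
  }
})

test_that("spearman_rho rank-transforms then correlates, with average ranks", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # ties get average ranks (matches the standard statistic)
  a <- c(1, 2, 2, 3); b <- c(4, 6, 5, 9)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  expect_error(spearman_rho(c(1, 1), c(1, 2)), "constant")
})

test_that("evaluate_scores dispatches measure names", {
  y <- c(3, 2, 1, 0.5); s <- c(2.9, 2.2, 0.8, 0.1)
  out <- evaluate_scores(y, s, c("mse", "pearson", "tau", "pa", "ndcg@2",
                                 "mean-ndcg@3"))
  expect_named(out, c("mse", "pearson", "tau", "pa", "ndcg@2", "mean-ndcg@3"))
  expect_equal(out[["mse"]], mse(y, s))
  expect_equal(out[["ndcg@2"]], ndcg_at_k(y, s, 2))
  expect_error(evaluate_measure("bogus", y, s), "unknown measure")
})
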