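#' @title Ranking evaluation measures
#' @name rank_metrics
#' @description Evaluation measures for genomic selection viewed as a ranking
#'   problem. Besides the traditional mean squared error and Pearson
#'   correlation, these cover global ranking quality through strict
#'   preference pairs (pairwise accuracy, Kendall's tau) and top-k ranking
#'   quality through discounted cumulative gain (DCG), its normalized form
#'   (NDCG) and Mean NDCG. Pair-based and NDCG measures depend on predicted
#'   scores only through the ordering they induce, so any strictly increasing
#'   transform of the scores leaves them unchanged.
NULL

.check_lengths <- function(y, s) {
  if (length(y) != length(s))
    stop(sprintf("length mismatch: reference has %d values, scores have %d",
                 length(y), length(s)))
}

#' Mean squared error
#'
#' @param y reference trait values.
#' @param s predicted values.
#' @return `mean((y - s)^2)`.
#' @export
mse <- function(y, s) {
  y <- as.numeric(y); s <- as.numeric(s)
  .check_lengths(y, s)
  if (length(y) < 1L) stop("need at least one observation")
  mean((y - s)^2)
}

#' Pearson correlation
#'
#' Product-moment correlation between reference trait values and predictions.
#' Equals 1 exactly when predictions are a positive affine transform of the
#' truth; a constant input is an error (the formula divides by a zero
#' standard deviation, and silently returning 0 would corrupt model
#' selection).
#'
#' @inheritParams mse
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(y, s) {
  y <- as.numeric(y); s <- as.numeric(s)
  .check_lengths(y, s)
  if (length(y) < 2L) stop("need at least two observations")
  if (stats::sd(y) == 0 || stats::sd(s) == 0)
    stop("Pearson correlation undefined for a constant vector")
  stats::cor(y, s)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank-transformed vectors, with average ranks on
#' ties. Used to quantify agreement between evaluation measures across
#' methods.
#'
#' @param a,b numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  .check_lengths(a, b)
  if (length(a) < 2L) stop("need at least two observations")
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(ra, rb)
}

#' Strict preference pairs and their partition
#'
#' The preference set `P(y)` contains every ordered pair `(i, j)` with
#' `y_i > y_j` (individual i strictly preferred to j). Against predicted
#' scores `s`, each preference pair is concordant (`s_i > s_j`), discordant
#' (`s_i < s_j`) or tied (`s_i == s_j`).
#'
#' @inheritParams mse
#' @return A `pair_partition`: list with integer two-column matrices
#'   `preference`, `concordant`, `discordant`, `tied` and their counts
#'   `n_pref`, `n_conc`, `n_disc`, `n_tied`.
#' @export
pair_partition <- function(y, s) {
  y <- as.numeric(y); s <- as.numeric(s)
  .check_lengths(y, s)
  n <- length(y)
  ij <- which(outer(y, y, ">"), arr.ind = TRUE)
  colnames(ij) <- c("i", "j")
  si <- s[ij[, 1L]]; sj <- s[ij[, 2L]]
  conc <- si > sj
  disc <- si < sj
  tied <- si == sj
  structure(list(
    preference = ij,
    concordant = ij[conc, , drop = FALSE],
    discordant = ij[disc, , drop = FALSE],
    tied       = ij[tied, , drop = FALSE],
    n_pref = nrow(ij), n_conc = sum(conc),
    n_disc = sum(disc), n_tied = sum(tied)
  ), class = "pair_partition")
}

#' @export
print.pair_partition <- function(x, ...) {
  cat(sprintf("pair_partition: |P|=%d, concordant=%d, discordant=%d, tied=%d\n",
              x$n_pref, x$n_conc, x$n_disc, x$n_tied))
  invisible(x)
}

.pair_counts <- function(y, s) {
  pp <- pair_partition(y, s)
  if (pp$n_pref == 0L)
    stop("constant reference: no preference pairs, measure undefined")
  pp
}

#' Pairwise accuracy
#'
#' Proportion of strict preference pairs ordered correctly by the scores,
#' `|C| / |P(y)|` in `[0, 1]`. On a binary reference it equals the area under
#' the ROC curve.
#'
#' @inheritParams mse
#' @export
pairwise_accuracy <- function(y, s) {
  pp <- .pair_counts(y, s)
  pp$n_conc / pp$n_pref
}

#' Kendall's tau over strict preference pairs
#'
#' `(|C| - |D|) / |P(y)|` in `[-1, 1]`: the proportion of concordant minus
#' the proportion of discordant preference pairs. With no score ties this
#' equals `2 * pairwise_accuracy - 1`. The denominator is the number of
#' strict preference pairs of the reference, so ties in the reference are
#' excluded entirely; this is the tau-a convention on a tie-free reference
#' and deliberately not the tau-b tie correction used by
#' `cor(..., method = "kendall")` when ties are present.
#'
#' @inheritParams mse
#' @export
kendall_tau <- function(y, s) {
  pp <- .pair_counts(y, s)
  (pp$n_conc - pp$n_disc) / pp$n_pref
}

#' Permutation induced by scores
#'
#' Indices sorted by decreasing score; ties broken by ascending original
#' index, so the result is deterministic.
#'
#' @param s numeric score vector.
#' @return Integer permutation `pi` with `s[pi]` non-increasing.
#' @export
induced_permutation <- function(s) {
  s <- as.numeric(s)
  if (length(s) < 1L) stop("empty score vector")
  order(-s, seq_along(s))
}

#' Gain/discount specification for DCG
#'
#' @param gain `"linear"` (`g(y) = y`) or `"exponential"` (`g(y) = 2^y - 1`).
#'   Linear gain is the sensible default for traits, whose values are not
#'   bounded relevance grades.
#' @param discount `"log2"` (`d(i) = 1/log2(i + 1)`) or `"none"` (`d(i) = 1`).
#' @return A `gain_discount_spec` list with a `gain_fun` and `discount_fun`.
#' @export
gain_discount_spec <- function(gain = c("linear", "exponential"),
                               discount = c("log2", "none")) {
  gain <- match.arg(gain)
  discount <- match.arg(discount)
  structure(list(
    gain = gain, discount = discount,
    gain_fun = if (gain == "linear") function(y) y else function(y) 2^y - 1,
    discount_fun = if (discount == "log2") function(i) 1 / log2(i + 1)
                   else function(i) rep(1, length(i))
  ), class = "gain_discount_spec")
}

#' Discounted cumulative gain at position k
#'
#' `sum_{i=1..k} g(y[pi_i]) * d(i)` for a ranking `pi`: the gain of the item
#' placed at rank i, discounted by its rank.
#'
#' @param y reference trait values (gains are computed from these).
#' @param perm integer permutation of `seq_along(y)` (ranks to items), e.g.
#'   from [induced_permutation()].
#' @param k position cutoff, `1 <= k <= length(y)`.
#' @param spec a [gain_discount_spec()].
#' @export
dcg_at_k <- function(y, perm, k, spec = gain_discount_spec()) {
  y <- as.numeric(y)
  n <- length(y)
  if (k < 1L || k > n) stop(sprintf("k = %d outside 1..n = %d", k, n))
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    stop("perm must be a permutation of 1..n")
  i <- seq_len(k)
  sum(spec$gain_fun(y[perm[i]]) * spec$discount_fun(i))
}

#' Normalized DCG at position k
#'
#' Ratio of the DCG of the score-induced ranking to the DCG of the ideal
#' ranking (the reference sorted decreasingly); in `[0, 1]` for nonnegative
#' references, 1 whenever the top k is ordered gain-optimally. Negative
#' reference values are an error: apply [shift_nonnegative()] first. When the
#' ideal DCG is zero (all gains in the top k are zero) the reference carries
#' no preference signal and the measure is defined as 0 with a warning.
#'
#' @inheritParams mse
#' @inheritParams dcg_at_k
#' @export
ndcg_at_k <- function(y, s, k, spec = gain_discount_spec()) {
  y <- as.numeric(y); s <- as.numeric(s)
  .check_lengths(y, s)
  if (min(y) < 0)
    stop("NDCG requires nonnegative reference values; apply shift_nonnegative() first")
  ideal <- dcg_at_k(y, induced_permutation(y), k, spec)
  if (ideal == 0) {
    warning("ideal DCG is zero (all top-k gains zero); returning NDCG = 0")
    return(0)
  }
  dcg_at_k(y, induced_permutation(s), k, spec) / ideal
}

#' Mean NDCG over positions 1..K
#'
#' `mean(NDCG@k, k = 1..K)`; rewards models that rank well at every cutoff up
#' to K rather than at a single one.
#'
#' @inheritParams ndcg_at_k
#' @param K largest position, `1 <= K <= length(y)`.
#' @export
mean_ndcg_at_k <- function(y, s, K, spec = gain_discount_spec()) {
  if (K < 1L || K > length(y))
    stop(sprintf("K = %d outside 1..n = %d", K, length(y)))
  mean(vapply(seq_len(K), function(k) ndcg_at_k(y, s, k, spec), numeric(1)))
}

#' Evaluate a set of measures
#'
#' Computes named evaluation measures of predicted scores against a
#' reference. Measure names: `"mse"`, `"pearson"`, `"tau"`, `"pa"`
#' (pairwise accuracy), `"ndcg@k"` and `"mean-ndcg@K"` for integer k/K.
#'
#' @inheritParams mse
#' @param measures character vector of measure names.
#' @param spec gain/discount specification for the NDCG family.
#' @return Named numeric vector, one entry per measure.
#' @export
evaluate_scores <- function(y, s,
                            measures = c("mse", "pearson", "tau", "pa",
                                         "ndcg@1", "ndcg@5", "ndcg@10",
                                         "mean-ndcg@10"),
                            spec = gain_discount_spec()) {
  vapply(measures, function(m) evaluate_measure(m, y, s, spec), numeric(1))
}

#' Evaluate one named measure
#'
#' @param name measure name, see [evaluate_scores()].
#' @inheritParams evaluate_scores
#' @export
evaluate_measure <- function(name, y, s, spec = gain_discount_spec()) {
  if (name == "mse") return(mse(y, s))
  if (name == "pearson") return(pearson(y, s))
  if (name == "tau") return(kendall_tau(y, s))
  if (name == "pa") return(pairwise_accuracy(y, s))
  if (grepl("^ndcg@[0-9]+$", name))
    return(ndcg_at_k(y, s, as.integer(sub("^ndcg@", "", name)), spec))
  if (grepl("^mean-ndcg@[0-9]+$", name))
    return(mean_ndcg_at_k(y, s, as.integer(sub("^mean-ndcg@", "", name)), spec))
  stop("unknown measure: ", name)
}

# TRUE for measures where larger is better (everything except mse)
.measure_maximize <- function(name) name != "mse"
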