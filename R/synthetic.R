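#' @title Synthetic genotype/phenotype simulation
#' @name synthetic
#' @description Generates biallelic marker data and quantitative traits with
#'   the statistical structure genomic-selection methods assume: markers in
#'   Hardy-Weinberg proportions at chosen allele frequencies (no linkage
#'   disequilibrium by default), a sparse set of causal loci (QTL) with
#'   normal additive effects (optionally plus pairwise epistatic products),
#'   and environmental noise calibrated so the genetic fraction of the
#'   phenotypic variance equals a stated heritability h2. Since the genetic
#'   variance explained equals h2 by construction, the correlation between
#'   the true genetic values and the simulated trait concentrates around
#'   sqrt(h2), the ceiling any predictor can attain.
NULL

# independent deterministic sub-streams below 2^31
.derive_seed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) %% 65011 * 31013 + a * 104729 + b * 7919) %%
               2147483647)
}

#' Simulation configuration
#'
#' Defaults emulate a typical reference-population design in the n << p
#' marker regime: a few hundred individuals, a few thousand markers, a few
#' dozen QTL, moderate heritability.
#'
#' @param n number of individuals.
#' @param p number of markers.
#' @param maf_range interval in (0, 0.5] from which per-marker minor allele
#'   frequencies are drawn uniformly.
#' @param n_qtl number of causal markers (<= p).
#' @param heritability h2 in [0, 1]: genetic fraction of trait variance.
#' @param architecture `"additive"` or `"additive-plus-epistatic"` (adds
#'   pairwise products of consecutive QTL genotypes).
#' @param seed integer master seed; genotypes, effects and noise use
#'   independent derived streams.
#' @export
sim_config <- function(n = 400L, p = 2000L, maf_range = c(0.05, 0.5),
                       n_qtl = 20L, heritability = 0.6,
                       architecture = c("additive", "additive-plus-epistatic"),
                       seed = 1L) {
  architecture <- match.arg(architecture)
  if (n_qtl > p) stop("n_qtl must be <= p")
  if (heritability < 0 || heritability > 1) stop("heritability must be in [0, 1]")
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L])
    stop("maf_range must lie within (0, 0.5]")
  structure(list(n = as.integer(n), p = as.integer(p), maf_range = maf_range,
                 n_qtl = as.integer(n_qtl), heritability = heritability,
                 architecture = architecture, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic genotypes
#'
#' Marker j gets an allele frequency drawn uniformly from `maf_range`;
#' genotypes are allele counts in `{0, 1, 2}` from two independent allele
#' draws (Hardy-Weinberg proportions), so at frequency 0.5 the genotype
#' classes appear in roughly 1:2:1 ratio.
#'
#' @param cfg a [sim_config()].
#' @return A [marker_matrix()] with encoding `"codominant-012"`.
#' @export
simulate_genotypes <- function(cfg) {
  .with_seed(.derive_seed(cfg$seed, 1L), {
    freqs <- stats::runif(cfg$p, cfg$maf_range[1L], cfg$maf_range[2L])
    geno <- vapply(freqs, function(f) stats::rbinom(cfg$n, 2L, f),
                   numeric(cfg$n))
    marker_matrix(geno,
                  sample_ids = sprintf("ind%03d", seq_len(cfg$n)),
                  marker_ids = sprintf("m%04d", seq_len(cfg$p)),
                  encoding = "codominant-012")
  })
}

#' Simulate a quantitative trait on given genotypes
#'
#' Chooses `n_qtl` causal markers without replacement, draws their additive
#' effects from a standard normal, forms genetic values
#' `g = X[, qtl] %*% effects` (plus products of consecutive QTL genotypes
#' under the epistatic architecture), and adds normal noise with variance
#' `var(g) * (1 - h2) / h2` (zero when `h2 = 1`). The trait is shifted so
#' its minimum is zero, making it directly usable with NDCG.
#'
#' @param X a [marker_matrix()] (typically from [simulate_genotypes()]).
#' @param cfg the same [sim_config()].
#' @return A `simulated_dataset`: list with `dataset` (a `gs_dataset`),
#'   `genetic_values` (shifted by the same constant as the trait),
#'   `qtl_indices`, `effects` and `heritability`.
#' @export
simulate_trait <- function(X, cfg) {
  Xm <- unclass(as.matrix(X))
  g <- .with_seed(.derive_seed(cfg$seed, 2L), {
    qtl <- sample.int(ncol(Xm), cfg$n_qtl)
    effects <- stats::rnorm(cfg$n_qtl)
    gv <- as.numeric(Xm[, qtl, drop = FALSE] %*% effects)
    if (cfg$architecture == "additive-plus-epistatic" && cfg$n_qtl >= 2L) {
      epi_effects <- stats::rnorm(cfg$n_qtl - 1L)
      for (q in seq_len(cfg$n_qtl - 1L))
        gv <- gv + epi_effects[q] * Xm[, qtl[q]] * Xm[, qtl[q + 1L]]
    }
    list(values = gv, qtl = qtl,
         effects = effects)
  })
  h2 <- cfg$heritability
  noise <- .with_seed(.derive_seed(cfg$seed, 3L), {
    if (h2 == 1 || stats::var(g$values) == 0) numeric(cfg$n)
    else if (h2 == 0) stats::rnorm(cfg$n, sd = max(stats::sd(g$values), 1))
    else stats::rnorm(cfg$n, sd = sqrt(stats::var(g$values) * (1 - h2) / h2))
  })
  y_raw <- if (h2 == 0) noise else g$values + noise
  offset <- min(y_raw)
  y <- trait_vector(y_raw - offset, trait_name = "sim_trait",
                    sample_ids = rownames(X))
  structure(list(dataset = align(X, y),
                 genetic_values = as.numeric(g$values) - offset,
                 qtl_indices = g$qtl, effects = g$effects,
                 heritability = h2),
            class = "simulated_dataset")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_trait()].
#'
#' @inheritParams simulate_genotypes
#' @export
simulate_dataset <- function(cfg) simulate_trait(simulate_genotypes(cfg), cfg)

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: n=%d, p=%d, %d QTL, h2=%.2f (%s)\n",
    nrow(x$dataset$markers), ncol(x$dataset$markers),
    length(x$qtl_indices), x$heritability,
    "trait shifted nonnegative"))
  invisible(x)
}
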