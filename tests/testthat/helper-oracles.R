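# Independent brute-force oracles used to pin expected values.
# These deliberately share no code with the package internals.

# DCG by an explicit loop over the top-k positions
naive_dcg <- function(y, perm, k, gain = "linear", discount = "log2") {
  total <- 0
  for (i in seq_len(k)) {
    g <- if (gain == "linear") y[perm[i]] else 2^y[perm[i]] - 1
    d <- if (discount == "log2") 1 / log2(i + 1) else 1
    total <- total + g * d
  }
  total
}

# pair counts by exhaustive double loop
naive_pair_counts <- function(y, s) {
  P <- C <- D <- Tt <- 0
  n <- length(y)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (y[i] > y[j]) {
      P <- P + 1
      if (s[i] > s[j]) C <- C + 1
      else if (s[i] < s[j]) D <- D + 1
      else Tt <- Tt + 1
    }
  }
  list(P = P, C = C, D = D, T = Tt)
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# tie-free random vectors (distinct values with probability 1; enforced)
random_tie_free <- function(n) {
  repeat {
    v <- stats::rnorm(n)
    if (!anyDuplicated(v)) return(v)
  }
}

# small genotype/trait toy: one causal marker, clean signal
toy_marker_data <- function(n = 30, p = 8, seed = 42) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.4), n, p)
  y <- 2 * X[, 1] - X[, 2] + rnorm(n, sd = 0.1)
  list(X = X, y = y)
}

# a classifier contract that memorizes the training rows exactly:
# returns one-hot probabilities for seen rows, uniform otherwise
memorizing_classifier <- function() {
  list(
    seed = 0L,
    fit = function(X, labels) {
      list(keys = apply(X, 1, paste, collapse = ","),
           labels = as.character(labels),
           classes = sort(unique(as.character(labels))))
    },
    predict_prob = function(model, X) {
      keys <- apply(X, 1, paste, collapse = ",")
      pr <- matrix(1 / length(model$classes), length(keys),
                   length(model$classes),
                   dimnames = list(NULL, model$classes))
      hit <- match(keys, model$keys)
      for (r in which(!is.na(hit))) {
        pr[r, ] <- 0
        pr[r, model$labels[hit[r]]] <- 1
      }
      pr
    }
  )
}

# benchmark methods that cheat by looking up the true trait for any row of
# the full genotype matrix: upper and lower reference points for ranking
oracle_method <- function(X_full, y_full, sign = 1) {
  keys_full <- apply(unclass(as.matrix(X_full)), 1, paste, collapse = ",")
  gs_method(
    name = if (sign > 0) "oracle" else "antioracle",
    fit = function(X, y, params) NULL,
    predict_scores = function(model, X) {
      keys <- apply(unclass(as.matrix(X)), 1, paste, collapse = ",")
      sign * y_full[match(keys, keys_full)]
    })
}
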