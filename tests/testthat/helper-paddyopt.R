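# Shared fixtures and independent oracles for the test suite.

BENEFITS <- c("yield", "ghg", "eb", "pfp", "eue")
INPUTS <- c("n_rate", "p_rate", "k_rate", "seed_rate")

# small cohort for fast end-to-end tests
small_config <- function(seed = 1L, ...) {
  synthetic_config(sizes = c(MT = 60L, MD = 50L, MAT = 80L, MAD = 40L),
                   seed = seed, ...)
}

# fast ensemble hyperparameters for tests
fast_params <- list(ntree_grid = 100L, mtry_grid = 2L, max_rounds = 60L,
                    cv_folds = 3L)

# independent exhaustive information-gain oracle (brute force over every
# feature and every midpoint threshold)
oracle_best_gain <- function(X, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  best <- list(gain = -Inf, feature = NA_character_, threshold = NA_real_)
  for (j in seq_along(X)) {
    xs <- sort(unique(X[[j]]))
    if (length(xs) < 2) next
    thr <- (xs[-length(xs)] + xs[-1]) / 2
    for (t in thr) {
      L <- y[X[[j]] < t]
      R <- y[X[[j]] >= t]
      g <- ent(y) - (length(L) / length(y)) * ent(L) -
        (length(R) / length(y)) * ent(R)
      if (g > best$gain + 1e-12) {
        best <- list(gain = g, feature = names(X)[j], threshold = t)
      }
    }
  }
  best
}

# independent loop implementation of the fit metrics
oracle_metrics <- function(obs, pred) {
  n <- length(obs)
  sse <- 0
  sae <- 0
  for (i in seq_len(n)) {
    sse <- sse + (obs[i] - pred[i])^2
    sae <- sae + abs(obs[i] - pred[i])
  }
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (obs[i] - mean(obs))^2
  rmse <- sqrt(sse / n)
  list(r2 = 1 - sse / sst, rmse = rmse, rrmse = 100 * rmse / mean(obs),
       mae = sae / n)
}

# walk a fitted tree checking child support sums at every split
check_support_conservation <- function(node) {
  if (node$type == "leaf") return(TRUE)
  node$left$n + node$right$n == node$n &&
    check_support_conservation(node$left) &&
    check_support_conservation(node$right)
}

tree_node_count <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + tree_node_count(node$left) + tree_node_count(node$right)
}

# bands whose pooled means are exactly the supplied values
bands_from_means <- function(means) {
  derive_bands(as.data.frame(as.list(means)))
}
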