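# a fake benefit table with a planted linear signal: yield = 2 * n_rate
planted_linear <- function(n = 200L, seed = 1L, shuffle = FALSE) {
  set.seed(seed)
  d <- data.frame(method = "MT",
                  n_rate = stats::runif(n, 100, 180),
                  p_rate = stats::runif(n, 60, 100),
                  k_rate = stats::runif(n, 110, 180),
                  seed_rate = stats::runif(n, 15, 26))
  d$yield <- 2 * d$n_rate
  if (shuffle) d$yield <- sample(d$yield)
  d
}

test_that("a noise-free planted linear signal is learned almost exactly", {
  d <- planted_linear(n = 400L)
  mods <- fit_benefit_models(d, "MT", benefits = "yield",
                             params = list(ntree_grid = c(200L, 400L),
                                           mtry_grid = c(2L, 3L),
                                           max_rounds = 150L,
                                           cv_folds = 3L), seed = 2L)
  expect_gte(mods$fits$yield$metrics_rf$r2, 0.99)
  expect_gte(mods$fits$yield$metrics_gbm$r2, 0.99)
})

test_that("permuted labels are unlearnable (negative control)", {
  d <- planted_linear(shuffle = TRUE)
  mods <- fit_benefit_models(d, "MT", benefits = "yield",
                             params = fast_params, seed = 2L)
  expect_lte(mods$fits$yield$metrics_rf$r2, 0.1)
  expect_lte(mods$fits$yield$metrics_gbm$r2, 0.1)
})

test_that("model fitting is deterministic given the seed", {
  d <- planted_linear()
  m1 <- fit_benefit_models(d, "MT", benefits = "yield",
                           params = fast_params, seed = 5L)
  m2 <- fit_benefit_models(d, "MT", benefits = "yield",
                           params = fast_params, seed = 5L)
  expect_identical(m1$fits$yield$pred_rf, m2$fits$yield$pred_rf)
  expect_identical(m1$fits$yield$pred_gbm, m2$fits$yield$pred_gbm)
  expect_identical(m1$fits$yield$train_idx, m2$fits$yield$train_idx)
})

test_that("degenerate inputs are rejected or skipped with a warning", {
  d <- planted_linear(n = 40L)
  d$yield <- 5
  expect_warning(mods <- fit_benefit_models(d, "MT", benefits = "yield",
                                            params = fast_params),
                 "constant")
  expect_length(mods$fits, 0L)
  expect_error(fit_benefit_models(planted_linear(n = 10L), "MT",
                                  params = fast_params),
               class = "validation_error")
  expect_error(fit_benefit_models(planted_linear(), "MAD",
                                  params = fast_params),
               class = "validation_error")
})

test_that("permutation importance finds the planted input", {
  d <- planted_linear()
  mods <- fit_benefit_models(d, "MT", benefits = "yield",
                             params = fast_params, seed = 3L)
  imp <- input_importance(mods, seed = 4L)
  for (mod in c("rf", "gbm")) {
    sub <- imp[imp$model == mod, ]
    expect_equal(sum(sub$importance), 1, tolerance = 1e-9)
    expect_equal(sub$input[sub$rank == 1], "n_rate")
    expect_gte(sub$importance[sub$input == "n_rate"], 0.8)
  }
})

test_that("inputs with zero planted effect never outrank planted inputs", {
  cfg <- small_config(seed = 22L,
                      effects = c(n_rate = 1500, p_rate = 0, k_rate = 800,
                                  seed_rate = 600))
  ben <- account_cohort(generate_cohort(cfg))
  mods <- fit_benefit_models(ben, "MAT", benefits = "yield",
                             params = fast_params, seed = 6L)
  imp <- input_importance(mods, seed = 7L)
  for (mod in c("rf", "gbm")) {
    sub <- imp[imp$model == mod, ]
    expect_equal(sub$input[sub$rank == 4], "p_rate")
  }
})

test_that("dependence curves respect the grid contract", {
  d <- planted_linear()
  mods <- fit_benefit_models(d, "MT", benefits = "yield",
                             params = fast_params, seed = 8L)
  pd_n <- partial_dependence(mods, "yield", "n_rate", grid_size = 15)
  expect_equal(nrow(pd_n), 15L)
  expect_true(all(diff(pd_n$x) > 0))
  qs <- stats::quantile(d$n_rate, c(0.05, 0.95))
  expect_gte(min(pd_n$x), qs[[1]] - 1e-9)
  expect_lte(max(pd_n$x), qs[[2]] + 1e-9)
  # an input with no planted effect gives an essentially flat curve
  pd_k <- partial_dependence(mods, "yield", "k_rate", grid_size = 15)
  expect_lte(diff(range(pd_k$yhat)), 0.1 * diff(range(pd_n$yhat)))
  expect_error(partial_dependence(mods, "yield", "rainfall"),
               class = "validation_error")
  expect_error(partial_dependence(mods, "eue", "n_rate"),
               class = "validation_error")
})

test_that("dependence_argmax locates the vertex of a concave curve", {
  curve <- structure(data.frame(x = seq(0, 10, length.out = 11)),
                     class = c("dependence_curve", "data.frame"))
  curve$yhat <- 50 - (curve$x - 6.3)^2
  expect_equal(dependence_argmax(curve), 6.3, tolerance = 1e-6)
  expect_equal(dependence_argmax(curve, smooth = FALSE), 6)
})

test_that("recommendations respect pinned constraints exactly", {
  d <- planted_linear()
  mods <- fit_benefit_models(d, "MT", benefits = "yield",
                             params = fast_params, seed = 9L)
  base <- vapply(d[, INPUTS], mean, numeric(1))
  pins <- lapply(base, function(v) c(v, v))
  rec <- recommend_inputs(mods, objective = "yield", constraints = pins)
  expect_equal(rec$recommended, base)
  expect_equal(unname(rec$pct_change), rep(0, 4))
  expect_error(recommend_inputs(mods, objective = "yield",
                                constraints = list(n_rate = c(10, 5))),
               class = "constraint_error")
})

test_that("minimizing emissions pushes nitrogen down", {
  ben <- account_cohort(generate_cohort(small_config(seed = 23L)))
  mods <- fit_benefit_models(ben, "MAT", benefits = "ghg",
                             params = fast_params, seed = 10L)
  rec <- recommend_inputs(mods, objective = "ghg")
  expect_lte(rec$recommended[["n_rate"]], rec$baseline[["n_rate"]])
})

test_that("mixed-effects model recovers a planted standardized effect", {
  set.seed(11)
  n <- 120L
  d <- data.frame(method = rep(c("MT", "MD", "MAT", "MAD"), each = n))
  d$n_rate <- stats::rnorm(4 * n, 140, 20)
  d$p_rate <- stats::rnorm(4 * n, 80, 12)
  d$k_rate <- stats::rnorm(4 * n, 150, 20)
  d$seed_rate <- stats::rnorm(4 * n, 21, 3)
  meth_off <- c(MT = 1, MD = -1, MAT = 0.5, MAD = -0.5)
  d$yield <- 2 * as.numeric(scale(d$n_rate)) + meth_off[d$method] +
    stats::rnorm(4 * n, 0, 0.5)
  chk <- mixed_effects_check(d, "yield")
  est <- chk$estimates[chk$estimates$term == "n_rate", ]
  expect_gt(est$ci_high, 2)
  expect_lt(est$ci_low, 2)
  expect_gt(chk$random_intercept_var, 0)
})

test_that("standardization makes estimates invariant to input rescaling", {
  set.seed(12)
  d <- data.frame(method = rep(c("MT", "MD"), each = 60))
  d$n_rate <- stats::rnorm(120, 140, 20)
  d$p_rate <- stats::rnorm(120, 80, 12)
  d$k_rate <- stats::rnorm(120, 150, 20)
  d$seed_rate <- stats::rnorm(120, 21, 3)
  d$yield <- 3 * as.numeric(scale(d$k_rate)) +
    (d$method == "MT") + stats::rnorm(120, 0, 0.4)
  c1 <- suppressWarnings(mixed_effects_check(d, "yield"))
  d2 <- d
  d2$k_rate <- d2$k_rate * 1000
  c2 <- suppressWarnings(mixed_effects_check(d2, "yield"))
  expect_equal(c1$estimates$estimate, c2$estimates$estimate,
               tolerance = 1e-8)
})

test_that("a pure-noise benefit shows no spurious input effects", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    d <- data.frame(method = rep(c("MT", "MD", "MAT", "MAD"), each = 40))
    for (j in INPUTS) d[[j]] <- stats::rnorm(160, 100, 15)
    d$eb <- stats::rnorm(160)
    chk <- suppressWarnings(mixed_effects_check(d, "eb"))
    covers <- all(chk$estimates$ci_low <= 0 & chk$estimates$ci_high >= 0)
    if (covers) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
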