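test_that("a perfectly separable toy set splits at the separating midpoint", {
  X <- data.frame(yield = c(9200, 9400, 9600, 9800,
                            10200, 10400, 10600, 10800),
                  ghg = c(5, 6, 7, 8, 5, 6, 7, 8))
  y <- rep(c("low", "high"), each = 4)
  tr <- fit_tree(X, y, params = list(train_frac = 1, min_leaf = 1,
                                     prune = FALSE))
  expect_equal(tr$root$type, "split")
  expect_equal(tr$root$feature, "yield")
  expect_equal(tr$root$threshold, 10000)
  expect_equal(tr$root$left$prob, 1)
  expect_equal(tr$root$right$prob, 1)
  oracle <- oracle_best_gain(X, y)
  expect_equal(tr$root$gain, oracle$gain, tolerance = 1e-12)
})

test_that("the chosen root split matches exhaustive search on small data", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    X <- as.data.frame(lapply(stats::setNames(1:k, paste0("f", 1:k)),
                              function(j) round(stats::runif(n, 0, 10), 1)))
    y <- sample(c("A", "B", "C")[1:sample(2:3, 1)], n, replace = TRUE)
    if (length(unique(y)) < 2) next
    tr <- fit_tree(X, y, params = list(train_frac = 1, min_leaf = 1,
                                       prune = FALSE, max_depth = 1))
    oracle <- oracle_best_gain(X, y)
    if (tr$root$type == "split") {
      expect_equal(tr$root$gain, oracle$gain, tolerance = 1e-9)
    } else {
      expect_lte(oracle$gain, 1e-8)
    }
  }
})

test_that("trees are deterministic and conserve leaf support", {
  ben <- account_cohort(generate_cohort(small_config(seed = 12L)))
  bands <- derive_bands(ben)
  codes <- classify_benefits(ben, bands)
  X <- ben[, BENEFITS]
  t1 <- fit_tree(X, codes, params = list(seed = 5L))
  t2 <- fit_tree(X, codes, params = list(seed = 5L))
  expect_identical(t1$root, t2$root)
  expect_identical(t1$train_idx, t2$train_idx)
  expect_true(check_support_conservation(t1$root))
  expect_true(check_support_conservation(t1$unpruned))
})

test_that("pruning shrinks the tree and never improves training accuracy", {
  ben <- account_cohort(generate_cohort(small_config(seed = 13L)))
  bands <- derive_bands(ben)
  codes <- classify_benefits(ben, bands)
  X <- ben[, BENEFITS]
  tr <- fit_tree(X, codes, params = list(seed = 2L, prune = TRUE))
  expect_lte(tree_node_count(tr$root), tree_node_count(tr$unpruned))
  pruned_acc <- mean(predict(tr, X[tr$train_idx, ]) == codes[tr$train_idx])
  full <- tr
  full$root <- tr$unpruned
  full_acc <- mean(predict(full, X[tr$train_idx, ]) == codes[tr$train_idx])
  expect_lte(pruned_acc, full_acc)
})

test_that("single-class input degenerates to one confident leaf", {
  X <- data.frame(yield = 1:10)
  expect_warning(tr <- fit_tree(X, rep("only", 10),
                                params = list(train_frac = 1)),
                 "single class")
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$prob, 1)
  paths <- extract_paths(tr, "only")
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$prob, 1)
  expect_equal(nrow(paths[[1]]$conditions), 0L)
})

test_that("extracted paths are consistent and target-filtered", {
  ben <- account_cohort(generate_cohort(small_config(seed = 14L)))
  bands <- derive_bands(ben)
  codes <- classify_benefits(ben, bands)
  tr <- fit_tree(ben[, BENEFITS], codes, params = list(seed = 7L))
  paths <- extract_paths(tr)
  expect_gt(length(paths), 0L)
  for (p in paths) {
    # per feature and direction at most one binding threshold
    key <- paste(p$conditions$feature, p$conditions$op)
    expect_false(anyDuplicated(key) > 0)
  }
  expect_length(extract_paths(tr, "no-such-code"), 0L)
})

test_that("confusion statistics match hand arithmetic", {
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  ev <- evaluate_predictions(truth, pred)
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$detection_prevalence[["pos"]], 0.4)
  expect_equal(unname(rowSums(ev$confusion)), c(6, 4))
  expect_error(evaluate_predictions(character(0), character(0)),
               class = "validation_error")
})

test_that("an unbootstrapped single-bag ensemble reduces to one tree", {
  ben <- account_cohort(generate_cohort(small_config(seed = 15L)))
  bands <- derive_bands(ben)
  codes <- classify_benefits(ben, bands)
  X <- ben[, BENEFITS]
  bag <- suppressWarnings(
    bagging_fit(X, codes, params = list(n_bags = 1L, bootstrap = FALSE,
                                        seed = 9L)))
  single <- fit_tree(X[bag$train_idx, ], codes[bag$train_idx],
                     params = list(train_frac = 1, prune = FALSE))
  expect_equal(as.character(predict(bag, X[bag$test_idx, ])),
               as.character(predict(single, X[bag$test_idx, ])))
})

test_that("stratified splitting preserves class proportions", {
  ben <- account_cohort(generate_cohort(small_config(seed = 16L)))
  bands <- derive_bands(ben)
  codes <- factor(classify_benefits(ben, bands))
  bag <- suppressWarnings(bagging_fit(ben[, BENEFITS], codes,
                                      params = list(seed = 3L)))
  tab_all <- table(codes)
  tab_train <- table(factor(codes[bag$train_idx], levels = levels(codes)))
  for (cl in names(tab_all)) {
    expect_lte(abs(tab_train[[cl]] - round(0.75 * tab_all[[cl]])), 1)
  }
  # a singleton class stays in training, with a warning
  y1 <- as.character(codes)
  y1[1] <- "unique-code"
  expect_warning(bagging_fit(ben[, BENEFITS], y1,
                             params = list(seed = 3L, n_bags = 2L)),
                 "single record")
})

test_that("bagging is at least as accurate as a pruned tree most seeds", {
  ben <- account_cohort(generate_cohort(
    synthetic_config(sizes = c(MT = 150L, MD = 40L, MAT = 40L, MAD = 40L),
                     seed = 17L)))
  bands <- derive_bands(ben)
  codes <- classify_benefits(ben, bands)
  sel <- ben$method == "MT"
  X <- ben[sel, BENEFITS]
  y <- codes[sel]
  wins <- 0L
  for (s in 1:10) {
    bag <- suppressWarnings(
      bagging_fit(X, y, params = list(seed = s, n_bags = 15L)))
    tr <- suppressWarnings(
      fit_tree(X, y, params = list(seed = s, train_frac = 0.75)))
    tr_acc <- evaluate_classifier(tr, X[tr$test_idx, ],
                                  y[tr$test_idx])$accuracy
    if (bag$eval$accuracy >= tr_acc) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
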