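dirs2 <- c(a = "benefit", b = "benefit")

test_that("entropy weights reward discriminating criteria", {
  # symmetric 2x2: both criteria equally informative
  dm <- decision_matrix(matrix(c(1, 0, 0, 1), 2, 2,
                               dimnames = list(NULL, c("a", "b"))), dirs2)
  expect_equal(unname(entropy_weights(dm)), c(0.5, 0.5))
  # a constant column carries no information
  dm2 <- decision_matrix(matrix(c(1, 2, 5, 5), 2, 2,
                                dimnames = list(NULL, c("a", "b"))), dirs2)
  expect_equal(unname(entropy_weights(dm2)), c(1, 0))
  # weights always sum to one
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(stats::runif(12), 4, 3)
    colnames(m) <- c("x", "y", "z")
    dm3 <- decision_matrix(m, c(x = "benefit", y = "cost", z = "benefit"))
    expect_equal(sum(entropy_weights(dm3)), 1, tolerance = 1e-12)
  }
  # fully constant matrix: uniform weights with a warning
  dm4 <- decision_matrix(matrix(1, 3, 2,
                                dimnames = list(NULL, c("a", "b"))), dirs2)
  expect_warning(w <- entropy_weights(dm4), "uniform")
  expect_equal(unname(w), c(0.5, 0.5))
})

test_that("ideal and anti-ideal alternatives score 100 and 0", {
  m <- rbind(best = c(10, 1, 8), mid = c(6, 3, 5), worst = c(2, 9, 1))
  colnames(m) <- c("yield", "ghg", "eb")
  dm <- decision_matrix(m, c(yield = "benefit", ghg = "cost",
                             eb = "benefit"))
  res <- topsis(dm, rep(1 / 3, 3))
  expect_equal(res$score[["best"]], 100)
  expect_equal(res$score[["worst"]], 0)
  expect_equal(unname(res$rank), c(1L, 2L, 3L))
})

test_that("closeness is invariant to criterion rescaling", {
  set.seed(2)
  m <- matrix(stats::runif(20, 1, 10), 4, 5)
  colnames(m) <- c("yield", "ghg", "eb", "pfp", "eue")
  dirs <- c(yield = "benefit", ghg = "cost", eb = "benefit",
            pfp = "benefit", eue = "benefit")
  w <- rep(0.2, 5)
  r1 <- topsis(decision_matrix(m, dirs), w)
  m2 <- m
  m2[, "eb"] <- m2[, "eb"] * 1000
  r2 <- topsis(decision_matrix(m2, dirs), w)
  expect_equal(r1$closeness, r2$closeness, tolerance = 1e-12)
})

test_that("improving an alternative never lowers its own closeness", {
  set.seed(3)
  dirs <- c(yield = "benefit", ghg = "cost", eb = "benefit")
  for (i in 1:25) {
    m <- matrix(stats::runif(12, 1, 10), 4, 3)
    colnames(m) <- names(dirs)
    w <- stats::runif(3)
    w <- w / sum(w)
    r1 <- topsis(decision_matrix(m, dirs), w)
    i_alt <- sample(4, 1)
    j <- sample(3, 1)
    m2 <- m
    if (dirs[[j]] == "cost") {
      m2[i_alt, j] <- m2[i_alt, j] * 0.7
    } else {
      m2[i_alt, j] <- m2[i_alt, j] * 1.3
    }
    r2 <- topsis(decision_matrix(m2, dirs), w)
    expect_gte(r2$closeness[[i_alt]], r1$closeness[[i_alt]] - 1e-12)
  }
})

test_that("degenerate matrices are handled explicitly", {
  m <- matrix(c(1, 1, 2, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  res <- topsis(decision_matrix(m, dirs2), c(0.5, 0.5))
  expect_equal(unname(res$score), c(50, 50))   # identical alternatives
  mz <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(topsis(decision_matrix(mz, dirs2), c(0.5, 0.5)), "a",
               class = "scoring_error")
  expect_error(decision_matrix(matrix(1, 1, 2), c("benefit", "benefit")),
               class = "scoring_error")
})

test_that("the published method-mean matrix ranks MT first", {
  dm <- decision_matrix(reference_means(),
                        c(yield = "benefit", ghg = "cost", eb = "benefit",
                          pfp = "benefit", eue = "benefit"))
  res <- topsis(dm)
  expect_equal(res$rank,
               c(MT = 1L, MD = 2L, MAT = 3L, MAD = 4L))
})

test_that("method scoring works at both granularities", {
  ben <- account_cohort(generate_cohort(
    calibrate_yields(synthetic_config(seed = 31L))))
  res <- score_methods(ben)
  expect_equal(attr(res, "mode"), "method-means")
  expect_true(all(res$score >= 0 & res$score <= 100))
  expect_equal(res$rank[["MT"]], 1L)

  # zero within-method variance: record-level collapses to method-means
  base <- account_cohort(make_toy_fixture())
  rep_tab <- do.call(rbind, lapply(c("MT", "MD", "MAT", "MAD"),
    function(m) {
      row <- base[base$method == m, ][1, ]
      out <- row[rep(1, 5), ]
      out$row_id <- paste0(m, "-", 1:5)
      out
    }))
  r_means <- score_methods(rep_tab, mode = "method-means")
  r_rec <- score_methods(rep_tab, mode = "record-level")
  expect_equal(attr(r_rec, "mode"), "record-level")
  expect_equal(r_rec$rank, r_means$rank)

  same <- base
  same[, c("yield", "ghg", "eb", "pfp", "eue")] <-
    base[rep(1, nrow(base)), c("yield", "ghg", "eb", "pfp", "eue")]
  res_same <- suppressWarnings(score_methods(same))
  expect_equal(unname(diff(range(res_same$score))), 0)
})

test_that("ratios of the published comprehensive scores are reproduced", {
  s <- reference_scores()
  expect_equal(round(s[["MT"]] / s[["MD"]], 1), 1.1)
  expect_equal(round(s[["MT"]] / s[["MAT"]], 1), 2.1)
  expect_equal(round(s[["MT"]] / s[["MAD"]], 1), 2.6)
})
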