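# Entropy-weighted TOPSIS comprehensive benefit scoring.
#
# Criterion weights come from Shannon entropy of each min-max-normalized
# column: criteria whose values differ more across alternatives carry more
# information and get larger weight. TOPSIS then ranks alternatives by
# relative closeness to the ideal solution (best value of every criterion)
# versus the anti-ideal, on a weighted, vector-normalized matrix. GHG is a
# cost criterion: its ideal is the minimum.

#' Construct a decision matrix
#'
#' @param x Numeric matrix or data frame, alternatives in rows, criteria in
#'   columns; no missing cells, at least two alternatives.
#' @param directions Named character vector over the criteria, each
#'   `"benefit"` or `"cost"`.
#' @return A `decision_matrix` object.
#' @export
decision_matrix <- function(x, directions) {
  x <- as.matrix(x)
  if (!is.numeric(x)) pd_stop("decision matrix must be numeric", "scoring_error")
  if (nrow(x) < 2L)
    pd_stop("decision matrix needs at least 2 alternatives", "scoring_error")
  if (anyNA(x)) pd_stop("decision matrix has missing cells", "scoring_error")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("criterion", seq_len(ncol(x)))
  if (is.null(rownames(x)))
    rownames(x) <- paste0("alt", seq_len(nrow(x)))
  if (is.null(names(directions)) && length(directions) == ncol(x))
    names(directions) <- colnames(x)
  if (!all(colnames(x) %in% names(directions)))
    pd_stop("directions must cover every criterion", "scoring_error")
  directions <- directions[colnames(x)]
  if (!all(directions %in% c("benefit", "cost")))
    pd_stop("directions must be 'benefit' or 'cost'", "scoring_error")
  structure(list(x = x, directions = directions), class = "decision_matrix")
}

.default_directions <- function(criteria) {
  stats::setNames(ifelse(criteria == "ghg", "cost", "benefit"), criteria)
}

#' Entropy weights of a decision matrix
#'
#' Each column is min-max normalized to proportions; its Shannon entropy
#' (scaled by 1/ln m) measures how little the criterion discriminates, and
#' weights are proportional to 1 minus entropy. A constant column carries no
#' information and gets weight zero; if every column is constant, uniform
#' weights are returned with a warning.
#'
#' With `invert_cost = TRUE` cost columns are reflected (max minus x) before
#' normalization. The default leaves columns as-is: min-max reflection does
#' not change a criterion's dispersion, only which alternative sits at zero,
#' and the un-inverted form reproduces the published comprehensive-benefit
#' ordering of the four planting methods.
#'
#' @param dm A `decision_matrix`.
#' @param invert_cost Reflect cost columns before normalization.
#' @return Named weight vector summing to 1.
#' @export
entropy_weights <- function(dm, invert_cost = FALSE) {
  if (!inherits(dm, "decision_matrix"))
    pd_stop("expected a decision_matrix", "scoring_error")
  x <- dm$x
  m <- nrow(x)
  ent <- vapply(colnames(x), function(j) {
    v <- x[, j]
    if (invert_cost && dm$directions[[j]] == "cost") v <- max(v) - v
    rng <- max(v) - min(v)
    if (rng == 0) return(1)                      # constant: max entropy
    u <- (v - min(v)) / rng
    p <- u / sum(u)
    p <- p[p > 0]
    -sum(p * log(p)) / log(m)
  }, numeric(1))
  info <- 1 - ent
  if (all(info <= 0)) {
    warning("all criteria constant; falling back to uniform weights")
    return(stats::setNames(rep(1 / ncol(x), ncol(x)), colnames(x)))
  }
  info / sum(info)
}

# fixed TOPSIS geometry (norms, ideal, anti-ideal) reusable for scoring
# out-of-matrix candidate vectors
topsis_geometry <- function(dm, weights) {
  x <- dm$x
  norms <- sqrt(colSums(x^2))
  zero <- names(norms)[norms == 0]
  if (length(zero))
    pd_stop(sprintf("zero-norm criterion column: %s",
                    paste(zero, collapse = ", ")), "scoring_error")
  v <- sweep(sweep(x, 2, norms, "/"), 2, weights, "*")
  ideal <- anti <- numeric(ncol(v))
  names(ideal) <- names(anti) <- colnames(v)
  for (j in colnames(v)) {
    if (dm$directions[[j]] == "cost") {
      ideal[j] <- min(v[, j]); anti[j] <- max(v[, j])
    } else {
      ideal[j] <- max(v[, j]); anti[j] <- min(v[, j])
    }
  }
  list(norms = norms, weights = weights, ideal = ideal, anti = anti,
       directions = dm$directions)
}

closeness_in_geometry <- function(geom, values) {
  v <- (values / geom$norms) * geom$weights
  dpos <- sqrt(sum((v - geom$ideal)^2))
  dneg <- sqrt(sum((v - geom$anti)^2))
  if (dpos + dneg == 0) return(0.5)    # degenerate: all alternatives identical
  dneg / (dpos + dneg)
}

#' TOPSIS ranking of a decision matrix
#'
#' Vector (root-sum-square) column normalization, multiplication by the
#' criterion weights, Euclidean distances to the ideal and anti-ideal
#' solutions, relative closeness `d- / (d+ + d-)` and a 0-100 comprehensive
#' score. Ties in score are broken by alternative order.
#'
#' @param dm A `decision_matrix`.
#' @param weights Criterion weights; defaults to [entropy_weights()].
#' @return A `topsis_result` with weights, distances, closeness, scores and
#'   ranks.
#' @export
topsis <- function(dm, weights = NULL) {
  if (!inherits(dm, "decision_matrix"))
    pd_stop("expected a decision_matrix", "scoring_error")
  if (is.null(weights)) weights <- entropy_weights(dm)
  if (length(weights) != ncol(dm$x) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    pd_stop("weights must be non-negative and sum to 1", "scoring_error")
  geom <- topsis_geometry(dm, weights)
  cl <- apply(dm$x, 1L, function(row) closeness_in_geometry(geom, row))
  score <- 100 * cl
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score)); rank[ord] <- seq_along(score)
  v <- sweep(sweep(dm$x, 2, geom$norms, "/"), 2, weights, "*")
  dpos <- sqrt(rowSums(sweep(v, 2, geom$ideal)^2))
  dneg <- sqrt(rowSums(sweep(v, 2, geom$anti)^2))
  structure(list(weights = weights,
                 distances = data.frame(alternative = rownames(dm$x),
                                        d_ideal = dpos, d_anti = dneg),
                 closeness = stats::setNames(cl, rownames(dm$x)),
                 score = stats::setNames(score, rownames(dm$x)),
                 rank = stats::setNames(rank, rownames(dm$x)),
                 directions = dm$directions),
            class = "topsis_result")
}

#' Comprehensive benefit scores per planting method
#'
#' `"method-means"` (default) builds the methods-by-indicators matrix of
#' per-method mean benefits and scores the four methods; `"record-level"`
#' scores every record in a single TOPSIS geometry and averages closeness
#' per method. GHG is treated as a cost criterion, the other four
#' indicators as benefits.
#'
#' @param benefit_table A `benefit_table` (from [account_cohort()]) with a
#'   `method` column.
#' @param mode `"method-means"` or `"record-level"`.
#' @param invert_cost Passed to [entropy_weights()].
#' @return A `topsis_result`; attribute `mode` records the granularity.
#' @export
#' @examples
#' ben <- account_cohort(make_toy_fixture())
#' score_methods(ben)
score_methods <- function(benefit_table,
                          mode = c("method-means", "record-level"),
                          invert_cost = FALSE) {
  mode <- match.arg(mode)
  if (!("method" %in% names(benefit_table)))
    pd_stop("benefit_table needs a 'method' column", "schema_error")
  dirs <- .default_directions(.BENEFIT_COLS)
  if (mode == "method-means") {
    meth <- intersect(.PADDY_METHODS, unique(benefit_table$method))
    mat <- t(vapply(meth, function(m) {
      sub <- benefit_table[benefit_table$method == m, .BENEFIT_COLS]
      vapply(sub, function(v) mean(v, na.rm = TRUE), numeric(1))
    }, numeric(length(.BENEFIT_COLS))))
    colnames(mat) <- .BENEFIT_COLS
    dm <- decision_matrix(mat, dirs)
    res <- topsis(dm, entropy_weights(dm, invert_cost = invert_cost))
  } else {
    keep <- stats::complete.cases(benefit_table[, .BENEFIT_COLS])
    sub <- benefit_table[keep, ]
    mat <- as.matrix(sub[, .BENEFIT_COLS])
    rownames(mat) <- sub$row_id %||% seq_len(nrow(mat))
    dm <- decision_matrix(mat, dirs)
    w <- entropy_weights(dm, invert_cost = invert_cost)
    geom <- topsis_geometry(dm, w)
    cl <- apply(mat, 1L, function(row) closeness_in_geometry(geom, row))
    meth <- intersect(.PADDY_METHODS, unique(sub$method))
    avg <- vapply(meth, function(m) mean(cl[sub$method == m]), numeric(1))
    score <- 100 * avg
    ord <- order(-score, seq_along(score))
    rank <- integer(length(score)); rank[ord] <- seq_along(score)
    res <- structure(list(weights = w, distances = NULL,
                          closeness = stats::setNames(avg, meth),
                          score = stats::setNames(score, meth),
                          rank = stats::setNames(rank, meth),
                          directions = dirs),
                     class = "topsis_result")
  }
  attr(res, "mode") <- mode
  res
}

#' @export
print.topsis_result <- function(x, ...) {
  mode <- attr(x, "mode")
  cat("Entropy-weighted TOPSIS comprehensive benefits",
      if (!is.null(mode)) sprintf("(%s)", mode) else "", "\n")
  cat("weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                        collapse = " "), "\n")
  df <- data.frame(alternative = names(x$score),
                   closeness = round(x$closeness, 4),
                   score = round(x$score, 2), rank = x$rank)
  print(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}
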