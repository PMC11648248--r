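# Information-gain decision tree over the five benefit indicators.
#
# The classic ID3 criterion (maximum information gain) is defined for
# categorical attributes; benefit indicators are continuous, so splits are
# C4.5-style binary thresholds: candidate thresholds are the midpoints of
# consecutive distinct sorted values of each feature, and the split
# maximizing information gain is chosen greedily. Ties are broken by lowest
# feature index, then smallest threshold. Overfitting is controlled by
# reduced-error pruning against a validation fold carved from the training
# set. Leaf class probabilities are training-set purities and are labelled
# as such.

.entropy_counts <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

# exhaustive scan for the best binary threshold split
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  K <- nlevels(y)
  parent <- .entropy_counts(tabulate(as.integer(y), K))
  best <- NULL
  for (j in seq_along(X)) {
    x <- X[[j]]
    ord <- order(x)
    xs <- x[ord]
    ys <- as.integer(y[ord])
    Y <- matrix(0L, n, K)
    Y[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(Y, 2L, cumsum)
    total <- cum[n, ]
    pos <- which(diff(xs) > 0)
    pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
    if (!length(pos)) next
    for (i in pos) {
      left <- cum[i, ]
      right <- total - left
      h <- (i / n) * .entropy_counts(left) +
        ((n - i) / n) * .entropy_counts(right)
      gain <- parent - h
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = names(X)[j], j = j,
                     threshold = (xs[i] + xs[i + 1]) / 2, gain = gain)
      }
    }
  }
  best
}

leaf_node <- function(y, levels) {
  counts <- tabulate(as.integer(y), length(levels))
  cls <- levels[which.max(counts)]        # ties: first factor level
  list(type = "leaf", class = cls,
       prob = max(counts) / max(sum(counts), 1L),
       n = length(y), counts = stats::setNames(counts, levels))
}

grow_tree <- function(X, y, min_leaf, max_depth, min_gain, depth = 0L) {
  levels <- levels(y)
  node <- leaf_node(y, levels)
  if (length(unique(y)) < 2L || depth >= max_depth ||
      length(y) < 2L * min_leaf)
    return(node)
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp) || sp$gain <= min_gain) return(node)
  go_left <- X[[sp$feature]] < sp$threshold
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       gain = sp$gain, n = length(y),
       class = node$class, prob = node$prob, counts = node$counts,
       left = grow_tree(X[go_left, , drop = FALSE], y[go_left],
                        min_leaf, max_depth, min_gain, depth + 1L),
       right = grow_tree(X[!go_left, , drop = FALSE], y[!go_left],
                         min_leaf, max_depth, min_gain, depth + 1L))
}

# reduced-error pruning: collapse a subtree to its training-majority leaf
# whenever that does not increase validation errors (ties prune)
prune_node <- function(node, Xv, yv) {
  leaf_err <- sum(yv != node$class)
  if (node$type == "leaf") return(list(node = node, err = leaf_err))
  go_left <- Xv[[node$feature]] < node$threshold
  L <- prune_node(node$left, Xv[go_left, , drop = FALSE], yv[go_left])
  R <- prune_node(node$right, Xv[!go_left, , drop = FALSE], yv[!go_left])
  node$left <- L$node
  node$right <- R$node
  sub_err <- L$err + R$err
  if (leaf_err <= sub_err) {
    leaf <- list(type = "leaf", class = node$class, prob = node$prob,
                 n = node$n, counts = node$counts)
    return(list(node = leaf, err = leaf_err))
  }
  list(node = node, err = sub_err)
}

count_nodes <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + count_nodes(node$left) + count_nodes(node$right)
}

predict_node <- function(node, X, idx, out, levels) {
  if (!length(idx)) return(out)
  if (node$type == "leaf") {
    out[idx] <- node$class
    return(out)
  }
  go_left <- X[[node$feature]][idx] < node$threshold
  out <- predict_node(node$left, X, idx[go_left], out, levels)
  predict_node(node$right, X, idx[!go_left], out, levels)
}

#' Fit an information-gain decision tree on benefit indicators
#'
#' Greedy binary threshold splits on continuous features maximizing
#' information gain; candidate thresholds are midpoints of sorted unique
#' values. The data are split into training and held-out fractions; when
#' pruning is enabled a validation fold is carved from the training set for
#' reduced-error pruning. Deterministic given the seed. A single-class
#' input yields a degenerate one-leaf tree with a warning.
#'
#' @param features Data frame of numeric features (typically the five
#'   benefit columns).
#' @param labels Class labels (composite benefit codes), coercible to
#'   factor.
#' @param params List of tuning parameters: `train_frac` (default 0.70),
#'   `min_leaf` (5), `max_depth` (5), `prune` (TRUE), `val_frac` (0.2 of
#'   the training set), `min_gain` (1e-8), `seed` (1).
#' @return A `benefit_tree` with the fitted root node, train/validation/
#'   held-out row indices and the parameters used.
#' @export
#' @examples
#' ben <- account_cohort(make_toy_fixture())
#' bands <- derive_bands(ben)
#' codes <- classify_benefits(ben, bands)
#' fit_tree(ben[, c("yield", "ghg", "eb", "pfp", "eue")], codes,
#'          params = list(train_frac = 1, min_leaf = 1, prune = FALSE))
fit_tree <- function(features, labels, params = list()) {
  p <- utils::modifyList(list(train_frac = 0.70, min_leaf = 5L,
                              max_depth = 5L, prune = TRUE, val_frac = 0.2,
                              min_gain = 1e-8, seed = 1L), params)
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1))))
    pd_stop("tree features must be numeric", "validation_error")
  labels <- factor(labels)
  n <- nrow(features)
  if (length(labels) != n)
    pd_stop("features and labels must have equal length", "validation_error")
  keep <- stats::complete.cases(features) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  n <- nrow(features)
  with_seed(p$seed, {
    n_train <- max(1L, round(p$train_frac * n))
    train_idx <- sort(sample.int(n, n_train))
    test_idx <- setdiff(seq_len(n), train_idx)
    val_idx <- integer(0)
    fit_idx <- train_idx
    if (isTRUE(p$prune) && p$val_frac > 0 && length(train_idx) >= 5L) {
      n_val <- max(1L, round(p$val_frac * length(train_idx)))
      val_idx <- sort(sample(train_idx, n_val))
      fit_idx <- setdiff(train_idx, val_idx)
    }
    y_fit <- droplevels(labels[fit_idx])
    if (nlevels(y_fit) < 2L) {
      warning("single class in training data; returning a one-leaf tree")
      root <- leaf_node(y_fit, levels(y_fit))
      unpruned <- root
    } else {
      root <- grow_tree(features[fit_idx, , drop = FALSE], y_fit,
                        p$min_leaf, p$max_depth, p$min_gain)
      unpruned <- root
      if (isTRUE(p$prune) && length(val_idx)) {
        root <- prune_node(root, features[val_idx, , drop = FALSE],
                           labels[val_idx])$node
      }
    }
    structure(list(root = root, unpruned = unpruned,
                   levels = levels(labels),
                   features = names(features),
                   train_idx = train_idx, val_idx = val_idx,
                   test_idx = test_idx, params = p, n = n),
              class = "benefit_tree")
  })
}

#' @export
predict.benefit_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    pd_stop(sprintf("newdata lacks feature(s): %s",
                    paste(miss, collapse = ", ")), "validation_error")
  out <- character(nrow(newdata))
  out <- predict_node(object$root, newdata, seq_len(nrow(newdata)), out,
                      object$levels)
  factor(out, levels = object$levels)
}

print_node <- function(node, indent = "") {
  if (node$type == "leaf") {
    cat(sprintf("%s=> %s (p=%.2f, n=%d)\n", indent, node$class, node$prob,
                node$n))
  } else {
    cat(sprintf("%s%s < %.4g ?\n", indent, node$feature, node$threshold))
    print_node(node$left, paste0(indent, "  "))
    print_node(node$right, paste0(indent, "  "))
  }
}

#' @export
print.benefit_tree <- function(x, ...) {
  cat(sprintf("Information-gain decision tree (%d nodes, %d classes)\n",
              count_nodes(x$root), length(x$levels)))
  print_node(x$root)
  invisible(x)
}

collect_paths <- function(node, conds) {
  if (node$type == "leaf") {
    return(list(list(conditions = conds, class = node$class,
                     prob = node$prob, support = node$n)))
  }
  lc <- rbind(conds, data.frame(feature = node$feature, op = "<",
                                threshold = node$threshold,
                                stringsAsFactors = FALSE))
  rc <- rbind(conds, data.frame(feature = node$feature, op = ">=",
                                threshold = node$threshold,
                                stringsAsFactors = FALSE))
  c(collect_paths(node$left, lc), collect_paths(node$right, rc))
}

# keep only the binding condition per (feature, op): max threshold for >=,
# min for <, so each path is a consistent interval per feature
simplify_conditions <- function(conds) {
  if (!nrow(conds)) return(conds)
  out <- do.call(rbind, lapply(split(conds, conds[, c("feature", "op")],
                                     drop = TRUE), function(d) {
    thr <- if (d$op[1] == ">=") max(d$threshold) else min(d$threshold)
    data.frame(feature = d$feature[1], op = d$op[1], threshold = thr,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$feature, out$op), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract decision paths reaching a target benefit code
#'
#' Walks every root-to-leaf path of a fitted tree and returns those whose
#' leaf predicts the target class, as ordered threshold conditions with the
#' leaf's class probability (training purity) and support.
#'
#' @param tree A `benefit_tree`.
#' @param target Target class label; `NULL` returns every leaf path.
#' @return A `decision_paths` list; each element has `conditions` (data
#'   frame feature/op/threshold), `class`, `prob`, `support`. Empty if the
#'   target is unreachable.
#' @export
extract_paths <- function(tree, target = NULL) {
  if (!inherits(tree, "benefit_tree"))
    pd_stop("expected a benefit_tree", "validation_error")
  empty <- data.frame(feature = character(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  paths <- collect_paths(tree$root, empty)
  if (!is.null(target)) paths <- Filter(function(p) p$class == target, paths)
  paths <- lapply(paths, function(p) {
    p$conditions <- simplify_conditions(p$conditions)
    p
  })
  structure(paths, class = "decision_paths")
}

format_path <- function(p) {
  cond <- if (nrow(p$conditions))
    paste(sprintf("%s %s %.4g", p$conditions$feature, p$conditions$op,
                  p$conditions$threshold), collapse = " & ")
  else "(root)"
  sprintf("%s -> %s (p=%.2f, n=%d)", cond, p$class, p$prob, p$support)
}

#' @export
print.decision_paths <- function(x, ...) {
  cat(sprintf("%d decision path(s)\n", length(x)))
  for (p in x) cat(" ", format_path(p), "\n")
  invisible(x)
}

#' Confusion-matrix evaluation of predictions
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @return A `classifier_eval`: confusion matrix (rows = truth, columns =
#'   predictions), overall accuracy, and per-class detection prevalence
#'   `(TP + FP) / total` (the fraction of cases assigned to each class).
#' @export
evaluate_predictions <- function(truth, pred) {
  if (!length(truth)) pd_stop("empty evaluation set", "validation_error")
  if (length(truth) != length(pred))
    pd_stop("truth and pred must have equal length", "validation_error")
  lev <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  dp <- colSums(cm) / sum(cm)
  structure(list(confusion = cm, accuracy = acc,
                 detection_prevalence = dp, n = length(truth)),
            class = "classifier_eval")
}

#' Evaluate a classifier on held-out records
#'
#' @param model A fitted `benefit_tree` or `bag_ensemble`.
#' @param features Held-out feature rows.
#' @param labels Held-out true labels. Classes present here but absent from
#'   training are simply never predicted (zero prediction column).
#' @return A `classifier_eval`; see [evaluate_predictions()].
#' @export
evaluate_classifier <- function(model, features, labels) {
  if (!length(labels)) pd_stop("empty evaluation set", "validation_error")
  evaluate_predictions(labels, predict(model, features))
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("Accuracy %.3f on %d records\n", x$accuracy, x$n))
  print(x$confusion)
  cat("detection prevalence:",
      paste(sprintf("%s=%.2f", names(x$detection_prevalence),
                    x$detection_prevalence), collapse = " "), "\n")
  invisible(x)
}

#' Bagged ensemble of information-gain trees
#'
#' Stratified train/test split (per-class proportions preserved within one
#' record), then `n_bags` unpruned trees fit on bootstrap resamples of the
#' training set; prediction is by majority vote with ties broken by class
#' level order. With `n_bags = 1` and `bootstrap = FALSE` the ensemble
#' reduces to a single tree on the training set. Classes with a single
#' record are kept whole in training with a warning.
#'
#' @param features Data frame of numeric features.
#' @param labels Class labels.
#' @param params List: `train_frac` (default 0.75), `n_bags` (25),
#'   `bootstrap` (TRUE), `min_leaf` (5), `max_depth` (5), `min_gain`
#'   (1e-8), `seed` (1).
#' @return A `bag_ensemble` with the trees, split indices and a held-out
#'   [evaluate_predictions()] report (when the test set is non-empty).
#' @export
bagging_fit <- function(features, labels, params = list()) {
  p <- utils::modifyList(list(train_frac = 0.75, n_bags = 25L,
                              bootstrap = TRUE, min_leaf = 5L,
                              max_depth = 5L, min_gain = 1e-8, seed = 1L),
                         params)
  features <- as.data.frame(features)
  labels <- factor(labels)
  keep <- stats::complete.cases(features) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  n <- nrow(features)
  with_seed(p$seed, {
    train_idx <- integer(0)
    singletons <- character(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) == 1L) {
        singletons <- c(singletons, cl)
        train_idx <- c(train_idx, idx)
      } else {
        k <- max(1L, round(p$train_frac * length(idx)))
        k <- min(k, length(idx))
        train_idx <- c(train_idx, sort(sample(idx, k)))
      }
    }
    if (length(singletons))
      warning(sprintf("class(es) with a single record kept whole in training: %s",
                      paste(singletons, collapse = ", ")))
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_len(n), train_idx)
    Xt <- features[train_idx, , drop = FALSE]
    yt <- labels[train_idx]
    trees <- lapply(seq_len(p$n_bags), function(b) {
      idx <- if (isTRUE(p$bootstrap))
        sample.int(length(train_idx), replace = TRUE)
      else seq_along(train_idx)
      grow_tree(Xt[idx, , drop = FALSE], yt[idx],
                p$min_leaf, p$max_depth, p$min_gain)
    })
    ens <- structure(list(trees = trees, levels = levels(labels),
                          features = names(features),
                          train_idx = train_idx, test_idx = test_idx,
                          params = p, n = n),
                     class = "bag_ensemble")
    if (length(test_idx))
      ens$eval <- evaluate_classifier(ens,
                                      features[test_idx, , drop = FALSE],
                                      labels[test_idx])
    ens
  })
}

#' @export
predict.bag_ensemble <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (tr in object$trees) {
    out <- character(nrow(newdata))
    out <- predict_node(tr, newdata, seq_len(nrow(newdata)), out,
                        object$levels)
    for (cl in object$levels) votes[, cl] <- votes[, cl] + (out == cl)
  }
  # majority vote; ties resolved by class level order via which.max
  factor(object$levels[apply(votes, 1L, which.max)], levels = object$levels)
}

#' @export
print.bag_ensemble <- function(x, ...) {
  cat(sprintf("Bagged ensemble of %d trees, %d classes, %d training records\n",
              length(x$trees), length(x$levels), length(x$train_idx)))
  if (!is.null(x$eval))
    cat(sprintf("held-out accuracy %.3f (n=%d)\n", x$eval$accuracy,
                x$eval$n))
  invisible(x)
}

# serialize a tree to plain nested lists for JSON export
tree_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", class = node$class, prob = node$prob, n = node$n)
  } else {
    list(type = "split", feature = node$feature, threshold = node$threshold,
         n = node$n,
         left = tree_to_list(node$left), right = tree_to_list(node$right))
  }
}
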