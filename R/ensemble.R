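# Tree-ensemble response surfaces mapping the four agricultural inputs
# (N, P2O5, K2O, seed) to each benefit, per planting method, plus the
# derived analyses: permutation variable importance, partial dependence,
# a constrained input-recommendation search, and a mixed-effects
# cross-check of input effects.

predict_fit <- function(fit, newdata) {
  if (inherits(fit, "randomForest")) {
    unname(stats::predict(fit, newdata))
  } else if (inherits(fit, "xgb.Booster")) {
    fn <- attr(fit, "features")
    stats::predict(fit, as.matrix(newdata[, fn, drop = FALSE]))
  } else {
    pd_stop("unsupported model object", "validation_error")
  }
}

fit_one_rf <- function(X, y, params) {
  grid <- expand.grid(mtry = params$mtry_grid, ntree = params$ntree_grid)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    randomForest::randomForest(x = X, y = y, mtry = grid$mtry[i],
                               ntree = grid$ntree[i])
  })
  oob <- vapply(fits, function(f) f$mse[length(f$mse)], numeric(1))
  best <- which.min(oob)
  fit <- fits[[best]]
  attr(fit, "selected") <- grid[best, ]
  fit
}

fit_one_gbm <- function(X, y, params) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xp <- list(objective = "reg:squarederror", eta = params$eta,
             max_depth = params$max_depth, subsample = params$subsample,
             min_child_weight = params$min_child_weight, nthread = 1)
  cv <- xgboost::xgb.cv(params = xp, data = dtrain,
                        nrounds = params$max_rounds,
                        nfold = params$cv_folds,
                        early_stopping_rounds = 20, verbose = 0)
  best_iter <- cv$best_iteration %||% params$max_rounds
  fit <- xgboost::xgb.train(params = xp, data = dtrain, nrounds = best_iter,
                            verbose = 0)
  attr(fit, "features") <- colnames(X)
  fit
}

#' Fit forest and boosted response-surface models for each benefit
#'
#' For one planting method, fits a random forest and a gradient-boosted
#' tree model predicting each benefit from the four inputs. The data are
#' split 3:1 into training and held-out sets; forest hyperparameters
#' (trees, variables per split) are selected by out-of-bag error over a
#' small fixed grid, and the boosting iteration count by internal
#' cross-validation with early stopping. Held-out predictions are retained
#' and scored with [compute_metrics()]. Deterministic given the seed.
#'
#' @param benefit_table A `benefit_table` (from [account_cohort()]).
#' @param method Planting method to model (`"MT"`, `"MD"`, `"MAT"`,
#'   `"MAD"`).
#' @param benefits Benefit columns to model (default all five). A constant
#'   benefit is skipped with a warning.
#' @param inputs Input columns (default N, P2O5, K2O, seed rates).
#' @param params List: `train_frac` (0.75), `ntree_grid` (c(150, 300)),
#'   `mtry_grid` (c(2, 3)), `max_rounds` (250), `cv_folds` (5), `eta`
#'   (0.08), `max_depth` (3), `subsample` (0.8), `min_child_weight` (5).
#' @param seed Integer seed.
#' @return A `benefit_models` object: per-benefit fits (`rf`, `gbm`),
#'   split indices, held-out metrics, and the modelled data subset.
#' @export
fit_benefit_models <- function(benefit_table, method,
                               benefits = .BENEFIT_COLS,
                               inputs = .INPUT_COLS,
                               params = list(), seed = 1L) {
  p <- utils::modifyList(list(train_frac = 0.75, ntree_grid = c(150L, 300L),
                              mtry_grid = c(2L, 3L), max_rounds = 250L,
                              cv_folds = 5L, eta = 0.08, max_depth = 3L,
                              subsample = 0.8, min_child_weight = 5),
                         params)
  if (!(method %in% benefit_table$method))
    pd_stop(sprintf("no records for method '%s'", method),
            "validation_error")
  sub <- benefit_table[benefit_table$method == method, , drop = FALSE]
  if (nrow(sub) < 30L)
    pd_stop("need at least 30 records per method to fit benefit models",
            "validation_error")
  fits <- list()
  with_seed(seed, {
    for (b in benefits) {
      keep <- stats::complete.cases(sub[, c(inputs, b)])
      d <- sub[keep, , drop = FALSE]
      y <- d[[b]]
      if (length(unique(y)) < 2L) {
        warning(sprintf("benefit '%s' is constant for %s; model skipped",
                        b, method))
        next
      }
      n <- nrow(d)
      tr <- sort(sample.int(n, round(p$train_frac * n)))
      te <- setdiff(seq_len(n), tr)
      X <- d[, inputs, drop = FALSE]
      rf <- fit_one_rf(X[tr, , drop = FALSE], y[tr], p)
      gbm <- fit_one_gbm(X[tr, , drop = FALSE], y[tr], p)
      pred_rf <- predict_fit(rf, X[te, , drop = FALSE])
      pred_gbm <- predict_fit(gbm, X[te, , drop = FALSE])
      fits[[b]] <- list(
        rf = rf, gbm = gbm, train_idx = tr, test_idx = te,
        observed_test = y[te], pred_rf = pred_rf, pred_gbm = pred_gbm,
        metrics_rf = compute_metrics(y[te], pred_rf),
        metrics_gbm = compute_metrics(y[te], pred_gbm))
    }
  })
  structure(list(fits = fits, method = method, inputs = inputs,
                 data = sub, params = p, seed = as.integer(seed)),
            class = "benefit_models")
}

#' @export
print.benefit_models <- function(x, ...) {
  cat(sprintf("Benefit response-surface models for %s (n=%d)\n", x$method,
              nrow(x$data)))
  for (b in names(x$fits)) {
    f <- x$fits[[b]]
    cat(sprintf("  %-5s held-out R2: forest %.3f, boosted %.3f (n=%d)\n",
                b, f$metrics_rf$r2, f$metrics_gbm$r2,
                length(f$test_idx)))
  }
  invisible(x)
}

#' Permutation variable importance per benefit
#'
#' For each benefit and model, measures the increase in held-out MSE when
#' one input column is permuted (averaged over `n_perm` permutations),
#' clipped at zero and normalized so the fractions per benefit and model
#' sum to 1. Forest and boosted importances are reported side by side.
#'
#' @param models A `benefit_models` object.
#' @param n_perm Permutations per input (default 5).
#' @param seed Integer seed for the permutations.
#' @return An `importance_profile` data frame: benefit, model, input,
#'   importance, rank.
#' @export
input_importance <- function(models, n_perm = 5L, seed = 1L) {
  inputs <- models$inputs
  rows <- list()
  with_seed(seed, {
    for (b in names(models$fits)) {
      f <- models$fits[[b]]
      d <- models$data[stats::complete.cases(
        models$data[, c(inputs, b)]), , drop = FALSE]
      Xte <- d[f$test_idx, inputs, drop = FALSE]
      yte <- f$observed_test
      for (mod in c("rf", "gbm")) {
        fit <- f[[mod]]
        base_mse <- mean((yte - predict_fit(fit, Xte))^2)
        inc <- vapply(inputs, function(j) {
          delta <- vapply(seq_len(n_perm), function(r) {
            Xp <- Xte
            Xp[[j]] <- Xp[[j]][sample.int(nrow(Xp))]
            mean((yte - predict_fit(fit, Xp))^2) - base_mse
          }, numeric(1))
          max(mean(delta), 0)
        }, numeric(1))
        frac <- if (sum(inc) > 0) inc / sum(inc)
                else rep(1 / length(inputs), length(inputs))
        rows[[length(rows) + 1L]] <- data.frame(
          benefit = b, model = mod, input = inputs,
          importance = unname(frac),
          rank = rank(-frac, ties.method = "first"),
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("importance_profile", "data.frame"))
}

#' @export
print.importance_profile <- function(x, ...) {
  cat("Permutation variable importance (fractions sum to 1 per benefit/model)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Partial dependence of a benefit on one input
#'
#' Classic partial dependence: the input of interest is swept over a grid
#' spanning the observed 5th-95th percentile while the other inputs keep
#' their empirical joint distribution (every data row), and predictions
#' are averaged at each grid point.
#'
#' @param models A `benefit_models` object.
#' @param benefit Benefit to profile.
#' @param input Input to sweep.
#' @param model `"rf"` or `"gbm"`.
#' @param grid_size Number of grid points (default 20).
#' @return A `dependence_curve` data frame with columns `x` (input value)
#'   and `yhat` (mean prediction).
#' @export
partial_dependence <- function(models, benefit, input,
                               model = c("rf", "gbm"), grid_size = 20L) {
  model <- match.arg(model)
  if (!(benefit %in% names(models$fits)))
    pd_stop(sprintf("no fitted model for benefit '%s'", benefit),
            "validation_error")
  if (!(input %in% models$inputs))
    pd_stop(sprintf("unknown input '%s'", input), "validation_error")
  fit <- models$fits[[benefit]][[model]]
  d <- models$data[stats::complete.cases(
    models$data[, c(models$inputs, benefit)]), models$inputs, drop = FALSE]
  qs <- stats::quantile(d[[input]], c(0.05, 0.95), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_size)
  yhat <- vapply(grid, function(g) {
    dd <- d
    dd[[input]] <- g
    mean(predict_fit(fit, dd))
  }, numeric(1))
  structure(data.frame(x = grid, yhat = yhat),
            benefit = benefit, input = input, model = model,
            class = c("dependence_curve", "data.frame"))
}

#' Estimate the maximizing input level from a dependence curve
#'
#' Tree-ensemble dependence curves are step functions around the underlying
#' response, so the raw grid argmax is noisy. The default estimator fits a
#' quadratic to the curve and returns its vertex (clamped to the grid range)
#' whenever the fit is concave, falling back to the raw grid argmax
#' otherwise; with `smooth = FALSE` the raw grid argmax is returned.
#'
#' @param curve A `dependence_curve`.
#' @param smooth Use the concave quadratic-vertex estimator (default TRUE).
#' @return The estimated input value maximizing the benefit.
#' @export
dependence_argmax <- function(curve, smooth = TRUE) {
  raw <- curve$x[which.max(curve$yhat)]
  if (!smooth || nrow(curve) < 4L) return(raw)
  fit <- stats::lm(yhat ~ x + I(x^2), data = curve)
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) return(raw)
  min(max(-b[2] / (2 * b[3]), min(curve$x)), max(curve$x))
}

#' @export
plot.dependence_curve <- function(x, ...) {
  plot(x$x, x$yhat, type = "l",
       xlab = attr(x, "input"), ylab = sprintf("mean predicted %s",
                                               attr(x, "benefit")), ...)
  invisible(x)
}

# best grid index along one coordinate scan: tree surfaces are piecewise
# constant, so the scan is regularized by a concave quadratic fit (vertex
# snapped to the grid) with a plateau-middle fallback
scan_best <- function(g, vals) {
  tol <- 1e-9 * (max(abs(vals)) + 1)
  cand <- which(vals >= max(vals) - tol)
  best <- g[cand[ceiling(length(cand) / 2)]]
  if (length(g) >= 4L) {
    b <- stats::coef(stats::lm(vals ~ g + I(g^2)))
    if (all(is.finite(b)) && b[3] < 0) {
      best <- min(max(-b[2] / (2 * b[3]), g[1]), g[length(g)])
    }
  }
  best
}

# objective closure for the recommendation search
make_objective <- function(models, objective, reference, model) {
  benefits <- names(models$fits)
  predict_vec <- function(x) {
    nd <- as.data.frame(as.list(x))
    vapply(benefits, function(b)
      predict_fit(models$fits[[b]][[model]], nd), numeric(1))
  }
  if (objective == "composite") {
    if (!all(.BENEFIT_COLS %in% benefits))
      pd_stop("composite objective needs fitted models for all five benefits",
              "validation_error")
    if (is.null(reference))
      pd_stop("composite objective needs the full benefit table as reference",
              "validation_error")
    meth <- intersect(.PADDY_METHODS, unique(reference$method))
    mat <- t(vapply(meth, function(m) {
      s <- reference[reference$method == m, .BENEFIT_COLS]
      vapply(s, function(v) mean(v, na.rm = TRUE), numeric(1))
    }, numeric(length(.BENEFIT_COLS))))
    colnames(mat) <- .BENEFIT_COLS
    dm <- decision_matrix(mat, .default_directions(.BENEFIT_COLS))
    geom <- topsis_geometry(dm, entropy_weights(dm))
    function(x) {
      v <- predict_vec(x)[.BENEFIT_COLS]
      list(value = closeness_in_geometry(geom, v), benefits = v)
    }
  } else {
    if (!(objective %in% benefits))
      pd_stop(sprintf("no fitted model for objective benefit '%s'",
                      objective), "validation_error")
    sgn <- if (objective == "ghg") -1 else 1   # emissions are minimized
    function(x) {
      v <- predict_vec(x)
      list(value = sgn * v[[objective]], benefits = v)
    }
  }
}

#' Search for recommended input adjustments
#'
#' Deterministic coordinate-ascent grid search over a constrained input box
#' maximizing either the composite TOPSIS closeness of the predicted
#' benefit vector (scored in the fixed geometry of the cohort's
#' method-mean matrix, GHG as cost) or a single predicted benefit (GHG is
#' minimized, all others maximized). The default constraint box is the
#' observed 5th-95th percentile per input, which forbids extrapolating
#' beyond training support.
#'
#' @param models A `benefit_models` object for the method of interest.
#' @param baseline Baseline input vector; defaults to the method's mean
#'   observed inputs.
#' @param objective `"composite"` or one of the benefit names.
#' @param reference Full `benefit_table` over all methods, required for the
#'   composite objective (supplies the method-mean TOPSIS geometry).
#' @param bands Optional `benefit_bands` for reporting the predicted
#'   composite benefit code before and after.
#' @param constraints Optional named list of `c(lower, upper)` per input.
#' @param grid_size Grid points per input (default 11).
#' @param sweeps Maximum coordinate-ascent sweeps (default 3).
#' @param model `"rf"` or `"gbm"` prediction surface.
#' @return A `recommendation` object: baseline and recommended inputs,
#'   percent changes, predicted benefit vectors and deltas, objective
#'   values, and predicted codes when `bands` is given.
#' @export
recommend_inputs <- function(models, baseline = NULL,
                             objective = "composite", reference = NULL,
                             bands = NULL, constraints = NULL,
                             grid_size = 11L, sweeps = 3L,
                             model = c("rf", "gbm")) {
  model <- match.arg(model)
  inputs <- models$inputs
  d <- models$data[, inputs, drop = FALSE]
  if (is.null(baseline)) baseline <- vapply(d, mean, numeric(1))
  baseline <- baseline[inputs]
  grids <- lapply(stats::setNames(inputs, inputs), function(j) {
    box <- constraints[[j]] %||%
      stats::quantile(d[[j]], c(0.05, 0.95), names = FALSE)
    if (box[1] > box[2])
      pd_stop(sprintf("empty feasible box for input '%s'", j),
              "constraint_error")
    if (box[1] == box[2]) return(box[1])
    unique(sort(c(seq(box[1], box[2], length.out = grid_size),
                  min(max(baseline[[j]], box[1]), box[2]))))
  })
  obj <- make_objective(models, objective, reference, model)
  # start from the (clamped) baseline and sweep coordinates
  x <- vapply(inputs, function(j) {
    g <- grids[[j]]
    g[which.min(abs(g - baseline[[j]]))]
  }, numeric(1))
  cur <- obj(x)
  for (s in seq_len(sweeps)) {
    changed <- FALSE
    for (j in inputs) {
      g <- grids[[j]]
      if (length(g) == 1L) next
      vals <- vapply(g, function(v) {
        xx <- x; xx[[j]] <- v
        obj(xx)$value
      }, numeric(1))
      best <- scan_best(g, vals)
      if (best != x[[j]]) {
        x[[j]] <- best
        cur <- obj(x)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  base_eval <- obj(baseline)
  pct <- 100 * (x - baseline) / ifelse(baseline == 0, NA, baseline)
  out <- list(method = models$method, objective = objective, model = model,
              baseline = baseline, recommended = x, pct_change = pct,
              predicted_baseline = base_eval$benefits,
              predicted_recommended = cur$benefits,
              predicted_delta = cur$benefits - base_eval$benefits,
              objective_baseline = base_eval$value,
              objective_recommended = cur$value,
              grid_size = grid_size)
  if (!is.null(bands)) {
    out$code_baseline <- classify_benefits(base_eval$benefits[.BENEFIT_COLS],
                                           bands)
    out$code_recommended <- classify_benefits(cur$benefits[.BENEFIT_COLS],
                                              bands)
  }
  structure(out, class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("Input recommendation for %s (objective: %s, %s surface)\n",
              x$method, x$objective, x$model))
  df <- data.frame(input = names(x$baseline),
                   baseline = round(x$baseline, 1),
                   recommended = round(x$recommended, 1),
                   pct_change = round(x$pct_change, 1))
  print(df, row.names = FALSE)
  cat("predicted benefit deltas:",
      paste(sprintf("%s %+.3g", names(x$predicted_delta),
                    x$predicted_delta), collapse = ", "), "\n")
  if (!is.null(x$code_baseline))
    cat(sprintf("predicted code: %s -> %s\n", x$code_baseline,
                x$code_recommended))
  invisible(x)
}

#' Mixed-effects cross-check of input effects on a benefit
#'
#' Fits `benefit ~ N + P2O5 + K2O + seed` with a random intercept per
#' planting method, inputs standardized (z-scored) and the response left
#' on its natural scale. Singular random-effect fits fall back to a fixed-
#' effects-only linear model with a warning and are flagged.
#'
#' @param benefit_table A `benefit_table` covering at least two methods.
#' @param benefit Benefit column to model.
#' @param inputs Input columns (default the four rates).
#' @return A `mixed_check`: data frame of fixed-effect estimates with 95%
#'   Wald intervals and p-values, the random-intercept variance, and a
#'   `singular` flag.
#' @export
mixed_effects_check <- function(benefit_table, benefit,
                                inputs = .INPUT_COLS) {
  if (length(unique(benefit_table$method)) < 2L)
    pd_stop("mixed-effects check needs at least 2 methods",
            "validation_error")
  keep <- stats::complete.cases(benefit_table[, c(inputs, benefit,
                                                  "method")])
  d <- benefit_table[keep, , drop = FALSE]
  dz <- d
  for (j in inputs) dz[[paste0(j, "_z")]] <- as.numeric(scale(d[[j]]))
  zs <- paste0(inputs, "_z")
  fml <- stats::as.formula(paste(benefit, "~",
                                 paste(zs, collapse = " + "),
                                 "+ (1 | method)"))
  fit <- lmerTest::lmer(fml, data = dz)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-intercept fit; falling back to fixed effects only")
    fit_lm <- stats::lm(stats::as.formula(
      paste(benefit, "~", paste(zs, collapse = " + "))), data = dz)
    cf <- summary(fit_lm)$coefficients
    ci <- stats::confint(fit_lm)
    est <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p_value = cf[, 4], stringsAsFactors = FALSE)
    ranvar <- NA_real_
  } else {
    cf <- stats::coef(summary(fit))
    ci <- stats::confint(fit, parm = "beta_", method = "Wald")
    est <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p_value = cf[, "Pr(>|t|)"], stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranvar <- vc$vcov[vc$grp == "method"][1]
  }
  est <- est[est$term != "(Intercept)", , drop = FALSE]
  est$term <- sub("_z$", "", est$term)
  rownames(est) <- NULL
  structure(list(benefit = benefit, estimates = est,
                 random_intercept_var = ranvar, singular = singular,
                 n = nrow(d)),
            class = "mixed_check")
}

#' @export
print.mixed_check <- function(x, ...) {
  cat(sprintf("Mixed-effects check for %s (n=%d%s)\n", x$benefit, x$n,
              if (x$singular) ", singular fit: fixed effects only" else ""))
  print(transform(x$estimates, estimate = signif(estimate, 4),
                  ci_low = signif(ci_low, 4), ci_high = signif(ci_high, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  if (!is.na(x$random_intercept_var))
    cat(sprintf("random-intercept variance (method): %.4g\n",
                x$random_intercept_var))
  invisible(x)
}
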