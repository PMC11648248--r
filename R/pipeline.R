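# End-to-end pipeline: generate -> account -> classify -> score -> tree ->
# optimize, writing plain-text artifacts to an output directory. Every
# stochastic stage is seeded from the single pipeline seed, so two runs with
# the same seed and config produce bit-identical files.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

paths_to_df <- function(paths) {
  if (!length(paths)) {
    return(data.frame(path = integer(), conditions = character(),
                      class = character(), prob = numeric(),
                      support = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    cond <- if (nrow(p$conditions))
      paste(sprintf("%s %s %.6g", p$conditions$feature, p$conditions$op,
                    p$conditions$threshold), collapse = " & ")
    else "(root)"
    data.frame(path = i, conditions = cond, class = p$class, prob = p$prob,
               support = p$support, stringsAsFactors = FALSE)
  }))
}

recommendation_to_list <- function(rec) {
  keep <- c("method", "objective", "model", "baseline", "recommended",
            "pct_change", "predicted_baseline", "predicted_recommended",
            "predicted_delta", "objective_baseline",
            "objective_recommended", "code_baseline", "code_recommended")
  out <- unclass(rec)[intersect(keep, names(rec))]
  lapply(out, function(v) if (is.numeric(v) && !is.null(names(v)))
    as.list(v) else v)
}

#' Run the full decision pipeline
#'
#' Generates a synthetic cohort (calibrated so method mean yields hit the
#' published averages), accounts the five benefits, derives bands and
#' composite codes, scores the methods by entropy-weighted TOPSIS, fits the
#' decision tree for one method's benefit codes, fits the benefit response
#' surfaces for one method and searches for an input recommendation. All
#' artifacts are written to `out_dir` as CSV/JSON.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param config Optional `synthetic_config`; defaults to the study
#'   conditions with `seed` as RNG seed.
#' @param coeffs Coefficient table.
#' @param tree_method Method whose benefit codes the tree classifies.
#' @param opt_method Method optimized by the recommendation search.
#' @param tree_params,model_params Stage parameter overrides.
#' @param objective Recommendation objective (default composite TOPSIS).
#' @param grid_size Recommendation grid resolution.
#' @param calibrate Calibrate generator intercepts to the published method
#'   mean yields before generating (default TRUE).
#' @return Invisibly, a list with every intermediate object.
#' @export
run_pipeline <- function(out_dir, seed, config = NULL,
                         coeffs = default_coefficients(),
                         tree_method = "MT", opt_method = "MT",
                         tree_params = list(), model_params = list(),
                         objective = "composite", grid_size = 11L,
                         calibrate = TRUE) {
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config %||% synthetic_config(seed = seed)
  if (isTRUE(calibrate)) cfg <- calibrate_yields(cfg)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  ben <- account_cohort(cohort, coeffs)
  utils::write.csv(as.data.frame(ben), file.path(out_dir, "benefits.csv"),
                   row.names = FALSE)

  bands <- derive_bands(ben)
  write_json_file(list(rule = list(low_mult = bands$low_mult,
                                   high_mult = bands$high_mult),
                       means = as.list(bands$means),
                       low = as.list(bands$low),
                       high = as.list(bands$high)),
                  file.path(out_dir, "bands.json"))

  codes <- classify_benefits(ben, bands)
  coded <- cbind(as.data.frame(ben), code = codes)
  utils::write.csv(coded, file.path(out_dir, "coded.csv"),
                   row.names = FALSE)
  freqs <- code_frequencies(codes, ben$method)

  scores <- score_methods(ben, mode = "method-means")
  write_json_file(list(mode = attr(scores, "mode"),
                       weights = as.list(scores$weights),
                       score = as.list(scores$score),
                       rank = as.list(scores$rank)),
                  file.path(out_dir, "scores.json"))

  sel <- ben$method == tree_method
  tree <- fit_tree(ben[sel, .BENEFIT_COLS],
                   codes[sel],
                   params = utils::modifyList(list(seed = seed + 1L),
                                              tree_params))
  write_json_file(tree_to_list(tree$root), file.path(out_dir, "tree.json"))
  utils::write.csv(paths_to_df(extract_paths(tree)),
                   file.path(out_dir, "paths.csv"), row.names = FALSE)
  tree_eval <- if (length(tree$test_idx)) {
    sub <- ben[sel, , drop = FALSE]
    evaluate_classifier(tree, sub[tree$test_idx, .BENEFIT_COLS],
                        codes[sel][tree$test_idx])
  }

  models <- fit_benefit_models(ben, opt_method, params = model_params,
                               seed = seed + 2L)
  imp <- input_importance(models, seed = seed + 3L)
  utils::write.csv(as.data.frame(imp), file.path(out_dir, "importance.csv"),
                   row.names = FALSE)
  rec <- recommend_inputs(models, objective = objective, reference = ben,
                          bands = bands, grid_size = grid_size)
  write_json_file(recommendation_to_list(rec),
                  file.path(out_dir, "recommendation.json"))
  metrics <- lapply(models$fits, function(f)
    list(rf = unclass(f$metrics_rf), gbm = unclass(f$metrics_gbm)))
  write_json_file(metrics, file.path(out_dir, "metrics.json"))

  invisible(list(config = cfg, cohort = cohort, benefits = ben,
                 bands = bands, codes = codes, frequencies = freqs,
                 scores = scores, tree = tree, tree_eval = tree_eval,
                 models = models, importance = imp,
                 recommendation = rec))
}
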