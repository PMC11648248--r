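#' Model-fit metrics
#'
#' Coefficient of determination, root-mean-square error, relative RMSE and
#' mean absolute error of predictions against observations:
#' \deqn{R^2 = 1 - \sum_i (y_i - y_i')^2 / \sum_i (y_i - \bar y)^2}
#' \deqn{RMSE = \sqrt{\sum_i (y_i - y_i')^2 / n}}
#' \deqn{rRMSE = 100 \cdot RMSE / \bar y}
#' R-squared may be negative for models worse than the observed mean. rRMSE
#' is undefined (NA) when the observed mean is zero, and R-squared is
#' undefined when the observations are all identical.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A `metric_report` list: `r2`, `rmse`, `rrmse` (percent), `mae`,
#'   `n`.
#' @export
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 4))
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    pd_stop("observed and predicted must have equal length",
            "validation_error")
  if (length(observed) < 2L)
    pd_stop("need at least 2 observations", "validation_error")
  if (anyNA(observed) || anyNA(predicted))
    pd_stop("metrics input contains missing values", "validation_error")
  err <- observed - predicted
  sse <- sum(err^2)
  sst <- sum((observed - mean(observed))^2)
  rmse <- sqrt(sse / length(observed))
  ybar <- mean(observed)
  structure(list(
    r2 = if (sst == 0) NA_real_ else 1 - sse / sst,
    rmse = rmse,
    rrmse = if (ybar == 0) NA_real_ else 100 * rmse / ybar,
    mae = mean(abs(err)),
    n = length(observed)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n=%d  R2=%.4f  RMSE=%.4g  rRMSE=%.2f%%  MAE=%.4g\n",
              x$n, x$r2, x$rmse, x$rrmse, x$mae))
  invisible(x)
}
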