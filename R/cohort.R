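# Cohort table: one row per field-season, all quantities per hectare.

#' Validate a cohort of per-field records
#'
#' Checks the mandatory schema (planting method plus nine per-hectare input
#' and yield columns), method codes, and non-negativity of all quantities.
#' A `row_id` column is added when absent and an optional `straw_yield`
#' column is filled with `NA` when missing.
#'
#' @param df A data frame with columns `method`, `n_rate`, `p_rate`,
#'   `k_rate`, `seed_rate`, `herbicide`, `pesticide`, `labor_hours`,
#'   `machine_hours`, `grain_yield` and optionally `straw_yield`, `row_id`.
#' @return The validated data frame, classed `cohort_table`.
#' @export
validate_cohort <- function(df) {
  if (!is.data.frame(df)) pd_stop("cohort must be a data frame", "schema_error")
  missing_cols <- setdiff(.COHORT_COLS, names(df))
  if (length(missing_cols))
    pd_stop(sprintf("missing mandatory column(s): %s",
                    paste(missing_cols, collapse = ", ")), "schema_error")
  df$method <- as.character(df$method)
  bad_m <- which(!(df$method %in% .PADDY_METHODS))
  if (length(bad_m))
    pd_stop(sprintf("unknown method code '%s' on row %d",
                    df$method[bad_m[1]], bad_m[1]), "validation_error")
  if (!("row_id" %in% names(df))) {
    df$row_id <- stats::ave(seq_len(nrow(df)), df$method,
                            FUN = function(i) seq_along(i))
    df$row_id <- paste0(df$method, "-", df$row_id)
  }
  df$row_id <- as.character(df$row_id)
  if (anyDuplicated(df$row_id))
    pd_stop("duplicated row_id in cohort", "validation_error")
  if (!("straw_yield" %in% names(df))) df$straw_yield <- NA_real_
  quant <- setdiff(.COHORT_COLS, "method")
  for (col in quant) {
    v <- df[[col]]
    if (!is.numeric(v))
      pd_stop(sprintf("column '%s' must be numeric", col), "schema_error")
    bad <- which(!is.na(v) & (v < 0 | !is.finite(v)))
    if (length(bad))
      pd_stop(sprintf("negative or non-finite %s on row %s", col,
                      df$row_id[bad[1]]), "validation_error")
    if (anyNA(v))
      pd_stop(sprintf("missing value in mandatory column '%s'", col),
              "validation_error")
  }
  sw <- df$straw_yield
  bad <- which(!is.na(sw) & (sw < 0 | !is.finite(sw)))
  if (length(bad))
    pd_stop(sprintf("negative or non-finite straw_yield on row %s",
                    df$row_id[bad[1]]), "validation_error")
  ord <- c("row_id", .COHORT_COLS, "straw_yield")
  keep_attrs <- attributes(df)[c("seed", "config_hash")]
  df <- df[, c(ord, setdiff(names(df), ord)), drop = FALSE]
  for (a in names(keep_attrs)) {
    if (!is.null(keep_attrs[[a]])) attr(df, a) <- keep_attrs[[a]]
  }
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Read a cohort CSV
#'
#' Expects UTF-8 CSV with a header row naming all mandatory record fields;
#' lines starting with `#` are provenance comments (seed, config hash) and
#' are parsed back into attributes.
#'
#' @param path Path to the CSV file.
#' @return A validated `cohort_table`, row order preserved. Attributes
#'   `seed` and `config_hash` are set when present in the file header.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path))
    pd_stop(sprintf("cohort file not found: %s", path), "io_error")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  meta <- grep("^#", head_lines, value = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- validate_cohort(df)
  pick <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else NULL
  }
  if (!is.null(pick("seed"))) attr(df, "seed") <- as.integer(pick("seed"))
  if (!is.null(pick("config_hash"))) attr(df, "config_hash") <- pick("config_hash")
  df
}

#' Write a cohort CSV with provenance header
#'
#' @param cohort A `cohort_table` (or validatable data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  hdr <- c("# paddyopt cohort")
  if (!is.null(attr(cohort, "seed")))
    hdr <- c(hdr, sprintf("# seed: %d", as.integer(attr(cohort, "seed"))))
  if (!is.null(attr(cohort, "config_hash")))
    hdr <- c(hdr, sprintf("# config_hash: %s", attr(cohort, "config_hash")))
  cnt <- table(factor(cohort$method, levels = .PADDY_METHODS))
  hdr <- c(hdr, sprintf("# counts: %s",
                        paste(sprintf("%s=%d", names(cnt), as.integer(cnt)),
                              collapse = " ")))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(cohort)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "NA")
  invisible(path)
}

#' Per-method record counts of a cohort
#' @param cohort A `cohort_table`.
#' @return Named integer vector over the four planting methods.
#' @export
method_counts <- function(cohort) {
  tab <- table(factor(cohort$method, levels = .PADDY_METHODS))
  stats::setNames(as.integer(tab), names(tab))
}

#' Deterministic 12-row toy cohort
#'
#' Three hand-chosen records per planting method with round-number inputs,
#' used in unit tests and documentation examples. The first mechanical
#' transplanting row applies 136 kg N/ha and yields 10000 kg/ha.
#'
#' @return A `cohort_table` with 12 rows (3 per method).
#' @export
#' @examples
#' make_toy_fixture()
make_toy_fixture <- function() {
  df <- data.frame(
    method = rep(c("MT", "MD", "MAT", "MAD"), each = 3L),
    n_rate = c(136, 150, 120,   125, 140, 110,   140, 160, 120,   200, 220, 180),
    p_rate = c(78.6, 85, 70,    76, 80, 70,      96, 105, 85,     150, 165, 140),
    k_rate = c(143.5, 150, 130, 150, 160, 140,   157, 165, 145,   192, 210, 180),
    seed_rate = c(20.5, 22, 18, 31, 33, 28,      15, 16, 14,      20.5, 22, 19),
    herbicide = c(3, 3, 3,      4, 4, 4,         2, 2, 2,         3, 3, 3),
    pesticide = c(3, 3, 3,      4, 4, 4,         2, 2, 2,         3, 3, 3),
    labor_hours = c(0, 0, 0,    0, 0, 0,         150, 150, 150,   120, 120, 120),
    machine_hours = c(12, 12, 12, 8, 8, 8,       0, 0, 0,         0, 0, 0),
    grain_yield = c(10000, 11000, 9000,
                    9300, 10200, 8400,
                    8800, 9800, 7800,
                    8100, 9000, 7200),
    stringsAsFactors = FALSE
  )
  df$straw_yield <- df$grain_yield
  validate_cohort(df)
}

#' @export
print.cohort_table <- function(x, ...) {
  if (!is.null(x$method)) {
    cnt <- method_counts(x)
    cat(sprintf("Cohort of %d field records (%s)\n", nrow(x),
                paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")))
  }
  NextMethod()
}
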