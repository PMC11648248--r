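# Benefit-interval banding and composite benefit codes.
#
# Bands are multiples of the pooled mean of each indicator: yield has three
# bands (low <= 0.8 x mean < medium < 1.2 x mean <= high) and the other four
# indicators two bands (high at >= 1.2 x mean, low otherwise). The composite
# code concatenates the five band letters in fixed order yield-GHG-EB-PFP-EUE,
# e.g. "HY-LG-HB-HP-HE" is the optimal pattern (high yield, low emissions,
# high economic benefit, high fertilizer productivity, high energy efficiency).

.CODE_LETTERS <- c(yield = "Y", ghg = "G", eb = "B", pfp = "P", eue = "E")

#' Derive benefit bands from pooled means
#'
#' Pooled (all methods together) means are computed per indicator, missing
#' values excluded, and thresholds set at `low_mult` and `high_mult` times
#' the mean. Per-method banding is available via `by = "method"` for
#' sensitivity analysis; the default pools because the published limits are
#' a single set.
#'
#' @param benefit_table Data frame with the five benefit columns (e.g. from
#'   [account_cohort()]).
#' @param low_mult,high_mult Band multipliers (defaults 0.8 and 1.2).
#' @param by `"pooled"` (default) or `"method"`.
#' @return A `benefit_bands` object (or a named list of them for
#'   `by = "method"`), holding means, thresholds and the rule parameters.
#' @export
#' @examples
#' ben <- account_cohort(make_toy_fixture())
#' derive_bands(ben)
derive_bands <- function(benefit_table, low_mult = 0.8, high_mult = 1.2,
                         by = c("pooled", "method")) {
  by <- match.arg(by)
  if (!all(.BENEFIT_COLS %in% names(benefit_table)))
    pd_stop("benefit_table lacks the five benefit columns", "schema_error")
  if (!is_number(low_mult) || !is_number(high_mult) ||
      low_mult <= 0 || high_mult <= low_mult)
    pd_stop("band multipliers must satisfy 0 < low_mult < high_mult",
            "validation_error")
  if (by == "method") {
    out <- lapply(split(benefit_table, benefit_table$method),
                  derive_bands, low_mult = low_mult, high_mult = high_mult)
    return(out)
  }
  means <- vapply(.BENEFIT_COLS, function(col) {
    v <- benefit_table[[col]]
    v <- v[!is.na(v)]
    if (!length(v))
      pd_stop(sprintf("cannot derive bands: indicator '%s' has no values",
                      col), "banding_error")
    mean(v)
  }, numeric(1))
  n_used <- vapply(.BENEFIT_COLS,
                   function(col) sum(!is.na(benefit_table[[col]])),
                   integer(1))
  structure(list(means = means,
                 low = low_mult * means,
                 high = high_mult * means,
                 low_mult = low_mult, high_mult = high_mult,
                 n_used = n_used),
            class = "benefit_bands")
}

#' Assign composite benefit codes
#'
#' Boundary convention mirrors the banding rule text: "high" is inclusive at
#' the upper threshold (value >= high_mult x mean), "low" yield is inclusive
#' at the lower threshold, and medium yield is open on both sides. A missing
#' indicator produces a `?` wildcard in that slot.
#'
#' @param benefits A named benefit vector (from [benefits()]), a one-row
#'   data frame, or a multi-row benefit table for vectorized use.
#' @param bands A `benefit_bands` object.
#' @return Character vector of composite codes such as `"MY-HG-HB-LP-LE"`.
#' @export
classify_benefits <- function(benefits, bands) {
  if (!inherits(bands, "benefit_bands"))
    pd_stop("bands must come from derive_bands()", "validation_error")
  if (is.numeric(benefits)) benefits <- as.data.frame(as.list(benefits))
  get <- function(col) as.numeric(benefits[[col]])
  y <- get("yield")
  yc <- ifelse(is.na(y), "?Y",
        ifelse(y >= bands$high["yield"], "HY",
        ifelse(y <= bands$low["yield"], "LY", "MY")))
  two <- function(col) {
    v <- get(col)
    L <- .CODE_LETTERS[[col]]
    ifelse(is.na(v), paste0("?", L),
           ifelse(v >= bands$high[col], paste0("H", L), paste0("L", L)))
  }
  paste(yc, two("ghg"), two("eb"), two("pfp"), two("eue"), sep = "-")
}

#' Parse a composite benefit code into its five components
#' @param code Character vector of codes like `"HY-HG-HB-HP-LE"`.
#' @return Data frame with one column per indicator slot.
#' @export
parse_code <- function(code) {
  parts <- strsplit(code, "-", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    pd_stop("benefit codes must have five '-'-separated slots",
            "validation_error")
  m <- do.call(rbind, parts)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .BENEFIT_COLS
  out
}

#' Per-method benefit-code frequencies
#'
#' Counts and proportions of each composite code within each planting
#' method. The modal code per method is reported as that method's
#' "conventional benefit" pattern.
#'
#' @param codes Character vector of composite codes.
#' @param methods Parallel vector of planting-method labels.
#' @return A `code_freq` data frame (method, code, n, prop) with a `modal`
#'   attribute naming each method's most frequent code.
#' @export
code_frequencies <- function(codes, methods) {
  if (length(codes) != length(methods))
    pd_stop("codes and methods must have equal length", "validation_error")
  methods <- factor(as.character(methods),
                    levels = intersect(.PADDY_METHODS, unique(methods)))
  tab <- as.data.frame(table(method = methods, code = codes),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$method, sum)
  tab$prop <- tab$n / as.numeric(tot[tab$method])
  tab <- tab[order(match(tab$method, .PADDY_METHODS), -tab$n, tab$code), ]
  rownames(tab) <- NULL
  modal <- vapply(split(tab, tab$method),
                  function(d) d$code[which.max(d$n)], character(1))
  structure(tab, modal = modal[intersect(.PADDY_METHODS, names(modal))],
            class = c("code_freq", "data.frame"))
}

#' @export
print.benefit_bands <- function(x, ...) {
  cat(sprintf("Benefit bands (pooled means x %.2f / %.2f)\n",
              x$low_mult, x$high_mult))
  df <- data.frame(indicator = names(x$means), mean = x$means,
                   low = x$low, high = x$high, n = x$n_used)
  df$rule <- ifelse(df$indicator == "yield",
                    "L <= low < M < high <= H", "H at >= high, else L")
  print(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.code_freq <- function(x, ...) {
  cat("Benefit-code frequencies by planting method\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  modal <- attr(x, "modal")
  cat("modal (conventional) codes:",
      paste(sprintf("%s=%s", names(modal), modal), collapse = ", "), "\n")
  invisible(x)
}
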