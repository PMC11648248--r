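# Published per-method reference summaries for rice planting methods in
# Southwest China (regional meta-analysis of 1722 field-season records:
# MT n=302, MD n=202, MAT n=1079, MAD n=139). These printed summary values
# are inputs to worked examples and qualitative anchors; they are not
# recomputed from raw data by this package.

#' Reference per-method benefit means
#'
#' Mean yield (kg/ha), GHG emissions (kg CO2-eq/ha), economic benefit
#' (CNY/ha), partial fertilizer productivity and energy use efficiency of
#' the four planting methods, as published for the Southwest China
#' meta-dataset.
#'
#' @return A 4 x 5 matrix, methods in rows (MT, MD, MAT, MAD), indicators
#'   in columns (`yield`, `ghg`, `eb`, `pfp`, `eue`).
#' @export
#' @examples
#' reference_means()["MT", "yield"] / reference_means()["MD", "yield"]
reference_means <- function() {
  m <- rbind(
    MT  = c(yield = 10033.2, ghg = 514.61, eb = 20043.3, pfp = 28.51, eue = 14.49),
    MD  = c(yield = 9268.6,  ghg = 490.00, eb = 18834.1, pfp = 26.94, eue = 13.91),
    MAT = c(yield = 8839.7,  ghg = 326.15, eb = 13986.7, pfp = 24.00, eue = 15.90),
    MAD = c(yield = 8135.9,  ghg = 420.45, eb = 12464.9, pfp = 16.39, eue = 11.27)
  )
  m
}

#' Reference comprehensive benefit scores
#'
#' Published entropy-weighted TOPSIS comprehensive-benefit scores of the
#' four planting methods (MT highest).
#'
#' @return Named numeric vector over MT, MD, MAT, MAD.
#' @export
reference_scores <- function() {
  c(MT = 38.51, MD = 35.03, MAT = 18.34, MAD = 14.81)
}

#' Reference pooled band limits
#'
#' The published pooled banding thresholds: the medium-yield range and the
#' lower limits of the high band for GHG emissions, EB, PFP and EUE.
#'
#' @return A list with `medium_yield` (length-2 range), `ghg_high`,
#'   `eb_high`, `pfp_high`, `eue_high`.
#' @export
reference_band_limits <- function() {
  list(medium_yield = c(7227.1, 10840.7),
       ghg_high = 386.04, eb_high = 18567.4,
       pfp_high = 29.29, eue_high = 18.31)
}

#' Reference per-method sample sizes
#' @return Named integer vector over MT, MD, MAT, MAD.
#' @export
reference_sizes <- function() {
  c(MT = 302L, MD = 202L, MAT = 1079L, MAD = 139L)
}
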