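# Per-record benefit accounting from the coefficient table.
#
# Five indicators per field record:
#   yield  grain yield, kg/ha (carried through unchanged)
#   ghg    input-embodied greenhouse-gas emissions, kg CO2-eq/ha: sum(Ri * Di)
#   eb     economic benefit, CNY/ha: grain revenue minus input costs
#   pfp    partial fertilizer productivity: yield / (N + P2O5 + K2O)
#   eue    energy use efficiency: output energy / input energy (MJ/MJ)

# Coerce a possibly partial record (list or 1-row data frame) to a full one.
# Absent input fields count as zero so worked examples like "herbicide only"
# are expressible; method defaults to MT and only matters when labor or
# machinery hours are non-zero.
as_record <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      pd_stop("record must be a single row", "validation_error")
    record <- as.list(record)
  }
  if (!is.list(record)) pd_stop("record must be a list", "validation_error")
  fields <- c(.INPUT_COLS, "herbicide", "pesticide",
              "labor_hours", "machine_hours", "grain_yield")
  out <- list(method = as.character(record$method %||% "MT"))
  for (f in fields) {
    v <- record[[f]] %||% 0
    if (!is_number(v) || v < 0)
      pd_stop(sprintf("field '%s' must be a non-negative number", f),
              "validation_error")
    out[[f]] <- as.numeric(v)
  }
  if (!(out$method %in% .PADDY_METHODS))
    pd_stop(sprintf("unknown method code '%s'", out$method),
            "validation_error")
  sw <- record$straw_yield
  out$straw_yield <- if (is.null(sw) || is.na(sw)) NA_real_ else as.numeric(sw)
  out
}

item_factor <- function(co, item, what) coef_row(co, item)[[what]]

# method-specific labor / machinery item names; NULL when the amount is zero
method_item <- function(co, prefix, method, amount) {
  if (amount <= 0) return(NULL)
  nm <- paste0(prefix, "_", method)
  if (is.na(match(nm, co$items$item)))
    pd_stop(sprintf("no coefficient entry for item '%s'", nm), "lookup_error")
  nm
}

#' Economic output of a record
#'
#' Grain revenue: grain yield times the unit sale price.
#'
#' @param grain_yield Grain yield, kg/ha.
#' @param coeffs A `coeff_table`; supplies the grain price.
#' @return Revenue in CNY/ha.
#' @export
#' @examples
#' economic_output(10000, default_coefficients())  # 27000
economic_output <- function(grain_yield, coeffs = default_coefficients()) {
  if (!is_number(grain_yield) || grain_yield < 0)
    pd_stop("grain_yield must be a non-negative number", "validation_error")
  grain_yield * coeffs$grain_price
}

#' Total input costs of a record
#'
#' Sum over input items of amount times unit cost, using the
#' method-appropriate labor/machinery entries. Labor entries with
#' `cost_basis = "per_ha"` are charged once per hectare-season whenever
#' labor hours are non-zero.
#'
#' @param record Field record (list or 1-row data frame); absent inputs
#'   count as zero.
#' @param coeffs A `coeff_table`.
#' @return Costs in CNY/ha.
#' @export
input_costs <- function(record, coeffs = default_coefficients()) {
  r <- as_record(record)
  total <- 0
  for (it in c(.INPUT_COLS, "herbicide", "pesticide")) {
    total <- total + r[[it]] * item_factor(coeffs, it, "cost")
  }
  mech <- method_item(coeffs, "machinery", r$method, r$machine_hours)
  if (!is.null(mech)) {
    row <- coef_row(coeffs, mech)
    total <- total + if (row$cost_basis == "per_ha") row$cost
                     else r$machine_hours * row$cost
  }
  lab <- method_item(coeffs, "labor", r$method, r$labor_hours)
  if (!is.null(lab)) {
    row <- coef_row(coeffs, lab)
    total <- total + if (row$cost_basis == "per_ha") row$cost
                     else r$labor_hours * row$cost
  }
  total
}

#' Economic benefit (EB) of a record
#'
#' Economic output minus input costs; can be negative.
#'
#' @inheritParams input_costs
#' @return EB in CNY/ha.
#' @export
economic_benefit <- function(record, coeffs = default_coefficients()) {
  r <- as_record(record)
  economic_output(r$grain_yield, coeffs) - input_costs(r, coeffs)
}

#' Input-embodied greenhouse-gas emissions of a record
#'
#' Sum over input items of amount `Ri` times emission factor `Di`, with the
#' method-appropriate machinery/labor factors. Field fluxes (CH4, N2O) are
#' out of scope: only emissions embodied in the inputs are counted.
#'
#' @inheritParams input_costs
#' @return Emissions in kg CO2-eq/ha.
#' @export
#' @examples
#' ghg_emissions(list(n_rate = 136, p_rate = 78.6, k_rate = 143.5))  # 221.22
ghg_emissions <- function(record, coeffs = default_coefficients()) {
  r <- as_record(record)
  total <- 0
  for (it in c(.INPUT_COLS, "herbicide", "pesticide")) {
    total <- total + r[[it]] * item_factor(coeffs, it, "ghg")
  }
  mech <- method_item(coeffs, "machinery", r$method, r$machine_hours)
  if (!is.null(mech)) total <- total + r$machine_hours * coef_row(coeffs, mech)$ghg
  lab <- method_item(coeffs, "labor", r$method, r$labor_hours)
  if (!is.null(lab)) total <- total + r$labor_hours * coef_row(coeffs, lab)$ghg
  total
}

#' Partial fertilizer productivity (PFP)
#'
#' Grain yield per unit total fertilizer mass (N + P2O5 + K2O). Seed does
#' not count toward the denominator. Undefined when no fertilizer was
#' applied; such records are excluded from banding rather than scored zero.
#'
#' @param grain_yield Grain yield, kg/ha.
#' @param record Field record supplying the fertilizer rates.
#' @return Dimensionless PFP.
#' @export
partial_fertilizer_productivity <- function(grain_yield, record) {
  r <- as_record(record)
  denom <- r$n_rate + r$p_rate + r$k_rate
  if (denom <= 0)
    pd_stop("PFP undefined: total fertilizer input is zero",
            "undefined_pfp_error")
  if (!is_number(grain_yield) || grain_yield < 0)
    pd_stop("grain_yield must be a non-negative number", "validation_error")
  grain_yield / denom
}

#' Energy balance of a record
#'
#' Output energy is grain plus straw mass times their energy equivalents;
#' when straw yield is unreported it defaults to grain yield times the
#' table's `straw_to_grain` ratio. Input energy sums every input amount
#' times its energy equivalent, including method-specific labor/machinery.
#'
#' @inheritParams input_costs
#' @return An `energy_balance` list with `energy_in` and `energy_out` (MJ/ha).
#' @export
energy_balance <- function(record, coeffs = default_coefficients()) {
  r <- as_record(record)
  straw <- if (is.na(r$straw_yield)) r$grain_yield * coeffs$straw_to_grain
           else r$straw_yield
  e_out <- r$grain_yield * coeffs$grain_energy + straw * coeffs$straw_energy
  e_in <- 0
  for (it in c(.INPUT_COLS, "herbicide", "pesticide")) {
    e_in <- e_in + r[[it]] * item_factor(coeffs, it, "energy")
  }
  mech <- method_item(coeffs, "machinery", r$method, r$machine_hours)
  if (!is.null(mech)) e_in <- e_in + r$machine_hours * coef_row(coeffs, mech)$energy
  lab <- method_item(coeffs, "labor", r$method, r$labor_hours)
  if (!is.null(lab)) e_in <- e_in + r$labor_hours * coef_row(coeffs, lab)$energy
  structure(list(energy_in = e_in, energy_out = e_out),
            class = "energy_balance")
}

#' Energy use efficiency (EUE)
#'
#' Ratio of total output energy to total input energy. Undefined for zero
#' input energy; such records are excluded from banding.
#'
#' @param bal An `energy_balance`.
#' @return Dimensionless EUE.
#' @export
energy_use_efficiency <- function(bal) {
  if (!inherits(bal, "energy_balance"))
    pd_stop("expected an energy_balance", "validation_error")
  if (bal$energy_in <= 0)
    pd_stop("EUE undefined: input energy is zero", "undefined_eue_error")
  bal$energy_out / bal$energy_in
}

#' Five benefit indicators of a single record
#'
#' Assembles yield, GHG emissions, EB, PFP and EUE. PFP and EUE that are
#' undefined (zero denominator) are carried as `NA` rather than zero.
#'
#' @inheritParams input_costs
#' @return Named numeric vector `c(yield, ghg, eb, pfp, eue)`.
#' @export
#' @examples
#' benefits(make_toy_fixture()[1, ])
benefits <- function(record, coeffs = default_coefficients()) {
  r <- as_record(record)
  pfp <- tryCatch(partial_fertilizer_productivity(r$grain_yield, r),
                  undefined_pfp_error = function(e) NA_real_)
  eue <- tryCatch(energy_use_efficiency(energy_balance(r, coeffs)),
                  undefined_eue_error = function(e) NA_real_)
  c(yield = r$grain_yield,
    ghg = ghg_emissions(r, coeffs),
    eb = economic_benefit(r, coeffs),
    pfp = pfp,
    eue = eue)
}

#' Append the five benefit columns to a cohort
#'
#' Vectorized accounting over a whole cohort; equivalent to calling
#' [benefits()] on each row. Records with zero fertilizer or zero input
#' energy get `NA` PFP/EUE and are counted in the `undefined_pfp` /
#' `undefined_eue` attributes.
#'
#' @param cohort A `cohort_table`.
#' @param coeffs A `coeff_table`.
#' @return The cohort with columns `yield`, `ghg`, `eb`, `pfp`, `eue`
#'   appended (class `benefit_table`).
#' @export
account_cohort <- function(cohort, coeffs = default_coefficients()) {
  cohort <- validate_cohort(cohort)
  if (any(cohort$grain_yield <= 0))
    pd_stop(sprintf("grain_yield must be positive for accounting (row %s)",
                    cohort$row_id[which(cohort$grain_yield <= 0)[1]]),
            "validation_error")
  n <- nrow(cohort)
  cost <- ghg <- e_in <- numeric(n)
  for (it in c(.INPUT_COLS, "herbicide", "pesticide")) {
    amt <- cohort[[it]]
    cost <- cost + amt * item_factor(coeffs, it, "cost")
    ghg  <- ghg  + amt * item_factor(coeffs, it, "ghg")
    e_in <- e_in + amt * item_factor(coeffs, it, "energy")
  }
  for (m in unique(cohort$method)) {
    sel <- cohort$method == m
    mh <- cohort$machine_hours[sel]
    if (any(mh > 0)) {
      row <- coef_row(coeffs, method_item(coeffs, "machinery", m, max(mh)))
      cost[sel] <- cost[sel] + ifelse(mh > 0,
        if (row$cost_basis == "per_ha") row$cost else mh * row$cost, 0)
      ghg[sel]  <- ghg[sel] + mh * row$ghg
      e_in[sel] <- e_in[sel] + mh * row$energy
    }
    lh <- cohort$labor_hours[sel]
    if (any(lh > 0)) {
      row <- coef_row(coeffs, method_item(coeffs, "labor", m, max(lh)))
      cost[sel] <- cost[sel] + ifelse(lh > 0,
        if (row$cost_basis == "per_ha") row$cost else lh * row$cost, 0)
      ghg[sel]  <- ghg[sel] + lh * row$ghg
      e_in[sel] <- e_in[sel] + lh * row$energy
    }
  }
  straw <- ifelse(is.na(cohort$straw_yield),
                  cohort$grain_yield * coeffs$straw_to_grain,
                  cohort$straw_yield)
  e_out <- cohort$grain_yield * coeffs$grain_energy + straw * coeffs$straw_energy
  fert <- cohort$n_rate + cohort$p_rate + cohort$k_rate

  cohort$yield <- cohort$grain_yield
  cohort$ghg <- ghg
  cohort$eb <- cohort$grain_yield * coeffs$grain_price - cost
  cohort$pfp <- ifelse(fert > 0, cohort$grain_yield / fert, NA_real_)
  cohort$eue <- ifelse(e_in > 0, e_out / e_in, NA_real_)
  attr(cohort, "undefined_pfp") <- sum(fert <= 0)
  attr(cohort, "undefined_eue") <- sum(e_in <= 0)
  class(cohort) <- unique(c("benefit_table", class(cohort)))
  cohort
}
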