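#' Default coefficient table for rice input accounting
#'
#' Unit cost (CNY), greenhouse-gas emission factor (kg CO2-eq) and energy
#' equivalent (MJ) for each agricultural input item, together with the grain
#' sale price and grain/straw energy equivalents. These are the published
#' life-cycle coefficients for rice production inputs in Southwest China.
#'
#' Fertilizer, herbicide, pesticide and machinery rows are unambiguous in the
#' published source. The seed and labor rows are typographically uncertain
#' there and ship with defensible defaults (`uncertain = TRUE`): seed
#' 5 CNY/kg, GHG factor 0, 17 MJ/kg; labor 1500 CNY per hectare-season (a flat
#' per-area charge rather than per hour), GHG factor 0, and 14.95 (manual
#' transplanting) or 27.5 (manual direct seeding) MJ/h. Every entry can be
#' overridden through [load_coefficients()].
#'
#' Labor and machinery coefficients are method-specific: items
#' `labor_MAT`/`labor_MAD` apply to `labor_hours` and
#' `machinery_MT`/`machinery_MD` apply to `machine_hours`, selected by the
#' record's planting method.
#'
#' @return An object of class `coeff_table`: a list with elements `items`
#'   (data frame of per-item factors), `grain_price` (CNY/kg), `grain_energy`
#'   (MJ/kg), `straw_energy` (MJ/kg) and `straw_to_grain` (straw mass assumed
#'   per unit grain when straw yield is unreported).
#' @seealso [load_coefficients()], [account_cohort()]
#' @export
#' @examples
#' co <- default_coefficients()
#' co$items[co$items$item == "n_rate", ]
default_coefficients <- function() {
  items <- data.frame(
    item = c("n_rate", "p_rate", "k_rate", "seed_rate",
             "herbicide", "pesticide",
             "labor_MAT", "labor_MAD", "machinery_MT", "machinery_MD"),
    unit = c("kg", "kg", "kg", "kg", "kg", "kg", "h", "h", "h", "h"),
    cost = c(3.8, 1.25, 2, 5, 175, 100, 1500, 1500, 120, 120),
    cost_basis = c(rep("per_unit", 6L), "per_ha", "per_ha",
                   "per_unit", "per_unit"),
    ghg = c(1.3, 0.2, 0.2, 0, 6.30, 5.10, 0, 0, 0.07, 0.07),
    energy = c(60.6, 11.93, 6.7, 17, 238, 199, 14.95, 27.5, 37.5, 34.95),
    uncertain = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(items = items, grain_price = 2.7, grain_energy = 14.7,
         straw_energy = 12.5, straw_to_grain = 1),
    class = "coeff_table"
  )
  validate_coefficients(out)
  out
}

validate_coefficients <- function(co) {
  if (!inherits(co, "coeff_table"))
    pd_stop("not a coeff_table", "validation_error")
  it <- co$items
  need <- c("item", "cost", "cost_basis", "ghg", "energy")
  if (!all(need %in% names(it)))
    pd_stop("coefficient items table lacks required columns",
            "validation_error")
  num <- c(it$cost, it$ghg, it$energy,
           co$grain_price, co$grain_energy, co$straw_energy, co$straw_to_grain)
  if (any(!is.finite(num)) || any(num < 0))
    pd_stop("coefficient factors must be finite and non-negative",
            "validation_error")
  if (co$grain_price <= 0)
    pd_stop("grain_price must be positive", "validation_error")
  if (anyDuplicated(it$item))
    pd_stop("duplicated coefficient item", "validation_error")
  invisible(co)
}

#' Load a coefficient table, optionally overriding packaged defaults
#'
#' Reads a YAML configuration and merges it over [default_coefficients()].
#' Recognized top-level keys: `grain_price`, `grain_energy`, `straw_energy`,
#' `straw_to_grain`, and `items`, a mapping from item name to any of
#' `cost`, `cost_basis`, `ghg`, `energy`. Unmentioned entries keep their
#' defaults, so a config only needs to state what it changes.
#'
#' @param path Path to a YAML file, or `NULL` for the packaged defaults.
#' @param overrides Optional list in the same shape as the YAML contents,
#'   applied after `path` (convenient for programmatic tweaks).
#' @return A validated `coeff_table`.
#' @export
#' @examples
#' co <- load_coefficients(overrides = list(grain_price = 3.0))
#' co$grain_price
load_coefficients <- function(path = NULL, overrides = NULL) {
  co <- default_coefficients()
  apply_cfg <- function(co, cfg) {
    for (key in c("grain_price", "grain_energy", "straw_energy",
                  "straw_to_grain")) {
      if (!is.null(cfg[[key]])) co[[key]] <- as.numeric(cfg[[key]])
    }
    for (nm in names(cfg$items %||% list())) {
      row <- match(nm, co$items$item)
      if (is.na(row)) {  # new item: append with zero defaults
        co$items <- rbind(co$items, data.frame(
          item = nm, unit = cfg$items[[nm]]$unit %||% "kg",
          cost = 0, cost_basis = "per_unit", ghg = 0, energy = 0,
          uncertain = FALSE, stringsAsFactors = FALSE))
        row <- nrow(co$items)
      }
      for (fld in c("cost", "ghg", "energy")) {
        if (!is.null(cfg$items[[nm]][[fld]]))
          co$items[[fld]][row] <- as.numeric(cfg$items[[nm]][[fld]])
      }
      if (!is.null(cfg$items[[nm]]$cost_basis))
        co$items$cost_basis[row] <- as.character(cfg$items[[nm]]$cost_basis)
    }
    co
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      pd_stop(sprintf("coefficient config not found: %s", path), "io_error")
    co <- apply_cfg(co, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) co <- apply_cfg(co, overrides)
  validate_coefficients(co)
  co
}

coef_row <- function(co, item, required = TRUE) {
  i <- match(item, co$items$item)
  if (is.na(i)) {
    if (required)
      pd_stop(sprintf("no coefficient entry for item '%s'", item),
              "lookup_error")
    return(NULL)
  }
  co$items[i, ]
}

#' @export
print.coeff_table <- function(x, ...) {
  cat("Input coefficient table (per-hectare accounting)\n")
  print(x$items[, c("item", "unit", "cost", "cost_basis", "ghg", "energy")],
        row.names = FALSE)
  cat(sprintf("grain price %.2f CNY/kg; grain energy %.2f, straw energy %.2f MJ/kg; straw:grain = %.2f\n",
              x$grain_price, x$grain_energy, x$straw_energy, x$straw_to_grain))
  invisible(x)
}
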