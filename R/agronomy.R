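#' Convert a net-plot mass to a per-hectare rate
#'
#' `mass / net_area * 10000`, the standard plot-to-hectare scaling for yield
#' and biomass recorded on a harvested net plot.
#'
#' @param plot_mass Mass harvested from the net plot (kg).
#' @param net_area Net plot area in m2; default the 1.65 m x 2.5 m = 4.125 m2
#'   net plot of [trial_design()].
#' @return kg per hectare (vectorized).
#' @examples
#' plot_to_hectare(4.125)            # 10000 kg/ha
#' plot_to_hectare(3.3, 4.125)       # 8000 kg/ha
#' @export
plot_to_hectare <- function(plot_mass, net_area = 1.65 * 2.5) {
  if (any(net_area <= 0)) abort("`net_area` must be positive.")
  plot_mass / net_area * 10000
}

#' Standardize grain yield to a reference moisture content
#'
#' Fresh grain mass is corrected to the marketing standard moisture (12.5%
#' for maize) with `gy * (100 - mc) / (100 - standard_mc)`.  The correction
#' is linear and monotone decreasing in the measured moisture.
#'
#' @param gy Grain yield (kg/ha, any mass unit works).
#' @param mc Measured grain moisture content at harvest (%), must be < 100.
#' @param standard_mc Standard moisture (%), default 12.5.
#' @return Moisture-standardized yield in the units of `gy`.
#' @examples
#' adjust_moisture(1000, 20)   # 914.2857
#' adjust_moisture(1000, 12.5) # unchanged
#' @export
adjust_moisture <- function(gy, mc, standard_mc = 12.5) {
  if (any(mc >= 100)) abort("Grain moisture `mc` must be below 100%.")
  gy * (100 - mc) / (100 - standard_mc)
}

#' Downward yield adjustment for farmer conditions
#'
#' Experiment-station yields overstate what farmers harvest; partial-budget
#' practice deducts a fixed fraction (10% by default) before valuing the
#' produce.
#'
#' @param y Yield (any unit).
#' @param fraction Fraction deducted, in `[0, 1)`; default 0.10.
#' @return `y * (1 - fraction)`.
#' @examples
#' farmer_adjust(12130)  # 10917
#' @export
farmer_adjust <- function(y, fraction = 0.10) {
  if (any(fraction < 0) || any(fraction >= 1)) {
    abort("`fraction` must lie in [0, 1).")
  }
  y * (1 - fraction)
}

#' Mass conversion yield of an amendment batch
#'
#' Product mass as a percentage of (air-dry) feedstock mass, e.g. biochar
#' recovered from pyrolysed maize cobs.
#'
#' @param product_mass Mass of finished amendment (kg).
#' @param feedstock_mass Mass of feedstock (kg), > 0.
#' @return Conversion yield in percent.
#' @examples
#' conversion_yield(89.1, 212.34)  # 41.96% (2023 biochar batch)
#' @export
conversion_yield <- function(product_mass, feedstock_mass) {
  if (any(feedstock_mass <= 0)) abort("`feedstock_mass` must be positive.")
  product_mass / feedstock_mass * 100
}

#' Per-tonne production cost of an amendment
#'
#' Sums itemized production costs and divides by the applied amount that the
#' cost basis covers (e.g. total production cost per hectare over the full
#' 8 t/ha biochar rate).  Item totals are taken as given, not recomputed from
#' quantity x unit cost, because recorded totals sometimes embed lump sums.
#'
#' @param cost_items A data frame with a `total_cost` column (see
#'   [reference_cost_items()] for the bundled example).
#' @param applied_total Amendment amount the summed cost covers (t), > 0.
#' @return A tibble with `total_cost` (sum of items) and `unit_cost`
#'   (currency per tonne).
#' @examples
#' bc <- dplyr::filter(reference_cost_items(), amendment == "biochar")
#' amendment_unit_cost(bc, applied_total = 8)
#' @export
amendment_unit_cost <- function(cost_items, applied_total) {
  if (length(applied_total) != 1 || applied_total <= 0) {
    abort("`applied_total` must be a single positive amount (t).")
  }
  if (!"total_cost" %in% names(cost_items) || nrow(cost_items) == 0) {
    abort("`cost_items` must be a non-empty table with a `total_cost` column.")
  }
  if (any(cost_items$total_cost < 0)) abort("Item costs must be non-negative.")
  total <- sum(cost_items$total_cost)
  tibble::tibble(total_cost = total, unit_cost = total / applied_total)
}

#' Nitrogen equivalence of vermicompost
#'
#' Scales the measured total-nitrogen percentage of vermicompost to kg of
#' plant-available nitrogen per tonne: `NEvc = 10 * TN`, the factor 10 being
#' the 100 kg -> 1 t step.
#'
#' @param tn Total nitrogen content of the vermicompost (%), in `[0, 100]`.
#' @return kg N per tonne of vermicompost.
#' @examples
#' vc_nitrogen_equivalence(2.42)  # 24.2 kg N/t
#' @export
vc_nitrogen_equivalence <- function(tn) {
  if (any(tn < 0 | tn > 100)) abort("`tn` must be a percentage in [0, 100].")
  10 * tn
}

#' Lime requirement from exchangeable acidity
#'
#' The Kamprath-style requirement is `lf * exc_ac` in cmol_c/kg, with the
#' lime factor `lf = 1.5` sized to push acidity saturation below the level
#' that harms most crops; a `dose_fraction` of the full rate (25% by default,
#' a common blanket dressing) is applied.  Field practice in the source
#' recommendation reads the cmol_c/kg figure directly as t CaCO3/ha; that
#' numeric-equivalence convention is the default and is announced via a
#' message.  Set `physical = TRUE` to instead convert through soil mass per
#' hectare (depth x bulk density) and the CaCO3 charge-equivalent weight.
#'
#' @param exc_ac Initial exchangeable acidity (H+ + Al3+), cmol_c/kg, >= 0.
#' @param lf Lime factor, default 1.5.
#' @param dose_fraction Fraction of the full requirement applied, in (0, 1];
#'   default 0.25.
#' @param physical If `TRUE`, compute a mass-based rate instead of the
#'   numeric-equivalence convention.
#' @param depth_m Incorporation depth (m), used when `physical = TRUE`.
#' @param bulk_density Soil bulk density (g/cm3), used when `physical = TRUE`.
#' @return A tibble with `full_rate` and `applied_rate` (t CaCO3/ha).
#' @examples
#' lime_requirement(1.68)  # applied_rate 0.63 t/ha
#' @export
lime_requirement <- function(exc_ac, lf = 1.5, dose_fraction = 0.25,
                             physical = FALSE, depth_m = 0.2,
                             bulk_density = 1.41) {
  if (any(exc_ac < 0)) abort("`exc_ac` must be non-negative.")
  if (any(dose_fraction <= 0 | dose_fraction > 1)) {
    abort("`dose_fraction` must lie in (0, 1].")
  }
  lr_cmol <- lf * exc_ac
  if (physical) {
    # cmol_c/kg = 0.01 mol_c/kg; x 50 g CaCO3 per mol charge = 0.5 g CaCO3
    # per kg soil per cmol_c.  Soil mass/ha from incorporation depth x BD.
    soil_t_ha <- depth_m * bulk_density * 10000   # t soil per ha
    full <- lr_cmol * 0.5 * soil_t_ha / 1000      # t CaCO3 per ha
  } else {
    inform(paste("lime_requirement(): using the numeric-equivalence",
                 "convention (cmol_c/kg read as t CaCO3/ha);",
                 "set physical = TRUE for a mass-based conversion."))
    full <- lr_cmol
  }
  tibble::tibble(full_rate = full, applied_rate = dose_fraction * full)
}

#' Percent change between a treated and a reference mean
#'
#' Agronomic reports frequently express the gain of a treatment over the
#' control as a share of the *treated* mean ("the treatment's yield was x%
#' higher"), i.e. `(treated - reference) / treated * 100`, which is bounded
#' above by 100.  That convention is the default; `base = "reference"` gives
#' the conventional reference-denominator change.
#'
#' @param treated Treated mean (non-zero under the default base).
#' @param reference Reference (e.g. control) mean.
#' @param base Denominator: `"treated"` (default) or `"reference"`.
#' @return Percent change (vectorized).
#' @examples
#' percent_increase(12.13, 4.40)    # 63.73
#' percent_increase(12.13, 4.40, base = "reference")  # 175.7
#' @export
percent_increase <- function(treated, reference, base = c("treated", "reference")) {
  base <- match.arg(base)
  den <- if (base == "treated") treated else reference
  if (any(den == 0)) abort("Denominator mean must be non-zero.")
  (treated - reference) / den * 100
}
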