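#' Treatment codebook for the 3 x 3 x 3 fertility trial
#'
#' The 27 treatments cross three nitrogen/phosphorus levels (applied jointly
#' as 0/0, 120/69 or 240/138 kg N / P2O5 per hectare), three biochar rates
#' (0, 4, 8 t/ha) and three vermicompost rates (0, 5.02, 10.04 t/ha).  Every
#' plot additionally receives a uniform lime dressing of 0.63 t CaCO3/ha, so
#' lime is not a design factor.  Treatment ids run T1..T27 with vermicompost
#' varying fastest, then nitrogen/phosphorus, then biochar: T1 is the limed
#' control, T14 is 120/69 N/P2O5 + 4 t biochar + 5.02 t vermicompost.
#'
#' @return A tibble with one row per treatment and columns `treatment`,
#'   `n_rate` (kg N/ha), `p2o5_rate` (kg P2O5/ha), `bc_rate` (t/ha),
#'   `vc_rate` (t/ha), `lime_rate` (t CaCO3/ha).
#' @examples
#' treatment_codebook()
#' dplyr::filter(treatment_codebook(), treatment == "T14")
#' @export
treatment_codebook <- function() {
  np <- c("0" = 0, "120" = 120, "240" = 240)
  p  <- c(0, 69, 138)
  bc <- c(0, 4, 8)
  vc <- c(0, 5.02, 10.04)
  idx <- 0:26
  tibble::tibble(
    treatment = paste0("T", idx + 1L),
    n_rate    = unname(np[idx %% 9L %/% 3L + 1L]),
    p2o5_rate = p[idx %% 9L %/% 3L + 1L],
    bc_rate   = bc[idx %/% 9L + 1L],
    vc_rate   = vc[idx %% 3L + 1L],
    lime_rate = 0.63
  )
}

#' Describe the trial layout
#'
#' Captures the design constants shared by the loader, the generator and the
#' ANOVA: factor levels, block count, season labels, plot geometry and the
#' standard grain moisture.  The net plot defaults to 1.65 m x 2.5 m =
#' 4.125 m2, the area inside the yield-conversion formulas; trial write-ups
#' sometimes quote a smaller nominal net area, so the value is configurable.
#'
#' @param years Season labels, default `c(2023, 2024)`.
#' @param n_blocks Number of replicate blocks, default 3.
#' @param gross_plot_area Gross plot area in m2, default 8.25.
#' @param net_plot_area Harvested net plot area in m2, default 4.125.
#' @param standard_mc Standard grain moisture content (%), default 12.5.
#' @return An object of class `trial_design`.
#' @examples
#' trial_design()
#' @export
trial_design <- function(years = c(2023, 2024), n_blocks = 3,
                         gross_plot_area = 8.25, net_plot_area = 1.65 * 2.5,
                         standard_mc = 12.5) {
  stopifnot(n_blocks >= 1, gross_plot_area > 0)
  if (net_plot_area <= 0 || net_plot_area > gross_plot_area) {
    abort("`net_plot_area` must be positive and no larger than the gross plot area.")
  }
  structure(
    list(
      np_levels = c("0/0", "120/69", "240/138"),
      bc_levels = c(0, 4, 8),
      vc_levels = c(0, 5.02, 10.04),
      years = years,
      n_blocks = as.integer(n_blocks),
      gross_plot_area = gross_plot_area,
      net_plot_area = net_plot_area,
      standard_mc = standard_mc
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> 3x3x3 factorial RCBD\n")
  cat("  N/P2O5 levels :", paste(x$np_levels, collapse = ", "), "kg/ha\n")
  cat("  biochar levels:", paste(x$bc_levels, collapse = ", "), "t/ha\n")
  cat("  vermicompost  :", paste(x$vc_levels, collapse = ", "), "t/ha\n")
  cat("  blocks        :", x$n_blocks, "\n")
  cat("  years         :", paste(x$years, collapse = ", "), "\n")
  cat("  net plot      :", x$net_plot_area, "m2 (gross", x$gross_plot_area, "m2)\n")
  invisible(x)
}

# Attach np/bc/vc design factors to a plot table, from its treatment column.
add_design_factors <- function(records, design = trial_design()) {
  cb <- treatment_codebook()
  cb$np <- factor(paste0(cb$n_rate, "/", cb$p2o5_rate), levels = design$np_levels)
  cb$bc <- factor(cb$bc_rate, levels = design$bc_levels)
  cb$vc <- factor(cb$vc_rate, levels = design$vc_levels)
  dplyr::left_join(records, cb[, c("treatment", "np", "bc", "vc")],
                   by = "treatment")
}
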