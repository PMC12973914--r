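# Bundled summary tables from the reference trial: a two-season 3x3x3
# N/P2O5 x biochar x vermicompost maize experiment on very strongly acidic
# sandy-clay-loam soil in northwestern Ethiopia.  The raw plot data are not
# public; these published treatment-level summaries are what the calibrated
# generator and the worked examples are anchored to.

#' Combined-over-years treatment cell means of the reference trial
#'
#' Mean value of each trait in every N/P2O5 x biochar x vermicompost cell,
#' averaged over the two seasons and three blocks.  Traits: days to 90%
#' physiological maturity (DPM, days), plant height (PH, cm), leaves per
#' plant (NLPP), ear length (EL, cm), ears per plant (ENPP), grains per ear
#' (GNPE), rows per ear (NRPE), thousand-grain weight (TGW, g), biological
#' yield (BY, t/ha) and grain yield (GY, t/ha).
#'
#' @return A tibble with columns `treatment`, `np`, `bc`, `vc` and one column
#'   per trait (27 rows).
#' @seealso [calibrated_spec()], [reference_trait_summary()]
#' @export
reference_cell_means <- function() {
  # Cell order: np slowest, then bc, then vc (vc fastest).
  g <- tidyr::expand_grid(np = c("0/0", "120/69", "240/138"),
                          bc = c(0, 4, 8),
                          vc = c(0, 5.02, 10.04))
  g$DPM <- c(142.11, 147.64, 149.24, 155.46, 156.18, 157.51, 162.41, 163.28,
             164.19, 150.05, 151.27, 153.28, 158.33, 158.68, 159.37, 165.20,
             166.83, 167.48, 154.55, 154.79, 155.32, 159.95, 160.99, 161.91,
             169.45, 171.61, 174.73)
  g$PH <- c(225.7, 248.1, 255.1, 281.3, 258.9, 260.7, 303.9, 271.3, 268.3,
            257.2, 270.7, 295.9, 289.5, 280.4, 309.9, 291.3, 274.3, 277.1,
            281.3, 299.3, 320.5, 255.7, 286.6, 307.2, 243.4, 263.0, 287.5)
  g$NLPP <- c(13.63, 15.08, 15.40, 15.20, 14.89, 15.15, 15.16, 14.70, 15.92,
              15.79, 16.89, 16.79, 15.54, 16.33, 16.15, 15.28, 16.13, 17.45,
              16.03, 16.27, 17.12, 15.96, 17.17, 15.06, 16.74, 16.48, 15.92)
  g$EL <- c(12.66, 14.28, 15.13, 14.45, 14.09, 16.19, 15.28, 15.13, 15.82,
            16.01, 16.21, 17.38, 16.77, 19.03, 18.51, 16.71, 18.32, 18.31,
            17.75, 19.09, 16.44, 17.76, 18.75, 18.50, 17.56, 20.39, 19.73)
  g$ENPP <- c(0.83, 0.94, 1.00, 1.00, 1.22, 1.23, 1.14, 1.23, 1.32,
              1.03, 1.08, 1.12, 1.27, 1.29, 1.34, 1.43, 1.46, 1.54,
              1.11, 1.16, 1.18, 1.36, 1.39, 1.47, 1.63, 1.36, 1.38)
  g$GNPE <- c(342.31, 503.17, 535.03, 489.37, 498.40, 514.20, 535.26, 541.26,
              552.71, 519.07, 555.17, 571.38, 558.03, 647.11, 609.27, 571.47,
              613.61, 630.25, 515.52, 580.23, 600.65, 564.17, 568.04, 599.52,
              603.55, 620.71, 607.38)
  g$NRPE <- c(8.81, 11.37, 12.77, 11.82, 13.03, 13.39, 11.99, 12.53, 12.44,
              12.87, 14.96, 13.80, 13.97, 14.28, 14.06, 12.45, 12.96, 13.58,
              12.94, 14.03, 15.03, 13.71, 14.43, 14.90, 13.85, 13.53, 13.11)
  g$TGW <- c(234.57, 302.61, 308.33, 311.51, 292.70, 357.09, 285.03, 304.65,
             322.20, 314.40, 346.10, 382.19, 377.95, 400.40, 425.18, 336.89,
             351.01, 407.74, 327.86, 360.51, 407.77, 356.98, 344.16, 399.86,
             388.37, 360.76, 373.57)
  # BY/GY published per treatment id (vc fastest, then np, then bc).
  by_t <- c(13.22, 15.93, 17.58, 17.23, 18.47, 18.95, 18.34, 19.94, 20.40,
            20.76, 21.31, 21.66, 22.01, 26.06, 25.19, 22.90, 23.42, 23.52,
            24.08, 21.88, 21.97, 23.10, 24.10, 26.53, 27.87, 26.66, 25.86)
  gy_t <- c(4.40, 6.59, 7.16, 7.59, 8.57, 8.50, 8.55, 9.86, 10.21,
            7.93, 8.24, 10.07, 10.37, 12.09, 11.15, 11.50, 11.72, 11.24,
            7.59, 8.07, 9.47, 9.14, 10.77, 12.13, 9.34, 9.06, 8.57)
  cb <- treatment_codebook()
  cb$np <- paste0(cb$n_rate, "/", cb$p2o5_rate)
  cb$BY <- by_t
  cb$GY <- gy_t
  out <- dplyr::left_join(
    g, cb[, c("np", "bc_rate", "vc_rate", "treatment", "BY", "GY")],
    by = c(np = "np", bc = "bc_rate", vc = "vc_rate")
  )
  dplyr::select(out, "treatment", "np", "bc", "vc", dplyr::all_of(.trait_vocab))
}

#' Whole-trial summary statistics of the reference trial
#'
#' Grand (pooled) mean and residual coefficient of variation per trait from
#' the combined-over-years analysis, plus per-year means where published
#' (grain and biological yield only).
#'
#' @return A tibble with columns `trait`, `grand_mean`, `cv` (%),
#'   `mean_2023`, `mean_2024` (NA when not published).
#' @export
reference_trait_summary <- function() {
  tibble::tibble(
    trait = .trait_vocab,
    grand_mean = c(158.95, 276.48, 15.86, 16.90, 1.24, 561.24, 13.29,
                   347.42, 21.82, 9.258),
    cv = c(0.34, 1.18, 1.35, 2.76, 3.33, 1.46, 2.89, 1.94, 1.203, 4.296),
    mean_2023 = c(rep(NA_real_, 8), 22.278, 9.34),
    mean_2024 = c(rep(NA_real_, 8), 21.35, 9.17)
  )
}

#' Input and output prices of the reference trial
#'
#' Market prices used in the partial-budget analysis, by season and as the
#' published two-year mean, in Ethiopian Birr (ETB) per the stated unit.
#'
#' @return A tibble with columns `item`, `unit`, `price_2023`, `price_2024`,
#'   `price_mean`.
#' @seealso [check_price_table()]
#' @export
reference_prices <- function() {
  tibble::tribble(
    ~item,          ~unit,            ~price_2023, ~price_2024, ~price_mean,
    "urea",         "100 kg",         8589.98,     4060.00,     6324.99,
    "npsb",         "100 kg",         10000.00,    4100.00,     7200.00,
    "biochar",      "kg",             10.20,       0.12,        5.16,
    "vermicompost", "kg",             3.80,        0.46,        2.13,
    "lime",         "100 kg",         654.58,      654.58,      654.58,
    "seed",         "kg",             88.00,       56.00,       72.00,
    "labor",        "person-day",     200.00,      250.00,      225.00,
    "grain",        "kg",             27.22,       28.45,       27.83,
    "straw",        "kg",             4.30,        4.56,        4.40
  )
}

#' Check a price table for internal consistency
#'
#' Flags items whose published mean price departs from the arithmetic mean
#' of the yearly prices by more than `tolerance` (ETB).  Published tables
#' occasionally carry such slips; they are reported, never silently fixed.
#'
#' @param prices A tibble like [reference_prices()].
#' @param tolerance Allowed absolute deviation, default 0.01.
#' @return `prices` with added `implied_mean` and `consistent` columns.
#' @export
check_price_table <- function(prices, tolerance = 0.01) {
  out <- dplyr::mutate(prices,
    implied_mean = (.data$price_2023 + .data$price_2024) / 2,
    consistent = abs(.data$implied_mean - .data$price_mean) <= tolerance
  )
  if (any(!out$consistent)) {
    warn(paste0("Mean price inconsistent with yearly prices for: ",
                paste(out$item[!out$consistent], collapse = ", ")))
  }
  out
}

#' Itemized amendment production costs of the reference trial
#'
#' Per-hectare production cost items for maize-cob biochar (8 t/ha basis)
#' and vermicompost (10.04 t/ha basis), in ETB.  Quantities in "quintal" use
#' the local quintal, which differs from the 100 kg metric quintal (1 local
#' quintal of dry maize cob weighs about 38.86 kg); item totals are recorded
#' as billed and are not recomputed from quantity x unit cost.
#'
#' @return A tibble with columns `amendment`, `activity`, `unit`, `quantity`,
#'   `unit_cost`, `total_cost`.
#' @export
reference_cost_items <- function() {
  tibble::tribble(
    ~amendment,     ~activity,                              ~unit,         ~quantity, ~unit_cost, ~total_cost,
    "biochar",      "Maize cob collection",                 "quintal",     188.92,    200.00,     37784.00,
    "biochar",      "Transportation",                       "quintal",     188.92,    5.00,       944.60,
    "biochar",      "Pyrolysis labor",                      "person-day",  4,         225.00,     900.00,
    "biochar",      "Quenching with water",                 "liter",       200,       1.75,       351.00,
    "biochar",      "Sieving and packaging",                "person-day",  4,         225.00,     900.00,
    "biochar",      "Tools",                                NA,            NA,        NA,         400.00,
    "vermicompost", "Collection of organic materials",      "quintal",     482.65,    20.59,      9937.76,
    "vermicompost", "Preparation of raw materials",         "quintal",     482.65,    10.00,      4820.00,
    "vermicompost", "Construction of earthworm bins",       "person-day",  2,         225.00,     450.00,
    "vermicompost", "Purchase or maintenance of earthworms","kg",          3,         234.14,     702.43,
    "vermicompost", "Moisture and temperature control",     "person-day",  10,        225.00,     2250.00,
    "vermicompost", "Mixing during composting",             NA,            NA,        NA,         400.00,
    "vermicompost", "Sieving and packaging",                "person-day",  4,         225.00,     900.00,
    "vermicompost", "Transportation",                       "quintal",     482.65,    4.00,       1928.00
  )
}

#' Soil and amendment characterization of the reference site
#'
#' Pre-experiment topsoil chemistry and the nutrient content of the produced
#' amendments.  The exchangeable acidity (1.68 cmol_c/kg) is the basis of
#' the uniform lime dressing; the vermicompost total nitrogen (mean 2.42%)
#' feeds the nitrogen-equivalence calculation.
#'
#' @return A list with `soil` (tibble parameter/value) and `amendments`
#'   (tibble: kind, year, ph, oc, tn, avp).
#' @export
reference_site <- function() {
  list(
    soil = tibble::tribble(
      ~parameter,      ~value,
      "ph",            4.94,
      "exc_ac",        1.68,
      "exc_h",         0.88,
      "exc_al",        0.80,
      "oc",            2.11,
      "tn",            0.25,
      "avp",           11.69,
      "bulk_density",  1.41
    ),
    amendments = tibble::tribble(
      ~kind,          ~year,  ~ph,   ~oc,   ~tn,  ~avp,
      "vermicompost", "2023", 7.78,  8.29,  2.16, 46.71,
      "vermicompost", "2024", 7.82,  13.56, 2.68, 49.89,
      "vermicompost", "mean", 7.80,  10.90, 2.42, 48.30,
      "biochar",      "2023", 10.14, 65.46, 0.36, 44.71,
      "biochar",      "2024", 9.63,  63.78, 1.86, 48.36,
      "biochar",      "mean", 9.88,  64.62, 1.11, 46.50
    )
  )
}

#' Biochar production batches of the reference trial
#'
#' Air-dry feedstock and finished biochar mass of the two annual pyrolysis
#' batches, used for conversion-yield accounting.
#'
#' @return A tibble with columns `year`, `feedstock_kg`, `product_kg`.
#' @export
reference_biochar_batches <- function() {
  tibble::tibble(
    year = c(2023, 2024),
    feedstock_kg = c(212.34, 208.49),
    product_kg = c(89.1, 89.1)
  )
}

#' Published partial-budget table of the reference trial
#'
#' The treatment-level partial budget as published: adjusted grain and straw
#' yields (kg/ha), gross benefit, mean total variable cost and net benefit
#' (ETB/ha), the published marginal rate of return (%) and dominance marker.
#' Rows are in ascending total-variable-cost order.  The published gross and
#' net benefits are not exactly reproducible from the published yields and
#' prices (intermediate rounding in the source); analyses that start from
#' this table therefore take `nb` and `tvc` as given.
#'
#' @return A tibble with columns `treatment`, `agy`, `asy`, `gb`, `tvc`,
#'   `nb`, `mrr_published`, `dominated_published`.
#' @seealso [dominance_analysis()], [marginal_rate_of_return()]
#' @export
reference_budget <- function() {
  tibble::tribble(
    ~treatment, ~agy,     ~asy,     ~gb,       ~tvc,      ~nb,       ~mrr_published, ~dominated_published,
    "T1",       4170.68,  8211.00,  156473.24, 22694.20,  128546.20, NA,        FALSE,
    "T10",      7570.42,  11660.83, 262077.38, 44094.20,  216834.10, 413,       FALSE,
    "T2",       6279.72,  9074.97,  215815.68, 46225.05,  167288.50, -2325.16,  TRUE,
    "T4",       7219.90,  9447.00,  241732.76, 48549.72,  192486.65, -546.46,   TRUE,
    "T19",      7242.75,  14221.07, 269492.52, 65444.20,  197914.70, -88.66,    TRUE,
    "T11",      7870.17,  11884.67, 269138.39, 67625.05,  202630.25, -60.36,    TRUE,
    "T3",       6835.23,  10034.25, 239638.82, 69755.90,  163503.90, -207.8,    TRUE,
    "T13",      9893.83,  11437.23, 326018.82, 69949.72,  254047.30, 143.93,    FALSE,
    "T5",       8192.47,  9656.63,  270944.29, 72080.57,  197037.80, -2675.43,  TRUE,
    "T7",       8125.35,  9725.52,  265101.37, 73205.16,  193957.95, -1845.81,  TRUE,
    "T20",      7708.90,  11540.57, 268727.13, 88975.05,  175104.95, -413.93,   TRUE,
    "T12",      9605.55,  11430.43, 294839.88, 91155.90,  224789.70, -137.97,   TRUE,
    "T22",      8726.05,  12025.77, 293950.73, 91299.72,  202984.45, -239.17,   TRUE,
    "T14",      11566.85, 14102.17, 376565.94, 93480.57,  289124.10, 149.067,   FALSE,
    "T16",      10978.55, 11437.55, 349927.50, 94605.16,  259307.25, -2651.35,  TRUE,
    "T6",       8105.05,  10277.20, 269576.53, 95611.42,  173719.90, -11468.6,  TRUE,
    "T8",       9424.77,  10038.48, 302354.54, 96736.01,  208110.55, -2488.36,  TRUE,
    "T17",      11169.63, 11912.87, 353117.83, 110153.01, 251050.60, -228.36,   TRUE,
    "T21",      9044.20,  10830.47, 295056.13, 112505.90, 185156.65, -546.47,   TRUE,
    "T23",      10290.42, 11969.65, 339147.26, 114830.57, 222452.15, -312.28,   TRUE,
    "T25",      8927.22,  14624.85, 312246.75, 115955.16, 195766.00, -415.39,   TRUE,
    "T15",      10654.92, 14007.10, 354327.23, 117011.42, 239743.25, -209.86,   TRUE,
    "T9",       9771.08,  10063.78, 314128.63, 120266.86, 194325.90, -353.91,   TRUE,
    "T24",      11536.00, 14064.73, 368168.20, 138361.42, 242439.75, -104.02,   TRUE,
    "T26",      8656.50,  14669.63, 305812.28, 139486.01, 164878.15, -270.07,   TRUE,
    "T18",      10747.90, 11706.55, 348612.70, 141666.85, 207248.25, -169.92,   TRUE,
    "T27",      8182.93,  14648.36, 294412.60, 163016.85, 128118.10, -231.54,   TRUE
  )
}
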