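#' Gross field benefit
#'
#' Values the adjusted grain and straw yields at field prices:
#' `agy * grain_price + asy * straw_price`.
#'
#' @param agy Adjusted grain yield (kg/ha), >= 0.
#' @param asy Adjusted straw yield (kg/ha), >= 0.
#' @param grain_price,straw_price Prices (currency per kg), > 0.
#' @return Gross benefit (currency/ha), vectorized.
#' @examples
#' gross_benefit(1000, 0, grain_price = 27.83, straw_price = 4.40)  # 27830
#' @export
gross_benefit <- function(agy, asy, grain_price, straw_price) {
  if (any(agy < 0) || any(asy < 0)) abort("Yields must be non-negative.")
  if (any(grain_price <= 0) || any(straw_price <= 0)) {
    abort("Prices must be positive.")
  }
  agy * grain_price + asy * straw_price
}

#' Total variable cost of a treatment
#'
#' Sums the treatment-specific input costs (rate x unit price for nitrogen,
#' P2O5, biochar, vermicompost and lime) plus any treatment-specific labor,
#' on top of a base cost common to all plots.  The limed control therefore
#' carries the lime cost and base labor only.
#'
#' @param treatments A tibble like [treatment_codebook()] (columns `n_rate`,
#'   `p2o5_rate`, `bc_rate`, `vc_rate`, `lime_rate`).
#' @param unit_prices Named vector of prices per unit of each rate column:
#'   `n` (per kg N), `p2o5` (per kg P2O5), `bc` (per t), `vc` (per t),
#'   `lime` (per t).  A missing price for an applied input is an error.
#' @param base_cost Cost common to every treatment (seed, base labor),
#'   currency/ha.
#' @param labor A function of the treatment row returning extra labor cost,
#'   or a numeric vector (one per treatment), or `NULL`.
#' @return The input tibble with a `tvc` column appended.
#' @examples
#' total_variable_cost(treatment_codebook(),
#'   c(n = 50, p2o5 = 40, bc = 5160, vc = 2130.3, lime = 6545.8))
#' @export
total_variable_cost <- function(treatments, unit_prices, base_cost = 0,
                                labor = NULL) {
  rate_cols <- c(n = "n_rate", p2o5 = "p2o5_rate", bc = "bc_rate",
                 vc = "vc_rate", lime = "lime_rate")
  used <- names(rate_cols)[vapply(rate_cols, function(col)
    any(treatments[[col]] > 0), logical(1))]
  missing_price <- setdiff(used, names(unit_prices))
  if (length(missing_price)) {
    abort(paste0("Missing unit price for applied input(s): ",
                 paste(missing_price, collapse = ", ")))
  }
  cost <- rep(base_cost, nrow(treatments))
  for (inp in used) {
    cost <- cost + treatments[[rate_cols[inp]]] * unit_prices[[inp]]
  }
  if (is.function(labor)) {
    cost <- cost + vapply(seq_len(nrow(treatments)),
                          function(i) labor(treatments[i, ]), numeric(1))
  } else if (is.numeric(labor)) {
    cost <- cost + labor
  }
  dplyr::mutate(treatments, tvc = cost)
}

#' Dominance analysis
#'
#' Orders treatments by total variable cost and flags as dominated every
#' treatment for which some cheaper (or equally cheap) treatment achieves at
#' least the same net benefit; the undominated treatments form the strictly
#' increasing net-benefit frontier.  Ties in both TVC and NB keep the first
#' row (by sort order) undominated.  The result is invariant to input row
#' order and idempotent.
#'
#' @param rows A tibble with at least `treatment`, `tvc`, `nb`.
#' @return The rows sorted by ascending `tvc` with a logical `dominated`
#'   column.
#' @examples
#' dominance_analysis(reference_budget())
#' @export
dominance_analysis <- function(rows) {
  if (!all(c("tvc", "nb") %in% names(rows))) {
    abort("`rows` must have `tvc` and `nb` columns.")
  }
  # arrange() is stable, so exact (tvc, nb) ties keep input order and the
  # later duplicate is the one flagged dominated.
  out <- dplyr::arrange(rows, .data$tvc, dplyr::desc(.data$nb))
  run_max <- cummax(c(-Inf, head(out$nb, -1)))
  out$dominated <- out$nb <= run_max
  out
}

#' Marginal rate of return along the net-benefit frontier
#'
#' For each treatment, the incremental net benefit per unit incremental cost
#' relative to its reference treatment, as a percentage:
#' `(NB - NB_ref) / (TVC - TVC_ref) * 100`.  Under the default
#' `reference = "undominated"` rule the reference is the nearest undominated
#' treatment with strictly lower TVC — the frontier step actually available
#' to a farmer; `reference = "immediate"` instead uses the immediate
#' predecessor in TVC order.  The cheapest treatment is the base and gets no
#' MRR.
#'
#' @param rows Output of [dominance_analysis()] (or a tibble with
#'   `treatment`, `tvc`, `nb`; dominance is computed if absent).
#' @param reference `"undominated"` (default) or `"immediate"`.
#' @return The rows with an `mrr` column (% per ETB step); `NA` for the base
#'   row and for zero-TVC steps (flagged with a warning).
#' @examples
#' marginal_rate_of_return(dominance_analysis(reference_budget()))
#' @export
marginal_rate_of_return <- function(rows,
                                    reference = c("undominated", "immediate")) {
  reference <- match.arg(reference)
  if (!"dominated" %in% names(rows)) rows <- dominance_analysis(rows)
  out <- dplyr::arrange(rows, .data$tvc, dplyr::desc(.data$nb))
  n <- nrow(out)
  mrr <- rep(NA_real_, n)
  for (i in seq_len(n)[-1]) {
    cand <- if (reference == "undominated") {
      which(!out$dominated[1:(i - 1)] & out$tvc[1:(i - 1)] < out$tvc[i])
    } else {
      which(out$tvc[1:(i - 1)] < out$tvc[i])
    }
    if (!length(cand)) {
      # happens only when all cheaper-or-equal rows tie this row's TVC
      warn(paste0("Zero TVC difference for ", out$treatment[i],
                  ": MRR undefined."))
      next
    }
    ref <- max(cand)
    mrr[i] <- (out$nb[i] - out$nb[ref]) / (out$tvc[i] - out$tvc[ref]) * 100
  }
  out$mrr <- mrr
  out
}

#' Recommend a treatment at a minimum acceptable rate of return
#'
#' Among undominated treatments whose marginal rate of return meets the
#' minimum acceptable rate of return (MARR), recommends the one with the
#' highest net benefit; ties go to the lower total variable cost.  If no
#' step qualifies, the base (cheapest) treatment is returned with a warning.
#'
#' @param rows Output of [marginal_rate_of_return()].
#' @param marr_threshold Minimum acceptable rate of return (%), default 100.
#' @return A list with `recommended` (treatment id), `qualifying` (ids of
#'   all undominated treatments meeting the MARR) and `rows` (the input).
#' @examples
#' recommend_treatment(marginal_rate_of_return(reference_budget()))
#' @export
recommend_treatment <- function(rows, marr_threshold = 100) {
  if (marr_threshold <= 0) abort("`marr_threshold` must be positive.")
  if (!"mrr" %in% names(rows)) rows <- marginal_rate_of_return(rows)
  qual <- dplyr::filter(rows, !.data$dominated, !is.na(.data$mrr),
                        .data$mrr >= marr_threshold)
  if (nrow(qual) == 0) {
    base <- rows$treatment[which.min(rows$tvc)]
    warn(paste0("No treatment reaches the MARR of ", marr_threshold,
                "%; falling back to the base treatment ", base, "."))
    return(list(recommended = base, qualifying = character(0), rows = rows))
  }
  pick <- dplyr::arrange(qual, dplyr::desc(.data$nb), .data$tvc)
  list(recommended = pick$treatment[1], qualifying = qual$treatment,
       rows = rows)
}

#' Full partial-budget pipeline from treatment means
#'
#' Assembles the complete partial budget from combined-over-years treatment
#' means of grain and biological yield: straw yield as biological minus
#' grain yield, the downward farmer adjustment (10% by default) on both,
#' gross benefit at field prices, net benefit over total variable cost, then
#' dominance analysis, marginal rates of return and the MARR recommendation.
#'
#' @param means A tibble with `treatment`, `gy`, `by` columns (t/ha,
#'   combined-over-years means).
#' @param tvc A tibble with `treatment` and `tvc` (currency/ha), e.g. from
#'   [total_variable_cost()].
#' @param grain_price,straw_price Field prices (currency per kg).
#' @param adjustment_fraction Farmer-adjustment fraction, default 0.10.
#' @param marr_threshold Minimum acceptable rate of return (%), default 100.
#' @param reference MRR reference rule, see [marginal_rate_of_return()].
#' @return An object of class `trial_budget`: the budget tibble (columns
#'   `treatment`, `agy`, `asy`, `gb`, `tvc`, `nb`, `dominated`, `mrr`) with
#'   the recommendation in attributes `recommended` and `qualifying`.
#' @examples
#' cells <- reference_cell_means()
#' tvc <- dplyr::select(reference_budget(), treatment, tvc)
#' bud <- build_budget(dplyr::tibble(treatment = cells$treatment,
#'                                   gy = cells$GY, by = cells$BY),
#'                     tvc, grain_price = 27.83, straw_price = 4.40)
#' attr(bud, "recommended")
#' @export
build_budget <- function(means, tvc, grain_price, straw_price,
                         adjustment_fraction = 0.10, marr_threshold = 100,
                         reference = c("undominated", "immediate")) {
  reference <- match.arg(reference)
  need <- c("treatment", "gy", "by")
  if (!all(need %in% names(means))) {
    abort("`means` must have treatment, gy and by columns (t/ha).")
  }
  if (nrow(means) == 0) abort("Empty treatment set.")
  if (any(means$by < means$gy)) {
    abort("Biological yield below grain yield: straw yield would be negative.")
  }
  rows <- means |>
    dplyr::transmute(
      treatment = .data$treatment,
      agy = farmer_adjust(.data$gy * 1000, adjustment_fraction),
      asy = farmer_adjust((.data$by - .data$gy) * 1000, adjustment_fraction)
    ) |>
    dplyr::left_join(tvc[, c("treatment", "tvc")], by = "treatment")
  if (anyNA(rows$tvc)) {
    abort(paste0("Missing TVC for treatment(s): ",
                 paste(rows$treatment[is.na(rows$tvc)], collapse = ", ")))
  }
  rows$gb <- gross_benefit(rows$agy, rows$asy, grain_price, straw_price)
  rows$nb <- rows$gb - rows$tvc
  rows <- marginal_rate_of_return(dominance_analysis(rows),
                                  reference = reference)
  rec <- recommend_treatment(rows, marr_threshold)
  structure(rows, recommended = rec$recommended,
            qualifying = rec$qualifying,
            class = c("trial_budget", class(rows)))
}

#' @export
print.trial_budget <- function(x, ...) {
  NextMethod()
  cat("Recommended:", attr(x, "recommended"),
      " (qualifying:", paste(attr(x, "qualifying"), collapse = ", "), ")\n")
  invisible(x)
}

#' Round a budget table for display
#'
#' Reporting helper: rounds monetary columns to 2 decimals (half-up at the
#' printed precision) and optionally the MRR to whole percent, leaving the
#' underlying full-precision table untouched.
#'
#' @param budget A budget tibble.
#' @param mrr_digits Decimals for the MRR column (0 reproduces whole-percent
#'   display), default 2.
#' @return A rounded copy of the table.
#' @export
format_budget <- function(budget, mrr_digits = 2) {
  out <- dplyr::mutate(budget, dplyr::across(
    dplyr::any_of(c("agy", "asy", "gb", "tvc", "nb")), ~ round(.x, 2)))
  if ("mrr" %in% names(out)) out$mrr <- round(out$mrr, mrr_digits)
  out
}
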