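#' Specify the effect structure of a synthetic trial
#'
#' An `effect_spec` describes one trait of the linear model the combined
#' ANOVA assumes: trait value = grand mean + year + block + main effects of
#' N/P2O5, biochar and vermicompost + optional interaction terms + Gaussian
#' plot error.  Every effect vector must sum to zero (the identifiable
#' parameterization); interaction arrays must sum to zero over each margin.
#'
#' @param trait Trait name the spec applies to.
#' @param grand_mean Grand mean in trait units.
#' @param year_effects,block_effects Additive shifts, one per year/block,
#'   summing to zero.  Defaults: no year or block effect.
#' @param np_effects,bc_effects,vc_effects Main-effect vectors (length 3,
#'   sum zero) for the three treatment factors.
#' @param interaction_effects Named list of arrays; names are factor subsets
#'   joined with `":"` from `np`, `bc`, `vc`, `year` (e.g. `"np:bc"`,
#'   `"np:bc:vc"`), dimensions matching the level counts in name order.
#' @param error_sd Plot-error standard deviation (trait units), >= 0.
#' @param mc_range Range the harvest grain-moisture column is drawn from
#'   (uniform), default 14-25%.
#' @param n_years,n_blocks Level counts the vectors must conform to.
#' @return An object of class `effect_spec`.
#' @seealso [calibrated_spec()], [simulate_trial()]
#' @examples
#' effect_spec("GY", grand_mean = 9.258, error_sd = 0.4,
#'             np_effects = c(-1.5, 0.75, 0.75))
#' @export
effect_spec <- function(trait = "GY", grand_mean = 0,
                        year_effects = c(0, 0), block_effects = c(0, 0, 0),
                        np_effects = c(0, 0, 0), bc_effects = c(0, 0, 0),
                        vc_effects = c(0, 0, 0),
                        interaction_effects = list(),
                        error_sd = 0, mc_range = c(14, 25),
                        n_years = 2, n_blocks = 3) {
  if (error_sd < 0) abort("`error_sd` must be non-negative.")
  chk <- function(v, len, what) {
    if (length(v) != len) {
      abort(paste0("`", what, "` must have length ", len, "."))
    }
    if (abs(sum(v)) > 1e-8 * max(1, max(abs(v)))) {
      abort(paste0("`", what, "` must sum to zero."))
    }
    v
  }
  lens <- c(np = 3L, bc = 3L, vc = 3L, year = as.integer(n_years))
  for (nm in names(interaction_effects)) {
    facs <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(facs %in% names(lens))) {
      abort(paste0("Unknown factor in interaction term '", nm, "'."))
    }
    a <- interaction_effects[[nm]]
    if (!identical(as.integer(dim(a) %||% length(a)),
                   unname(lens[facs]))) {
      abort(paste0("Interaction '", nm, "' has wrong dimensions."))
    }
    for (d in seq_along(facs)) {
      marg <- apply(a, setdiff(seq_along(facs), d), sum)
      if (any(abs(marg) > 1e-8 * max(1, max(abs(a))))) {
        abort(paste0("Interaction '", nm, "' must sum to zero over each margin."))
      }
    }
  }
  structure(
    list(trait = trait, grand_mean = grand_mean,
         year_effects = chk(year_effects, n_years, "year_effects"),
         block_effects = chk(block_effects, n_blocks, "block_effects"),
         np_effects = chk(np_effects, 3L, "np_effects"),
         bc_effects = chk(bc_effects, 3L, "bc_effects"),
         vc_effects = chk(vc_effects, 3L, "vc_effects"),
         interaction_effects = interaction_effects,
         error_sd = error_sd, mc_range = mc_range),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>", x$trait, " grand mean", x$grand_mean,
      " error sd", x$error_sd, "\n")
  cat("  interactions:", if (length(x$interaction_effects))
    paste(names(x$interaction_effects), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Effect spec calibrated to the reference trial
#'
#' Builds an [effect_spec()] whose expected cell means reproduce the
#' published combined-over-years treatment means of the reference trial
#' ([reference_cell_means()]): the published 27-cell table is decomposed
#' into main effects, all two-way and the three-way interaction of the
#' treatment factors, anchored at the published pooled mean.  The error SD
#' is set so the residual coefficient of variation matches the published CV
#' (`error_sd = cv/100 * grand_mean`).  Year effects come from the published
#' year means where available (grain and biological yield); block effects
#' are zero (the published block term is non-significant).
#'
#' @param trait One of the ten trait names (see [reference_trait_summary()]).
#' @param zero_effects If `TRUE`, return a null variant: same grand mean and
#'   error SD, all effect vectors zero.
#' @return An `effect_spec`.
#' @examples
#' calibrated_spec("GY")$grand_mean   # 9.258
#' @export
calibrated_spec <- function(trait, zero_effects = FALSE) {
  summ <- reference_trait_summary()
  if (!trait %in% summ$trait) {
    abort(paste0("Unknown trait '", trait, "'."))
  }
  row <- summ[summ$trait == trait, ]
  sdv <- row$cv / 100 * row$grand_mean
  if (zero_effects) {
    return(effect_spec(trait, grand_mean = row$grand_mean, error_sd = sdv))
  }

  cells <- reference_cell_means()
  arr <- array(NA_real_, dim = c(3, 3, 3))
  inp <- match(cells$np, c("0/0", "120/69", "240/138"))
  ibc <- match(cells$bc, c(0, 4, 8))
  ivc <- match(cells$vc, c(0, 5.02, 10.04))
  arr[cbind(inp, ibc, ivc)] <- cells[[trait]]

  m <- mean(arr)
  np_e <- apply(arr, 1, mean) - m
  bc_e <- apply(arr, 2, mean) - m
  vc_e <- apply(arr, 3, mean) - m
  np_bc <- apply(arr, c(1, 2), mean) - m - outer(np_e, bc_e, `+`)
  np_vc <- apply(arr, c(1, 3), mean) - m - outer(np_e, vc_e, `+`)
  bc_vc <- apply(arr, c(2, 3), mean) - m - outer(bc_e, vc_e, `+`)
  ix <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  three <- array(0, dim = c(3, 3, 3))
  three[ix] <- arr[ix] - m - np_e[ix[, 1]] - bc_e[ix[, 2]] - vc_e[ix[, 3]] -
    np_bc[ix[, c(1, 2)]] - np_vc[ix[, c(1, 3)]] - bc_vc[ix[, c(2, 3)]]

  yr <- c(0, 0)
  if (!is.na(row$mean_2023)) {
    yr <- c(row$mean_2023, row$mean_2024)
    yr <- yr - mean(yr)
  }

  effect_spec(
    trait, grand_mean = row$grand_mean,
    year_effects = yr,
    np_effects = np_e, bc_effects = bc_e, vc_effects = vc_e,
    interaction_effects = list("np:bc" = np_bc, "np:vc" = np_vc,
                               "bc:vc" = bc_vc, "np:bc:vc" = three),
    error_sd = sdv
  )
}

#' Calibrated specs for several traits
#'
#' @param traits Trait names; default all ten.
#' @return A named list of [effect_spec()] objects.
#' @export
calibrated_specs <- function(traits = reference_trait_summary()$trait) {
  setNames(lapply(traits, calibrated_spec), traits)
}

#' Generate a synthetic plot table
#'
#' Draws one record per (year, block, treatment) cell of the design for each
#' supplied trait spec: expected value from the spec's effect structure plus
#' independent Gaussian plot error.  A grain-moisture column `MC` is drawn
#' uniformly from the spec's `mc_range`, and when grain/biological yield are
#' among the traits the corresponding raw net-plot masses (`GY_plot`,
#' `BY_plot`, kg) are derived by inverting the moisture and area conversions
#' so the full agronomic chain can be exercised on synthetic data.
#'
#' @param specs An [effect_spec()] or a (named) list of them, one per trait.
#' @param design A [trial_design()].
#' @param seed Integer seed for reproducibility (optional).
#' @param derive_plot_masses Derive `GY_plot`/`BY_plot` from the generated
#'   yields?  Default `TRUE` when those traits are present.
#' @return A validated plot-record tibble (see [read_plot_table()]).
#' @examples
#' rec <- simulate_trial(calibrated_spec("GY"), seed = 1)
#' nrow(rec)  # 162
#' @export
simulate_trial <- function(specs = calibrated_specs(), design = trial_design(),
                           seed = NULL, derive_plot_masses = TRUE) {
  if (inherits(specs, "effect_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, `[[`, character(1), "trait")
  }
  if (!is.null(seed)) set.seed(seed)

  cb <- treatment_codebook()
  grid <- tidyr::expand_grid(year = design$years,
                             block = seq_len(design$n_blocks),
                             treatment = cb$treatment)
  idx <- list(
    year = match(grid$year, design$years),
    block = grid$block,
    np = (match(grid$treatment, cb$treatment) - 1L) %% 9L %/% 3L + 1L,
    bc = (match(grid$treatment, cb$treatment) - 1L) %/% 9L + 1L,
    vc = (match(grid$treatment, cb$treatment) - 1L) %% 3L + 1L
  )
  n <- nrow(grid)

  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (length(sp$year_effects) != length(design$years)) {
      abort(paste0("Spec for ", nm, " has ", length(sp$year_effects),
                   " year effects but the design has ",
                   length(design$years), " years."))
    }
    mu <- sp$grand_mean + sp$year_effects[idx$year] +
      sp$block_effects[idx$block] + sp$np_effects[idx$np] +
      sp$bc_effects[idx$bc] + sp$vc_effects[idx$vc]
    for (term in names(sp$interaction_effects)) {
      facs <- strsplit(term, ":", fixed = TRUE)[[1]]
      a <- sp$interaction_effects[[term]]
      mu <- mu + a[do.call(cbind, idx[facs])]
    }
    grid[[sp$trait]] <- mu + rnorm(n, sd = sp$error_sd)
  }

  mc_range <- specs[[1]]$mc_range
  grid$MC <- runif(n, mc_range[1], mc_range[2])

  if (derive_plot_masses && "GY" %in% names(grid)) {
    raw_kg_ha <- grid$GY * 1000 * (100 - design$standard_mc) / (100 - grid$MC)
    grid$GY_plot <- raw_kg_ha * design$net_plot_area / 10000
  }
  if (derive_plot_masses && "BY" %in% names(grid)) {
    grid$BY_plot <- grid$BY * 1000 * design$net_plot_area / 10000
  }
  validate_plot_table(grid, design)
}
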