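#' Combined-over-years factorial RCBD ANOVA
#'
#' Fits the fixed-effects decomposition used for multi-season factorial RCBD
#' trials: Block (a single replicate factor crossed with year, 2 df), the
#' three treatment factors (N/P2O5, biochar, vermicompost), Year, and every
#' interaction among the treatment factors and year, all tested against the
#' pooled residual.  On the complete 27 x 3 x 2 layout this leaves 106 error
#' df.  The design is balanced, so the sequential sums of squares are the
#' orthogonal marginal decomposition; for unbalanced input the fit proceeds
#' sequentially with a warning.
#'
#' @param records A validated plot table ([read_plot_table()] or
#'   [simulate_trial()]).
#' @param trait Trait column to analyze.
#' @param design A [trial_design()].
#' @return An object of class `trial_anova` with methods [tidy()],
#'   [glance()] and `print()`.  Components: `table` (source, df, ss, ms,
#'   f, p, sig), `trait`, `grand_mean`, `mse`, `df_error`, `cv`, `r2`,
#'   `data` (the analyzed records with design factors attached).
#' @examples
#' fit <- fit_trial_anova(simulate_trial(calibrated_spec("GY"), seed = 1), "GY")
#' glance(fit)
#' @export
fit_trial_anova <- function(records, trait, design = trial_design()) {
  if (!trait %in% names(records)) {
    abort(paste0("Trait column '", trait, "' not found."))
  }
  dat <- add_design_factors(tibble::as_tibble(records), design)
  dat$.y <- dat[[trait]]
  dat$year_f <- factor(dat$year)
  dat$block_f <- factor(dat$block)
  dat <- dat[!is.na(dat$.y), ]

  multi_year <- nlevels(dat$year_f) > 1
  if (!multi_year) {
    inform("Single-year table: year terms dropped from the model.")
  }
  n_cells <- dplyr::n_distinct(paste(dat$year, dat$treatment))
  if (nrow(dat) < n_cells + 1) {
    abort("Fewer than two replicates: no error degrees of freedom.")
  }
  balanced <- length(unique(table(paste(dat$year, dat$block, dat$treatment)))) == 1 &&
    isTRUE(attr(records, "design_complete") %||%
             (nrow(dat) == 27 * design$n_blocks * nlevels(dat$year_f)))
  if (!balanced) {
    warn("Unbalanced layout: reporting sequential sums of squares.")
  }

  form <- if (multi_year) {
    .y ~ block_f + np + bc + vc + year_f +
      np:bc + np:vc + np:year_f + bc:vc + bc:year_f + vc:year_f +
      np:bc:vc + np:bc:year_f + np:vc:year_f + bc:vc:year_f +
      np:bc:vc:year_f
  } else {
    .y ~ block_f + np + bc + vc + np:bc + np:vc + bc:vc + np:bc:vc
  }
  fit <- aov(form, data = dat)
  at <- anova(fit)

  relabel <- c(block_f = "Block", np = "N/P2O5", bc = "BC", vc = "VC",
               year_f = "Year", Residuals = "Error")
  src <- rownames(at)
  src <- vapply(src, function(s) {
    parts <- strsplit(trimws(s), ":", fixed = TRUE)[[1]]
    paste(ifelse(parts %in% names(relabel), relabel[parts], parts),
          collapse = ":")
  }, character(1))

  order_wanted <- c("Block", "N/P2O5", "BC", "VC", "Year",
                    "N/P2O5:BC", "N/P2O5:VC", "N/P2O5:Year", "BC:VC",
                    "BC:Year", "VC:Year", "N/P2O5:BC:VC", "N/P2O5:BC:Year",
                    "N/P2O5:VC:Year", "BC:VC:Year", "N/P2O5:BC:VC:Year",
                    "Error")
  tab <- tibble::tibble(
    source = unname(src),
    df = at$Df, ss = at$`Sum Sq`, ms = at$`Mean Sq`,
    f = at$`F value`, p = at$`Pr(>F)`
  )
  tab <- tab[order(match(tab$source, order_wanted)), ]
  zero_var <- var(dat$.y) == 0
  if (zero_var) {
    warn("Zero-variance trait: all sums of squares are zero, F undefined.")
    tab$f[tab$source != "Error"] <- NA_real_
    tab$p[tab$source != "Error"] <- NA_real_
  }
  tab$sig <- sig_class(tab$p)
  tab$sig[tab$source == "Error"] <- ""

  err <- tab[tab$source == "Error", ]
  gm <- mean(dat$.y)
  total_ss <- sum(tab$ss)
  structure(
    list(table = tab, trait = trait, grand_mean = gm,
         mse = err$ms, df_error = err$df,
         cv = 100 * sqrt(err$ms) / gm,
         r2 = if (total_ss > 0) 1 - err$ss / total_ss else NA_real_,
         n = nrow(dat), residuals = unname(stats::residuals(fit)),
         data = dat, design = design),
    class = "trial_anova"
  )
}

# ** p < 0.01, * p < 0.05, ns otherwise.
sig_class <- function(p) {
  dplyr::case_when(is.na(p) ~ "ns",
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' @export
print.trial_anova <- function(x, ...) {
  cat("Combined ANOVA for", x$trait, "\n")
  print(as.data.frame(dplyr::mutate(x$table,
    dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 5)))),
    row.names = FALSE)
  cat(sprintf("Grand mean %.4g  CV %.3g%%  R2 %.3g  (n = %d)\n",
              x$grand_mean, x$cv, x$r2, x$n))
  invisible(x)
}

#' @method tidy trial_anova
#' @export
tidy.trial_anova <- function(x, ...) {
  dplyr::rename(x$table, term = "source", sumsq = "ss", meansq = "ms",
                statistic = "f", p.value = "p")
}

#' @method glance trial_anova
#' @export
glance.trial_anova <- function(x, ...) {
  tibble::tibble(trait = x$trait, grand_mean = x$grand_mean, cv = x$cv,
                 r.squared = x$r2, mse = x$mse, df_error = x$df_error,
                 nobs = x$n)
}

#' Least significant difference
#'
#' The t-based threshold for declaring two treatment means different at
#' level `alpha`: `t(1 - alpha/2, df_error) * sqrt(2 * ms_error / n)`.
#'
#' @param ms_error Error mean square (trait units squared).
#' @param df_error Error degrees of freedom, >= 1.
#' @param n_per_mean Observations per compared mean (replications x years
#'   for combined-over-years means).
#' @param alpha Significance level, default 0.05.
#' @return The LSD in trait units.
#' @examples
#' lsd_value(0.16, 106, 6)
#' @export
lsd_value <- function(ms_error, df_error, n_per_mean, alpha = 0.05) {
  if (ms_error < 0) abort("`ms_error` must be non-negative.")
  if (df_error < 1 || n_per_mean < 1) {
    abort("`df_error` and `n_per_mean` must be at least 1.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
}

#' Compact letter display for LSD mean separation
#'
#' Assigns minimal letter codes so that two means share a letter if and only
#' if their absolute difference does not exceed the LSD.  With a single
#' scalar threshold the "not significantly different" relation is an
#' interval relation on the sorted means, so the letters are the maximal
#' runs of mutually indistinguishable means, lettered `a` from the largest
#' mean downward; ties are broken by descending mean, then by label.
#'
#' @param means Named numeric vector of group means.
#' @param lsd Least significant difference, >= 0.
#' @return Named character vector of letter strings, in the input order.
#' @examples
#' compact_letters(c(A = 10, B = 9.5, C = 9.0), lsd = 0.6)  # a, ab, b
#' @export
compact_letters <- function(means, lsd) {
  if (lsd < 0) abort("`lsd` must be non-negative.")
  if (is.null(names(means))) names(means) <- seq_along(means)
  ord <- order(-means, names(means))
  m <- means[ord]
  k <- length(m)

  # Maximal indistinguishability intervals on the sorted means.
  ends <- vapply(seq_len(k), function(i) {
    max(which(m[i] - m <= lsd + 1e-12))
  }, integer(1))
  groups <- list()
  for (i in seq_len(k)) {
    g <- c(i, ends[i])
    if (length(groups) == 0 || ends[i] > groups[[length(groups)]][2]) {
      groups[[length(groups) + 1]] <- g
    }
  }
  letters_out <- rep("", k)
  for (gi in seq_along(groups)) {
    span <- groups[[gi]]
    idx <- span[1]:span[2]
    letters_out[idx] <- paste0(letters_out[idx], make_letters(gi))
  }
  res <- setNames(letters_out, names(m))
  res[names(means)]
}

# a, b, ..., z, aa, ab, ... for >26 groups.
make_letters <- function(i) {
  if (i <= 26) return(letters[i])
  paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

#' Factor-level means with LSD letters
#'
#' Computes group means for any crossing of the design factors from a fitted
#' [fit_trial_anova()], the LSD at `alpha`, and the compact letter display.
#'
#' @param fit A `trial_anova` object.
#' @param terms Character vector of grouping factors among `"np"`, `"bc"`,
#'   `"vc"`, `"year"`, `"treatment"`; default the three-way treatment
#'   combination `c("np", "bc", "vc")`.
#' @param alpha Significance level for the LSD, default 0.05.
#' @return A tibble of groups, `mean` and `letters`, with attributes `lsd`,
#'   `cv`, `r2`, `grand_mean`, `n_per_mean`.
#' @examples
#' fit <- fit_trial_anova(simulate_trial(calibrated_spec("GY"), seed = 1), "GY")
#' head(means_table(fit))
#' @export
means_table <- function(fit, terms = c("np", "bc", "vc"), alpha = 0.05) {
  stopifnot(inherits(fit, "trial_anova"))
  dat <- fit$data
  dat$year <- factor(dat$year)
  bad <- setdiff(terms, c("np", "bc", "vc", "year", "treatment"))
  if (length(bad)) abort(paste0("Unknown grouping term(s): ",
                                paste(bad, collapse = ", ")))
  tab <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(terms))) |>
    dplyr::summarise(mean = mean(.data$.y), n = dplyr::n(),
                     .groups = "drop")
  n_per_mean <- min(tab$n)
  lsd <- lsd_value(fit$mse, fit$df_error, n_per_mean, alpha)
  mm <- setNames(tab$mean, do.call(paste, c(tab[terms], sep = "|")))
  tab$letters <- unname(compact_letters(mm, lsd))
  tab$n <- NULL
  attr(tab, "lsd") <- lsd
  attr(tab, "cv") <- fit$cv
  attr(tab, "r2") <- fit$r2
  attr(tab, "grand_mean") <- fit$grand_mean
  attr(tab, "n_per_mean") <- n_per_mean
  attr(tab, "alpha") <- alpha
  class(tab) <- c("trial_means", class(tab))
  tab
}

#' @export
print.trial_means <- function(x, ...) {
  NextMethod()
  cat(sprintf("LSD(%g) = %.4g, CV = %.3g%%, grand mean = %.4g (n/mean = %d)\n",
              attr(x, "alpha"), attr(x, "lsd"), attr(x, "cv"),
              attr(x, "grand_mean"), attr(x, "n_per_mean")))
  invisible(x)
}

#' Pairwise trait correlations with significance classes
#'
#' Pearson correlation for every trait pair with a two-sided t-test, classed
#' `**` (p < 0.01), `*` (p < 0.05) or `ns`.  Constant traits yield an
#' undefined correlation and are flagged with `NA`.
#'
#' @param records A plot table.
#' @param traits Trait columns to correlate; defaults to all built-in traits
#'   present.
#' @return A tibble with `trait1`, `trait2`, `r`, `p`, `sig` (upper
#'   triangle including the diagonal).
#' @examples
#' rec <- simulate_trial(calibrated_specs(c("GY", "TGW", "PH")), seed = 1)
#' trait_correlations(rec, c("GY", "TGW", "PH"))
#' @export
trait_correlations <- function(records, traits = NULL) {
  traits <- traits %||% intersect(.trait_vocab, names(records))
  if (length(traits) < 2) abort("Need at least two traits.")
  if (nrow(records) < 3) abort("Need at least three paired observations.")
  pairs <- tidyr::expand_grid(trait1 = traits, trait2 = traits) |>
    dplyr::filter(match(.data$trait1, traits) <= match(.data$trait2, traits))
  res <- purrr::pmap_dfr(pairs, function(trait1, trait2) {
    x <- records[[trait1]]; y <- records[[trait2]]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(paste0("Constant trait in pair ", trait1, "-", trait2,
                  ": correlation undefined."))
      return(tibble::tibble(trait1 = trait1, trait2 = trait2,
                            r = NA_real_, p = NA_real_, sig = NA_character_))
    }
    if (trait1 == trait2) {
      return(tibble::tibble(trait1 = trait1, trait2 = trait2, r = 1,
                            p = 0, sig = "**"))
    }
    ct <- cor.test(x, y)
    tibble::tibble(trait1 = trait1, trait2 = trait2,
                   r = unname(ct$estimate), p = ct$p.value,
                   sig = sig_class(ct$p.value))
  })
  res
}

#' Shapiro-Wilk normality screen
#'
#' Pre-analysis screen on a trait or residual vector: Shapiro-Wilk W and p,
#' passing when p > alpha.  On failure the recommended course is a variance-
#' stabilizing transform (log or square root), applied explicitly by the
#' analyst, never silently.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Screen level, default 0.05.
#' @return A tibble with `statistic` (W), `p`, `pass`.
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (sd(values) == 0) abort("Constant vector: normality test undefined.")
  sw <- shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic), p = sw$p.value,
                 pass = sw$p.value > alpha)
}

#' F-test screen for homogeneity of error variances across years
#'
#' Ratio of the larger to the smaller residual variance of the two year
#' groups, tested two-sided against the F distribution; the screen passes
#' when equality is not rejected at `alpha`.
#'
#' @param residuals Numeric vector of residuals.
#' @param year Grouping vector (exactly two groups, >= 2 values each).
#' @param alpha Screen level, default 0.05.
#' @return A tibble with `f` (variance ratio >= 1), `df1`, `df2`, `p`,
#'   `pass`.
#' @export
variance_homogeneity <- function(residuals, year, alpha = 0.05) {
  groups <- split(residuals, year)
  if (length(groups) != 2 || any(lengths(groups) < 2)) {
    abort("Need exactly two year groups with at least two residuals each.")
  }
  v <- vapply(groups, var, numeric(1))
  hi <- which.max(v); lo <- which.min(v)
  if (v[lo] == 0 && v[hi] == 0) {
    return(tibble::tibble(f = 1, df1 = lengths(groups)[hi] - 1,
                          df2 = lengths(groups)[lo] - 1, p = 1, pass = TRUE))
  }
  vt <- var.test(groups[[hi]], groups[[lo]])
  tibble::tibble(f = unname(vt$statistic),
                 df1 = unname(vt$parameter[1]), df2 = unname(vt$parameter[2]),
                 p = vt$p.value, pass = vt$p.value > alpha)
}
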