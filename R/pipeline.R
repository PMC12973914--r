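#' Analyze every trait of a plot table
#'
#' Runs the standard analysis chain per trait — residual normality screen,
#' year-variance homogeneity screen, combined ANOVA, LSD means with letters —
#' and the trait correlation matrix, in that order.  Screen failures are
#' reported in the result (and as warnings), never acted on silently.
#'
#' @param records A validated plot table.
#' @param traits Trait columns to analyze; defaults to the built-in traits
#'   present in `records`.  Requested traits missing from the table are
#'   skipped with a warning.
#' @param design A [trial_design()].
#' @param alpha Significance level for mean separation, default 0.05.
#' @param means_terms Grouping for the means tables, default
#'   `c("np", "bc", "vc")`.
#' @return An object of class `trial_analysis`: a list with `anova` and
#'   `means` (named lists per trait), `screens` (one row per trait) and
#'   `correlations`.
#' @examples
#' rec <- simulate_trial(calibrated_specs(c("GY", "TGW")), seed = 1)
#' res <- analyze_trial(rec)
#' res$screens
#' @export
analyze_trial <- function(records, traits = NULL, design = trial_design(),
                          alpha = 0.05, means_terms = c("np", "bc", "vc")) {
  present <- intersect(.trait_vocab, names(records))
  traits <- traits %||% present
  skipped <- setdiff(traits, names(records))
  if (length(skipped)) {
    warn(paste0("Trait column(s) missing, skipped: ",
                paste(skipped, collapse = ", ")))
    traits <- intersect(traits, names(records))
  }
  if (!length(traits)) abort("No analyzable trait columns found.")

  fits <- list(); means <- list(); screens <- list()
  for (tr in traits) {
    fit <- fit_trial_anova(records, tr, design)
    res <- fit$residuals
    nm <- normality_screen(fit$data$.y)
    hom <- if (length(unique(fit$data$year)) == 2) {
      variance_homogeneity(res, fit$data$year)
    } else {
      tibble::tibble(f = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p = NA_real_, pass = NA)
    }
    screens[[tr]] <- tibble::tibble(
      trait = tr, shapiro_w = nm$statistic, shapiro_p = nm$p,
      normal = nm$pass, var_ratio = hom$f, var_p = hom$p,
      homogeneous = hom$pass)
    if (!nm$pass) {
      warn(paste0("Trait ", tr, " fails the normality screen (p = ",
                  signif(nm$p, 3),
                  "); consider an explicit log or sqrt transform."))
    }
    fits[[tr]] <- fit
    means[[tr]] <- means_table(fit, means_terms, alpha)
  }
  corr <- if (length(traits) >= 2) {
    trait_correlations(records, traits)
  } else {
    NULL
  }
  structure(list(anova = fits, means = means,
                 screens = dplyr::bind_rows(screens),
                 correlations = corr),
            class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat("<trial_analysis>", length(x$anova), "trait(s):",
      paste(names(x$anova), collapse = ", "), "\n")
  print(x$screens)
  invisible(x)
}

#' Write analysis reports to a directory
#'
#' Writes per-trait ANOVA and means tables plus the correlation matrix as
#' CSV files, each with a comment header recording the package version and
#' the supplied run label, so a report can be traced to its run.
#'
#' @param analysis A [analyze_trial()] result.
#' @param dir Output directory (created if needed).
#' @param label Free-form run label (e.g. a seed or config hash) recorded in
#'   every file header.
#' @return Paths of the written files, invisibly.
#' @export
report_trial <- function(analysis, dir, label = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ver <- as.character(utils::packageVersion("isfmtrial"))
  hdr <- paste0("# isfmtrial ", ver,
                if (nzchar(label)) paste0(" | run: ", label) else "")
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_lines(c(hdr, readr::format_csv(tibble::as_tibble(x))), p)
    paths <<- c(paths, p)
  }
  for (tr in names(analysis$anova)) {
    emit(tidy(analysis$anova[[tr]]), paste0("anova_", tr, ".csv"))
    emit(analysis$means[[tr]], paste0("means_", tr, ".csv"))
  }
  if (!is.null(analysis$correlations)) {
    emit(analysis$correlations, "correlations.csv")
  }
  invisible(paths)
}

#' Net-benefit curve of a partial budget
#'
#' Plots net benefit against total variable cost: the undominated frontier
#' as a line, dominated treatments as hollow points, the recommended
#' treatment highlighted.
#'
#' @param object A `trial_budget` (or any tibble with `treatment`, `tvc`,
#'   `nb`, `dominated`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_budget
#' @export
autoplot.trial_budget <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  frontier <- dat[!dat$dominated, ]
  rec <- attr(object, "recommended")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$tvc, y = .data$nb)) +
    ggplot2::geom_line(data = frontier, linewidth = 0.4,
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dominated), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                labels = c("frontier", "dominated"),
                                name = NULL) +
    ggplot2::geom_text(data = frontier,
                       ggplot2::aes(label = .data$treatment),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "Total variable cost (ETB/ha)",
                  y = "Net benefit (ETB/ha)")
  if (!is.null(rec)) {
    p <- p + ggplot2::geom_point(data = dat[dat$treatment == rec, ],
                                 colour = "red3", size = 3)
  }
  p
}

#' Treatment means with letter groups
#'
#' Dot plot of group means ordered by value, annotated with the compact
#' letter display; the LSD is shown in the subtitle.
#'
#' @param object A `trial_means` table from [means_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_means
#' @export
autoplot.trial_means <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  grp_cols <- setdiff(names(dat), c("mean", "letters"))
  dat$group <- do.call(paste, c(dat[grp_cols], sep = " / "))
  dat$group <- stats::reorder(dat$group, dat$mean)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean, y = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       hjust = -0.6, size = 3) +
    ggplot2::labs(x = "Mean", y = NULL,
                  subtitle = sprintf("LSD(%g) = %.4g",
                                     attr(object, "alpha"),
                                     attr(object, "lsd")))
}
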