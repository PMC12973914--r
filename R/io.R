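#' Read a plot table
#'
#' Reads a delimited plot table (one row per plot-year) and validates it
#' against the treatment codebook and the trial design: treatment ids must
#' exist, `(year, block, treatment)` must be unique, trait cells must be
#' numeric, grain moisture must lie in (0, 100) and counts/masses must be
#' non-negative.  Columns outside the built-in trait vocabulary are kept but
#' ignored by the built-in analyses.
#'
#' @param path Path to a CSV file with columns `year`, `block`, `treatment`
#'   followed by trait columns.
#' @param design A [trial_design()].
#' @return A tibble of validated plot records.  The attribute
#'   `"design_complete"` is `TRUE` when every `(year, block, treatment)` cell
#'   of the full factorial grid is present; otherwise the loader warns and
#'   sets it to `FALSE`.
#' @seealso [write_table()], [simulate_trial()]
#' @export
read_plot_table <- function(path, design = trial_design()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_plot_table(raw, design)
}

#' Validate an in-memory plot table
#'
#' Applies [read_plot_table()]'s checks to a data frame that is already in
#' memory (e.g. the output of [simulate_trial()]).
#'
#' @param records A data frame with `year`, `block`, `treatment` and trait
#'   columns.
#' @inheritParams read_plot_table
#' @return The validated tibble (see [read_plot_table()]).
#' @export
validate_plot_table <- function(records, design = trial_design()) {
  records <- tibble::as_tibble(records)
  need <- c("year", "block", "treatment")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("Plot table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  cb <- treatment_codebook()
  bad <- which(!records$treatment %in% cb$treatment)
  if (length(bad)) {
    abort(paste0("Unknown treatment id ", records$treatment[bad[1]],
                 " in row ", bad[1], " of the plot table."))
  }

  key <- paste(records$year, records$block, records$treatment)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort(paste0("Duplicate (year, block, treatment) record in row ", d,
                 ": ", key[d]))
  }

  trait_cols <- intersect(c(.trait_vocab, .aux_vocab), names(records))
  for (col in trait_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      nn <- suppressWarnings(as.numeric(v))
      if (anyNA(nn) && !all(is.na(v) == is.na(nn))) {
        r <- which(is.na(nn) & !is.na(v))[1]
        abort(paste0("Non-numeric value '", v[r], "' in column ", col,
                     ", row ", r, "."))
      }
      records[[col]] <- nn
    }
  }
  if ("MC" %in% names(records)) {
    mc <- records$MC
    if (any(!is.na(mc) & (mc <= 0 | mc >= 100))) {
      abort("Grain moisture MC must lie strictly between 0 and 100%.")
    }
  }
  for (col in intersect(c("ENPP", "GNPE", "NRPE", "TGW", "BY", "GY",
                          "GY_plot", "BY_plot"), names(records))) {
    if (any(records[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("Column ", col, " contains negative values."))
    }
  }

  grid <- tidyr::expand_grid(year = design$years,
                             block = seq_len(design$n_blocks),
                             treatment = cb$treatment)
  complete <- nrow(records) == nrow(grid) &&
    all(paste(grid$year, grid$block, grid$treatment) %in% key)
  if (!complete) {
    warn(paste0("Plot table does not cover the full ",
                length(design$years), "-year x ", design$n_blocks,
                "-block x 27-treatment grid; design flagged incomplete."))
  }
  attr(records, "design_complete") <- complete
  records
}

#' Write a result table to CSV
#'
#' Full-precision CSV writer used for every tabular result (plot tables,
#' ANOVA tables, means tables, budget tables).  Values round-trip through
#' [readr::read_csv()] without loss beyond double precision.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}
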