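test_that("combined ANOVA reproduces the published source structure", {
  rec <- simulate_trial(calibrated_spec("GY"), seed = 4)
  fit <- fit_trial_anova(rec, "GY")
  tab <- tidy(fit)
  expect_equal(tab$term,
               c("Block", "N/P2O5", "BC", "VC", "Year",
                 "N/P2O5:BC", "N/P2O5:VC", "N/P2O5:Year", "BC:VC",
                 "BC:Year", "VC:Year", "N/P2O5:BC:VC", "N/P2O5:BC:Year",
                 "N/P2O5:VC:Year", "BC:VC:Year", "N/P2O5:BC:VC:Year",
                 "Error"))
  expect_equal(tab$df,
               c(2, 2, 2, 2, 1, 4, 4, 2, 4, 2, 2, 8, 4, 4, 4, 8, 106))
  expect_equal(sum(tab$df), 161)
  expect_equal(tab$meansq, tab$sumsq / tab$df)
  # SS conservation about the grand mean
  expect_equal(sum(tab$sumsq), sum((rec$GY - mean(rec$GY))^2),
               tolerance = 1e-10)
  # the injected treatment structure is recovered as highly significant
  expect_true(all(tab$sig[tab$term %in% c("N/P2O5", "BC", "VC")] == "**"))
})

test_that("every source SS matches the inclusion-exclusion oracle", {
  for (seed in c(21, 22)) {
    set.seed(seed)
    rec <- simulate_trial(calibrated_spec("GY"), seed = seed)
    rec$GY <- rnorm(nrow(rec))  # pure-noise response, arbitrary structure
    fit <- fit_trial_anova(rec, "GY")
    dat <- fit$data
    facs <- data.frame(np = dat$np, bc = dat$bc, vc = dat$vc,
                       year = factor(dat$year), block = factor(dat$block))
    tab <- tidy(fit)
    sources <- list(
      "Block" = "block", "N/P2O5" = "np", "BC" = "bc", "VC" = "vc",
      "Year" = "year", "N/P2O5:BC" = c("np", "bc"),
      "N/P2O5:VC" = c("np", "vc"), "N/P2O5:Year" = c("np", "year"),
      "BC:VC" = c("bc", "vc"), "BC:Year" = c("bc", "year"),
      "VC:Year" = c("vc", "year"), "N/P2O5:BC:VC" = c("np", "bc", "vc"),
      "N/P2O5:BC:Year" = c("np", "bc", "year"),
      "N/P2O5:VC:Year" = c("np", "vc", "year"),
      "BC:VC:Year" = c("bc", "vc", "year"),
      "N/P2O5:BC:VC:Year" = c("np", "bc", "vc", "year"))
    for (src in names(sources)) {
      expected <- oracle_ss(dat$.y, facs, sources[[src]])
      got <- tab$sumsq[tab$term == src]
      expect_equal(got, expected, tolerance = 1e-8,
                   label = paste0(src, " SS (seed ", seed, ")"))
    }
  }
})

test_that("relabelling factor levels permutes means but not SS", {
  rec <- simulate_trial(calibrated_spec("GY"), seed = 31)
  fit1 <- fit_trial_anova(rec, "GY")
  # swap the bc = 0 and bc = 8 labels throughout
  swapped <- rec
  cb <- treatment_codebook()
  idx <- match(swapped$treatment, cb$treatment)
  new_bc <- c(`0` = 8, `4` = 4, `8` = 0)[as.character(cb$bc_rate[idx])]
  key <- paste(cb$n_rate[idx], new_bc, cb$vc_rate[idx])
  swapped$treatment <- cb$treatment[match(
    key, paste(cb$n_rate, cb$bc_rate, cb$vc_rate))]
  fit2 <- fit_trial_anova(validate_plot_table(swapped), "GY")
  expect_equal(sort(tidy(fit2)$sumsq), sort(tidy(fit1)$sumsq),
               tolerance = 1e-10)
  expect_equal(tidy(fit2)$sumsq[tidy(fit2)$term == "BC"],
               tidy(fit1)$sumsq[tidy(fit1)$term == "BC"], tolerance = 1e-10)
})

test_that("degenerate inputs are refused or flagged", {
  rec <- simulate_trial(calibrated_spec("GY"), seed = 41)
  one_block <- rec[rec$block == 1, ]
  expect_error(
    suppressWarnings(fit_trial_anova(validate_plot_table(one_block), "GY")),
    "error degrees of freedom")

  flat <- rec; flat$GY <- 5
  expect_warning(fit0 <- fit_trial_anova(flat, "GY"), "Zero-variance")
  expect_true(all(fit0$table$ss < 1e-20))
  expect_true(all(is.na(fit0$table$f[fit0$table$source != "Error"])))

  single <- rec[rec$year == 2023, ]
  expect_message(
    fits <- fit_trial_anova(validate_plot_table(single), "GY"),
    "Single-year")
  expect_false(any(grepl("Year", tidy(fits)$term)))
  expect_equal(sum(tidy(fits)$df), 80)

  unbal <- rec[-(1:5), ]
  expect_warning(expect_warning(
    fit_trial_anova(validate_plot_table(unbal), "GY"),
    "incomplete"), "sequential")
})

test_that("LSD formula matches the t-quantile arithmetic", {
  expect_equal(lsd_value(0, 10, 3), 0)
  expect_equal(lsd_value(0.16, 106, 6),
               qt(0.975, 106) * sqrt(2 * 0.16 / 6))
  expect_equal(round(lsd_value(0.16, 106, 6), 4), 0.4579)
  # monotone in confidence: smaller alpha, larger LSD
  expect_gt(lsd_value(1, 20, 4, alpha = 0.01), lsd_value(1, 20, 4, 0.05))
  expect_error(lsd_value(1, 0, 3), "at least 1")
})

test_that("compact letters satisfy the shared-letter iff-LSD condition", {
  expect_equal(unname(compact_letters(c(a = 1, b = 1.2, c = 0.9), 1)),
               c("a", "a", "a"))
  expect_equal(compact_letters(c(hi = 10, lo = 5), 1),
               c(hi = "a", lo = "b"))
  expect_equal(compact_letters(c(x = 10, y = 9.5, z = 9.0), 0.6),
               c(x = "a", y = "ab", z = "b"))
})

test_that("means tables carry letters consistent with the LSD", {
  rec <- simulate_trial(calibrated_spec("GY"), seed = 51)
  fit <- fit_trial_anova(rec, "GY")
  mt <- means_table(fit)
  expect_equal(nrow(mt), 27)
  expect_equal(attr(mt, "n_per_mean"), 6L)
  expect_true(letters_consistent(mt$mean, mt$letters, attr(mt, "lsd")))
  expect_equal(attr(mt, "cv"), 100 * sqrt(fit$mse) / fit$grand_mean)

  by_np <- means_table(fit, "np")
  expect_equal(nrow(by_np), 3)
  expect_equal(attr(by_np, "n_per_mean"), 54L)
  expect_error(means_table(fit, "flavor"), "Unknown grouping")
})

test_that("correlations reproduce the published significance classing", {
  rec <- simulate_trial(calibrated_specs(c("GY", "TGW", "PH")), seed = 61)
  cm <- trait_correlations(rec, c("GY", "TGW", "PH"))
  expect_equal(cm$r[cm$trait1 == "GY" & cm$trait2 == "GY"], 1)
  # symmetric storage: every unordered pair appears once
  expect_equal(nrow(cm), 6)

  # perfect linearity
  toy <- data.frame(year = 1, block = 1:3, treatment = c("T1", "T2", "T3"),
                    GY = c(1, 2, 3), BY = c(2, 4, 6))
  cm2 <- trait_correlations(toy, c("GY", "BY"))
  expect_equal(cm2$r[cm2$trait1 == "GY" & cm2$trait2 == "BY"], 1)

  # the t-classing at the published TGW-GY magnitude: r = 0.809, n = 27
  r <- 0.809; n <- 27
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tstat), n - 2)
  expect_lt(p, 0.01)

  const <- data.frame(year = 1, block = 1:3, treatment = c("T1", "T2", "T3"),
                      GY = c(1, 2, 3), BY = c(5, 5, 5))
  expect_warning(cm3 <- trait_correlations(const, c("GY", "BY")), "undefined")
  expect_true(is.na(cm3$r[cm3$trait1 == "GY" & cm3$trait2 == "BY"]))
})

test_that("normality screen separates normal from exponential samples", {
  pass_rate <- mean(vapply(1:100, function(i) {
    set.seed(7000 + i)
    normality_screen(rnorm(162))$pass
  }, logical(1)))
  fail_rate <- mean(vapply(1:100, function(i) {
    set.seed(8000 + i)
    !normality_screen(rexp(162))$pass
  }, logical(1)))
  expect_gte(pass_rate, 0.90)
  expect_gte(fail_rate, 0.90)
  expect_error(normality_screen(rep(1, 10)), "Constant")
  expect_error(normality_screen(c(1, 2)), "3 <= n")
})

test_that("variance homogeneity screen flags unequal year variances", {
  set.seed(5)
  r1 <- rnorm(81); r2 <- rnorm(81)
  out <- variance_homogeneity(c(r1, r1), rep(c(1, 2), each = 81))
  expect_equal(out$f, 1)
  expect_true(out$pass)

  out2 <- variance_homogeneity(c(rnorm(81, sd = 2), rnorm(81, sd = 1)),
                               rep(c(1, 2), each = 81))
  expect_gte(out2$f, 1)
  expect_false(out2$pass)
  expect_error(variance_homogeneity(rnorm(5), rep(1, 5)), "two year groups")
})
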