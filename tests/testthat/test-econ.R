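test_that("gross benefit is priced linearly and guards inputs", {
  expect_equal(gross_benefit(1000, 0, 27.83, 4.40), 27830)
  expect_equal(gross_benefit(0, 0, 27.83, 4.40), 0)
  expect_error(gross_benefit(-1, 0, 27.83, 4.40), "non-negative")
  expect_error(gross_benefit(1, 0, 0, 4.40), "positive")
  # published gross benefits do NOT reconcile with published yields and
  # mean prices (intermediate rounding upstream); the discrepancy is real
  t14 <- reference_budget()[reference_budget()$treatment == "T14", ]
  gb <- gross_benefit(t14$agy, t14$asy, 27.83, 4.40)
  expect_equal(gb, 383955, tolerance = 1e-6)
  expect_gt(abs(gb - t14$gb), 1000)
})

test_that("total variable cost composes rates, prices and labor", {
  cb <- treatment_codebook()
  prices <- c(n = 100, p2o5 = 80, bc = 5160, vc = 2130.3, lime = 6545.8)
  tvc <- total_variable_cost(cb, prices, base_cost = 500)
  t1 <- tvc$tvc[tvc$treatment == "T1"]
  # control carries lime plus the base cost only
  expect_equal(t1, 500 + 0.63 * 6545.8)
  # adding 4 t of biochar raises the cost by exactly 4 x unit price
  expect_equal(tvc$tvc[tvc$treatment == "T10"] - t1, 4 * 5160)
  # doubling all input rates doubles the input portion
  doubled <- cb
  for (col in c("n_rate", "p2o5_rate", "bc_rate", "vc_rate", "lime_rate")) {
    doubled[[col]] <- doubled[[col]] * 2
  }
  tvc2 <- total_variable_cost(doubled, prices, base_cost = 500)
  expect_equal(tvc2$tvc - 500, 2 * (tvc$tvc - 500), tolerance = 1e-10)
  # missing price for an applied input is a named error
  expect_error(total_variable_cost(cb, prices[c("n", "p2o5")]), "bc")
  # labor hook sees the treatment row
  tvc3 <- total_variable_cost(cb, prices,
                              labor = function(t) 10 * t$bc_rate)
  expect_equal(tvc3$tvc[tvc3$treatment == "T19"] -
                 tvc$tvc[tvc$treatment == "T19"] + 500, 80)
})

test_that("dominance matches the brute-force pairwise oracle", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    rows <- tibble::tibble(treatment = paste0("X", seq_len(n)),
                           tvc = sample(round(runif(n, 10, 100)), n),
                           nb = round(runif(n, 0, 50)))
    out <- dominance_analysis(rows)
    oracle <- oracle_dominated(out$tvc, out$nb)
    expect_equal(out$dominated, oracle)
    # invariant to input order and idempotent
    shuf <- dominance_analysis(rows[sample(n), ])
    expect_equal(shuf[order(shuf$treatment), ],
                 out[order(out$treatment), ])
    expect_equal(dominance_analysis(out)$dominated, out$dominated)
  }
  single <- dominance_analysis(tibble::tibble(treatment = "A", tvc = 1, nb = 1))
  expect_false(single$dominated)
  two <- dominance_analysis(tibble::tibble(treatment = c("A", "B"),
                                           tvc = c(1, 2), nb = c(5, 5)))
  expect_equal(two$dominated, c(FALSE, TRUE))
})

test_that("undominated frontier has increasing NB, TVC and positive MRR", {
  bud <- marginal_rate_of_return(dominance_analysis(reference_budget()))
  fr <- bud[!bud$dominated, ]
  expect_true(all(diff(fr$tvc) > 0))
  expect_true(all(diff(fr$nb) > 0))
  expect_true(all(fr$mrr[-1] > 0))
})

test_that("MRR reference rules and edge cases", {
  rows <- tibble::tibble(treatment = c("A", "B", "C"),
                         tvc = c(10, 20, 30), nb = c(100, 90, 130))
  out <- marginal_rate_of_return(rows)  # B dominated
  expect_true(is.na(out$mrr[1]))
  expect_equal(out$mrr[out$treatment == "B"], -100)          # vs A
  expect_equal(out$mrr[out$treatment == "C"], 150)           # vs A, not B
  imm <- marginal_rate_of_return(rows, reference = "immediate")
  expect_equal(imm$mrr[imm$treatment == "C"], 400)           # vs B
  # zero net-benefit step has MRR 0
  flat <- marginal_rate_of_return(tibble::tibble(
    treatment = c("A", "B"), tvc = c(10, 20), nb = c(100, 100)))
  expect_equal(flat$mrr[2], 0)
  # zero TVC step is undefined and flagged
  tie <- tibble::tibble(treatment = c("A", "B"), tvc = c(10, 10),
                        nb = c(100, 90))
  expect_warning(mrr_tie <- marginal_rate_of_return(tie), "Zero TVC")
  expect_true(is.na(mrr_tie$mrr[2]))
})

test_that("MRR is invariant to a common price/cost scale", {
  rows <- reference_budget()
  a <- marginal_rate_of_return(dominance_analysis(rows))
  scaled <- dplyr::mutate(rows, tvc = tvc * 3.7, nb = nb * 3.7)
  b <- marginal_rate_of_return(dominance_analysis(scaled))
  expect_equal(b$dominated, a$dominated)
  expect_equal(b$mrr, a$mrr, tolerance = 1e-10)
})

test_that("computed MRRs reconcile with the published column", {
  bud <- marginal_rate_of_return(dominance_analysis(reference_budget()))
  # four published entries are transcription/reference slips in the source
  # table; every other non-base row agrees at its printed precision
  slips <- c("T19", "T20", "T8", "T6")
  check <- bud[!bud$treatment %in% c("T1", slips), ]
  printed_digits <- ifelse(check$treatment == "T10", 0,
                    ifelse(check$treatment == "T3", 1,
                    ifelse(check$treatment == "T14", 3, 2)))
  agree <- abs(round(check$mrr, printed_digits) - check$mrr_published) < 1e-9
  expect_true(all(agree), label = paste("disagreeing rows:",
    paste(check$treatment[!agree], collapse = ", ")))
  expect_equal(nrow(check), 22)
  # the four slips still reconcile in sign and order of magnitude except the
  # mixed-reference T6 entry
  for (t in c("T19", "T20", "T8")) {
    expect_equal(bud$mrr[bud$treatment == t],
                 bud$mrr_published[bud$treatment == t],
                 tolerance = 5e-3)
  }
})

test_that("recommendation picks the highest-NB qualifier and falls back", {
  bud <- marginal_rate_of_return(dominance_analysis(reference_budget()))
  rec <- recommend_treatment(bud, marr_threshold = 100)
  expect_equal(rec$recommended, "T14")
  expect_setequal(rec$qualifying, c("T10", "T13", "T14"))
  expect_warning(rec2 <- recommend_treatment(bud, marr_threshold = 10000),
                 "base treatment T1")
  expect_equal(rec2$recommended, "T1")
  expect_length(rec2$qualifying, 0)
  # equal-NB tie resolved toward the lower cost
  rows <- tibble::tibble(treatment = c("A", "B", "C"),
                         tvc = c(10, 20, 30), nb = c(10, 200, 200))
  out <- suppressWarnings(marginal_rate_of_return(rows))
  pick <- recommend_treatment(out, marr_threshold = 100)
  expect_equal(pick$recommended, "B")
})

test_that("build_budget runs the full chain from treatment means", {
  cells <- reference_cell_means()
  means <- tibble::tibble(treatment = cells$treatment,
                          gy = cells$GY, by = cells$BY)
  tvc <- reference_budget()[, c("treatment", "tvc")]
  bud <- build_budget(means, tvc, grain_price = 27.83, straw_price = 4.40)
  expect_s3_class(bud, "trial_budget")
  # the published adjusted grain yields are the 10%-adjusted means
  expect_equal(bud$agy[bud$treatment == "T24"], 12.13 * 1000 * 0.9)
  expect_equal(bud$nb, bud$gb - bud$tvc)
  expect_true(all(!bud$dominated[bud$treatment %in% c("T1", "T13", "T14")]))
  expect_type(attr(bud, "recommended"), "character")

  # constructed scenario: one cheap clearly-superior treatment wins
  toy_means <- tibble::tibble(treatment = c("T1", "T2", "T3"),
                              gy = c(4, 10, 6), by = c(10, 20, 14))
  toy_tvc <- tibble::tibble(treatment = c("T1", "T2", "T3"),
                            tvc = c(1000, 2000, 5000))
  toy <- build_budget(toy_means, toy_tvc, 27.83, 4.40)
  expect_equal(attr(toy, "recommended"), "T2")

  # identical yields and costs: everything but the base collapses
  same <- tibble::tibble(treatment = c("T1", "T2"), gy = 5, by = 12)
  same_tvc <- tibble::tibble(treatment = c("T1", "T2"), tvc = 1000)
  expect_warning(flat <- build_budget(same, same_tvc, 27.83, 4.40),
                 "base treatment")
  expect_equal(attr(flat, "recommended")[1], "T1")

  expect_error(build_budget(means[0, ], tvc, 27.83, 4.40), "Empty")
  expect_error(build_budget(tibble::tibble(treatment = "T1", gy = 5, by = 4),
                            tvc, 27.83, 4.40), "negative")
})
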