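# Frozen worked examples: the 2x2 table a=20, b=10, c=10, d=20 evaluated at
# high precision from the closed forms (see helper-oracle.R):
#   ROR = 4, CI (1.367, 11.703); PRR = 2, chi2 = 20/3;
#   gamma = 4, EIC = 0.39232, VIC = 0.131642, IC025 = -0.33331;
#   EBGM = 4/3, EBGM05 = 0.45574.

test_that("worked 2x2 table reproduces the four frozen statistics", {
  s <- disproportionality_stats(20, 10, 10, 20)
  expect_equal(s$ror, 4)
  expect_equal(s$ror_lower, 1.36720, tolerance = 1e-4)
  expect_equal(s$ror_upper, 11.70283, tolerance = 1e-4)
  expect_true(s$ror_positive)

  expect_equal(s$prr, 2)
  expect_equal(s$chisq, 20 / 3)
  expect_true(s$prr_positive)

  expect_equal(s$gamma, 4, tolerance = 1e-12)
  expect_equal(s$eic, 0.3923174, tolerance = 1e-6)
  expect_equal(s$vic, 0.1316421, tolerance = 1e-6)
  expect_equal(s$ic025, -0.3333330, tolerance = 1e-6)
  expect_false(s$bcpnn_positive)

  expect_equal(s$ebgm, 4 / 3, tolerance = 1e-12)
  expect_equal(s$ebgm05, 0.4557303, tolerance = 1e-6)
  expect_false(s$mgps_positive)

  expect_false(s$consensus_positive)
})

test_that("balanced and independent tables are calibrated at the null", {
  s <- disproportionality_stats(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1)
  expect_equal(s$chisq, 0)
  expect_false(any(s$ror_positive, s$prr_positive, s$bcpnn_positive,
                   s$mgps_positive))
  # independence with unequal margins: a/(a+b) == c/(c+d)
  s2 <- disproportionality_stats(30, 60, 20, 40)
  expect_equal(s2$prr, 1)
  expect_equal(s2$ror, 1)
  expect_equal(s2$ebgm, 1, tolerance = 1e-12)
  expect_equal(s2$chisq, 0)
})

test_that("the shared a >= 3 gate blocks small counts however elevated", {
  s <- disproportionality_stats(2, 1, 1, 10000)
  expect_false(s$ror_positive)
  expect_false(s$prr_positive)
  expect_false(s$consensus_positive)
})

test_that("zero cells leave frequentist statistics undefined, not corrected", {
  s <- disproportionality_stats(5, 0, 10, 100)
  expect_false(s$ror_defined)
  expect_true(is.na(s$ror))
  expect_true(is.na(s$ebgm05))
  expect_false(s$ror_positive)
  expect_false(s$mgps_positive)
  s0 <- disproportionality_stats(0, 10, 10, 100)
  expect_equal(s0$ebgm, 0)
  expect_false(s0$mgps_positive)
})

test_that("BCPNN shrinkage has the empty-table fixed point and vanishes
           in the large-N independence limit", {
  s <- disproportionality_stats(0, 0, 0, 0)
  expect_equal(s$gamma, 4)
  expect_equal(s$eic, 0)
  big <- disproportionality_stats(1000, 1000, 1000, 1000)
  expect_lt(abs(big$eic), 0.01)
})

test_that("consensus is the conjunction of the four criteria", {
  r <- evaluate_consensus(tibble::tibble(a = 20, b = 10, c = 10, d = 20))
  expect_equal(r$results$algorithm, c("ROR", "PRR", "BCPNN", "MGPS"))
  expect_equal(r$results$positive, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(r$consensus_positive)

  strong <- evaluate_consensus(tibble::tibble(a = 100, b = 10, c = 100,
                                              d = 10000))
  expect_true(all(strong$results$positive))
  expect_true(strong$consensus_positive)

  small <- evaluate_consensus(tibble::tibble(a = 2, b = 1, c = 1, d = 10000))
  expect_false(small$consensus_positive)
})

test_that("every statistic matches the independent oracle on 1000 random
           tables to relative error < 1e-12", {
  withr::with_seed(4711, {
    cells <- matrix(sample(0:500, 4000, replace = TRUE), ncol = 4)
  })
  s <- disproportionality_stats(cells[, 1], cells[, 2], cells[, 3],
                                cells[, 4])
  worst <- 0
  for (i in seq_len(nrow(cells))) {
    o <- oracle_stats(cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4])
    errs <- c(
      rel_err(s$ror[i], o$ror), rel_err(s$ror_lower[i], o$ror_lower),
      rel_err(s$ror_upper[i], o$ror_upper),
      rel_err(s$prr[i], o$prr), rel_err(s$chisq[i], o$chisq),
      rel_err(s$prr_lower[i], o$prr_lower),
      rel_err(s$prr_upper[i], o$prr_upper),
      rel_err(s$gamma[i], o$gamma), rel_err(s$eic[i], o$eic),
      rel_err(s$vic[i], o$vic), rel_err(s$ic025[i], o$ic025),
      rel_err(s$ebgm[i], o$ebgm), rel_err(s$ebgm05[i], o$ebgm05)
    )
    worst <- max(worst, errs, na.rm = TRUE)
  }
  expect_lt(worst, 1e-12)
})

test_that("chi-squared agrees with stats::chisq.test without correction", {
  withr::with_seed(99, {
    cells <- matrix(sample(1:300, 200, replace = TRUE), ncol = 4)
  })
  s <- disproportionality_stats(cells[, 1], cells[, 2], cells[, 3],
                                cells[, 4])
  for (i in seq_len(nrow(cells))) {
    m <- matrix(cells[i, ], nrow = 2, byrow = TRUE)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
    expect_equal(s$chisq[i], unname(ref), tolerance = 1e-10)
  }
})

test_that("increasing a with b, c, d fixed strictly increases all four
           point estimates in the rare-event screening regime", {
  # ROR and PRR are strictly increasing in a unconditionally. EBGM and the
  # information component are relative-reporting ratios whose margins grow
  # with a, so strict monotonicity requires the co-occurrence count to be
  # small against both margins (b, c >= 2a here) - the regime in which
  # drug-event screening operates.
  withr::with_seed(7, {
    for (k in 1:100) {
      a <- sample(1:50, 1)
      b <- 2 * a + sample(1:200, 1)
      c <- 2 * a + sample(1:200, 1)
      d <- sample(1:10000, 1)
      s1 <- disproportionality_stats(a, b, c, d)
      s2 <- disproportionality_stats(a + 1, b, c, d)
      expect_gt(s2$ror, s1$ror)
      expect_gt(s2$prr, s1$prr)
      expect_gt(s2$ebgm, s1$ebgm)
      expect_gt(s2$eic, s1$eic)
    }
  })
  # outside that regime the ratio statistics are not monotone: growing
  # margins can pull EBGM down even as a rises
  lo <- disproportionality_stats(10, 10, 10, 10000)
  hi <- disproportionality_stats(11, 10, 10, 10000)
  expect_lt(hi$ebgm, lo$ebgm)
  expect_gt(hi$ror, lo$ror)
})

test_that("screening renders two-decimal display columns", {
  fx <- fixture_five_reports()
  tabs <- enumerate_tables(fx$target, fx$background, "drugX",
                           level = "PT", min_a = 1)
  sig <- screen_signals(tabs)
  expect_equal(nrow(sig), 2)
  expect_true(all(c("frequency", "ror_ci", "prr_chisq", "ebgm_ebgm05",
                    "ic_ic025", "consensus_positive") %in% names(sig)))
  # formatting analogue: 6.0825 with CI (5.5603, 6.6437)
  expect_equal(unname(faersignal:::fmt_interval(6.0825, 5.5603, 6.6437)),
               "6.08 (5.56–6.64)")
  expect_equal(unname(faersignal:::fmt_stat(40653.321)), "40,653.32")
  expect_equal(nrow(screen_signals(tabs[0, ])), 0)
})

test_that("threshold and quantile overrides propagate", {
  # EBGM05 with z = 1.645 is larger than with 1.96
  s196 <- disproportionality_stats(20, 10, 10, 20)
  s164 <- disproportionality_stats(20, 10, 10, 20, z_ebgm = 1.645)
  expect_gt(s164$ebgm05, s196$ebgm05)
  # loosening the EBGM05 criterion can only add positives
  strong <- disproportionality_stats(40, 10, 40, 4000)
  loose <- disproportionality_stats(40, 10, 40, 4000, ebgm05_min = 1)
  expect_true(loose$mgps_positive >= strong$mgps_positive)
})
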