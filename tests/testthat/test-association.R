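test_that("continuity-corrected chi-square reproduces the published pairwise statistics", {
  expect_equal(round(chi2_2x2(contingency_2x2(105, 52, 60, 103))$statistic, 2), 27.76)
  expect_equal(round(chi2_2x2(contingency_2x2(105, 52, 106, 123))$statistic, 2), 15.11)
  expect_equal(round(chi2_2x2(contingency_2x2(106, 123, 60, 103))$statistic, 2), 3.13)
  # proportional table: the clamp keeps the corrected statistic at zero
  expect_equal(chi2_2x2(contingency_2x2(10, 10, 10, 10))$statistic, 0)
  expect_error(chi2_2x2(contingency_2x2(0, 0, 5, 5)), "margin")
})

test_that("corrected statistic agrees with the expected-count Yates formulation on random tables", {
  set.seed(101)
  n_tab <- 10000L
  for (i in seq_len(n_tab)) {
    m <- matrix(sample.int(60, 4, replace = TRUE), 2)
    got <- chi2_2x2(m)$statistic
    ref <- yates_oracle(m)
    expect_true(abs(got - ref) <= 1e-10 * max(1, ref))
    # correction never increases the statistic
    expect_lte(got, chi2_2x2(m, continuity = FALSE)$statistic + 1e-12)
  }
})

test_that("chi-square is invariant under joint row/column swap and RR inverts under row swap", {
  set.seed(202)
  for (i in 1:50) {
    m <- matrix(sample.int(40, 4, replace = TRUE), 2)
    swapped <- m[2:1, 2:1]
    expect_equal(chi2_2x2(swapped)$statistic, chi2_2x2(m)$statistic)
    rowswap <- m[2:1, ]
    expect_equal(relative_risk(rowswap)$rr, 1 / relative_risk(m)$rr)
  }
})

test_that("prevalence reports counts and the published percentage", {
  fx <- fixture_bundle()
  p <- prevalence(fx$dogs)
  expect_equal(p$n_affected, 394L)
  expect_equal(p$n_total, 799L)
  expect_equal(p$percent, 49.31)
  expect_equal(prevalence(data.frame(status = rep("unaffected", 10)))$percent, 0)
  expect_equal(round(100 * 271 / 549, 2), 49.36)
  expect_error(prevalence(fx$dogs[0, ]), "empty")
})

test_that("sex association reproduces the published test and vanishes for equal risks", {
  fx <- fixture_bundle()
  res <- sex_association(fx$dogs)
  expect_equal(round(res$statistic, 4), 6.7599)
  expect_equal(round(res$p_value, 4), 0.0093)
  expect_equal(unname(res$table["male", ]), c(121, 161))
  expect_equal(unname(res$table["female", ]), c(273, 244))

  eq <- data.frame(sex = rep(c("male", "female"), each = 20),
                   status = rep(rep(c("affected", "unaffected"), each = 10), 2))
  expect_equal(sex_association(eq)$statistic, 0)
  expect_error(sex_association(data.frame(sex = "male", status = "affected")),
               "both sexes")
})

test_that("omnibus 2x3 test matches an independent Pearson computation", {
  fx <- fixture_bundle()
  res <- omnibus_association(fx$mating)
  expect_equal(res$df, 2L)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$statistic, 30.412978, tolerance = 1e-6)
  ref <- suppressWarnings(stats::chisq.test(unclass(fx$mating), correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  flat <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2)
  expect_equal(omnibus_association(flat)$statistic, 0)
})

test_that("relative risks match the published values", {
  expect_equal(relative_risk(contingency_2x2(106, 123, 60, 103))$rr_rounded, 1.3)
  expect_equal(relative_risk(contingency_2x2(105, 52, 60, 103))$rr_rounded, 1.8)
  expect_equal(relative_risk(contingency_2x2(105, 52, 106, 123))$rr_rounded, 1.4)
  expect_equal(relative_risk(contingency_2x2(5, 5, 10, 10))$rr, 1.0)
  expect_error(relative_risk(contingency_2x2(3, 4, 0, 7)), "undefined")
})

test_that("continuity-corrected risk-difference intervals match the published table", {
  ci1 <- risk_difference_ci(contingency_2x2(106, 123, 60, 103))
  expect_equal(ci1$rounded, c(-0.01, 0.20))
  ci2 <- risk_difference_ci(contingency_2x2(105, 52, 60, 103))
  expect_equal(ci2$rounded, c(0.19, 0.41))
  ci3 <- risk_difference_ci(contingency_2x2(105, 52, 106, 123))
  expect_equal(ci3$rounded, c(0.10, 0.31))

  sym <- risk_difference_ci(contingency_2x2(12, 28, 12, 28))
  expect_equal(sym$lower, -sym$upper)
  expect_error(risk_difference_ci(contingency_2x2(1, 1, 1, 1), level = 1.2),
               "level")
})

test_that("all pairwise statistics derive from one mating-type table object", {
  fx <- fixture_bundle()
  cm <- mating_comparisons(fx$mating)
  expect_equal(cm$statistic_2dp, c(3.13, 15.11, 27.76))
  expect_equal(cm$rr_1dp, c(1.3, 1.4, 1.8))
  expect_equal(cm$rd_upper_2dp, c(0.20, 0.31, 0.41))
  expect_equal(cm$rd_lower_2dp, c(-0.01, 0.10, 0.19))
  expect_equal(round(cm$p_value[1], 2), 0.08)
  # corrected statistic 15.11 gives p = 1.01e-4, i.e. 1.0e-4 at two
  # significant digits
  expect_lt(cm$p_value[2], 1.05e-4)
  expect_lt(cm$p_value[3], 1.4e-7)
})
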