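test_that("specific growth rate is the log ratio per unit time", {
  expect_equal(specific_growth_rate(1000, 1000, 3), 0)
  expect_equal(specific_growth_rate(1000, 2000, 1), log(2))
  expect_equal(specific_growth_rate(1000, 87550, 4), log(87.55) / 4)
  expect_equal(round(specific_growth_rate(1000, 87550, 4), 3), 1.118)
  expect_error(specific_growth_rate(0, 10, 1),
               class = "soilBONCAT_undefined_rate")
  expect_error(specific_growth_rate(10, -1, 1),
               class = "soilBONCAT_undefined_rate")
})

test_that("required doubling time inverts exponential growth", {
  expect_equal(required_doubling_time(1000, 2000, 1), 1)
  expect_equal(round(required_doubling_time(1000, 87550, 4), 2), 0.62)
  # strictly decreasing in n2
  n2s <- c(2000, 4000, 10000, 87550)
  tds <- vapply(n2s, function(n2) required_doubling_time(1000, n2, 4),
                numeric(1))
  expect_true(all(diff(tds) < 0))
  expect_error(required_doubling_time(1000, 1000, 1),
               class = "soilBONCAT_no_growth")
  expect_error(required_doubling_time(1000, 500, 1),
               class = "soilBONCAT_no_growth")
})

test_that("generation times convert to hourly proportional increases", {
  expect_equal(hourly_rate_from_generation_time(1), 1)
  expect_equal(hourly_rate_from_generation_time(1 / 3), 7) # 2^3 - 1
  expect_equal(hourly_rate_from_generation_time(7.2), 2^(1 / 7.2) - 1)
  expect_equal(round(hourly_rate_from_generation_time(7.2), 4), 0.1011)
})

test_that("bundled reference rates are the literature anchors", {
  refs <- reference_rates()
  expect_setequal(refs$label,
                  c("e_coli_culture", "rhizosphere", "bulk_forest_soil"))
  expect_equal(refs$generation_time[refs$label == "e_coli_culture"], 1 / 3)
  expect_equal(refs$generation_time[refs$label == "rhizosphere"], 7.2)
  expect_equal(refs$generation_time[refs$label == "bulk_forest_soil"],
               14.1 * 24)
  expect_equal(refs$hourly_rate[refs$label == "e_coli_culture"], 7)
})

test_that("replication attribution is self-consistent and monotone", {
  # at the required doubling time, replication explains exactly everything
  td <- required_doubling_time(1000, 87550, 4)
  expect_equal(replication_attribution(1000, 87550, 4, td), 1)
  # rhizosphere reference on the same interval: well below 1%
  a <- replication_attribution(1000, 87550, 4, 7.2)
  expect_equal(a, (2^(4 / 7.2) - 1) * 1000 / 86550)
  expect_lt(a, 0.01)
  # slower reference -> smaller attribution
  tgens <- c(0.62, 2, 7.2, 24, 14.1 * 24)
  as <- vapply(tgens, function(tg)
    replication_attribution(1000, 87550, 4, tg), numeric(1))
  expect_true(all(diff(as) < 0))
  expect_error(replication_attribution(1000, 900, 4, 7.2),
               class = "soilBONCAT_no_growth")
})

test_that("delta-method SE propagates replicate-mean uncertainty", {
  expect_equal(propagate_se_mu(100, 0, 200, 0, 4), 0)
  # se/n = 0.1 on both ends, dt = 4 -> sqrt(0.02)/4
  expect_equal(propagate_se_mu(100, 10, 200, 20, 4), sqrt(0.02) / 4)
  expect_equal(round(propagate_se_mu(100, 10, 200, 20, 4), 4), 0.0354)
  expect_equal(propagate_se_mu(100, 10, 200, 20, 8),
               propagate_se_mu(100, 10, 200, 20, 4) / 2)
})

test_that("interval classification follows the cutoff rules", {
  # the printed glucose 2-6 h numbers: fast doubling, tiny attribution
  expect_equal(classify_interval(0.62, 0.0054, 7.2), "activation-dominated")
  expect_equal(classify_interval(0.3, 0.5, 7.2), "activation-dominated")
  expect_equal(classify_interval(20, 1.5, 7.2), "replication-plausible")
  expect_equal(classify_interval(2, 0.3, 7.2), "indeterminate")
  expect_equal(classify_interval(NA_real_, NA_real_, 7.2), "indeterminate")
})

test_that("noiseless exponential series give exact kinetics on every interval", {
  t_gen <- 3.7
  times <- c(2, 6, 12, 24)
  n0 <- 1e4
  counts <- tibble::tibble(
    treatment = "exp", time_h = rep(times, each = 2),
    active_cells_per_g = rep(n0 * 2^(times / t_gen), each = 2))
  gt <- growth_table(counts, reference_tgen = t_gen)
  expect_equal(gt$required_doubling_time, rep(t_gen, 3), tolerance = 1e-12)
  expect_equal(gt$replication_attribution, rep(1, 3), tolerance = 1e-12)
  expect_equal(gt$se_mu, rep(0, 3))
  # consistency: hourly fold change matches 2^(1/td) - 1
  expect_equal(gt$hourly_fold_change,
               2^(1 / gt$required_doubling_time) - 1)
  # and equals the per-hour ratio form
  expect_equal(gt$hourly_fold_change,
               (gt$n2 / gt$n1)^(1 / (gt$t2 - gt$t1)) - 1)
})

test_that("zero or shrinking intervals are flagged, not dropped", {
  counts <- tibble::tibble(
    treatment = "w", time_h = rep(c(2, 6, 12), each = 2),
    active_cells_per_g = c(0, 0, 50, 50, 40, 40))
  gt <- growth_table(counts)
  expect_equal(nrow(gt), 2)
  expect_true(all(gt$undefined))
  expect_true(all(gt$interval_class == "indeterminate"))
  expect_true(all(is.na(gt$required_doubling_time)))
})
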