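test_that("scatter gate bounds come from nearest-rank quantiles", {
  ev <- manual_events(fsc = 1:5, ssc = 1:5, fitc = rep(1, 5), apc = rep(1, 5))
  g0 <- fit_scatter_gate(ev, 0, 1)
  gates0 <- gate_set(g0, syto_threshold = 0, boncat_threshold = 0)
  expect_equal(apply_gates(ev, gates0)$n_events_total, 5)

  g <- fit_scatter_gate(ev, 0.2, 0.8)
  # nearest rank on 1..5: ceil(0.2*5)=1 -> 1, ceil(0.8*5)=4 -> 4
  expect_equal(g$fsc, c(1, 4))
  # in-gate count matches a linear scan
  oracle <- sum(ev$fsc >= g$fsc[1] & ev$fsc <= g$fsc[2] &
                  ev$ssc >= g$ssc[1] & ev$ssc <= g$ssc[2])
  gates <- gate_set(g, syto_threshold = 0, boncat_threshold = 0)
  expect_equal(apply_gates(ev, gates)$n_events_total, oracle)
  # refitting on an identical copy changes nothing
  expect_equal(apply_gates(ev, gate_set(fit_scatter_gate(ev, 0.2, 0.8),
                                        0, 0))$n_events_total, oracle)

  expect_error(fit_scatter_gate(ev[0, ], 0, 1),
               class = "soilBONCAT_insufficient_data")
  expect_error(fit_scatter_gate(ev, 0.8, 0.2),
               class = "soilBONCAT_invalid_parameter")
})

test_that("thresholds are control-anchored nearest-rank quantiles", {
  const <- manual_events(rep(1, 4), rep(1, 4), rep(1, 4), apc = rep(10, 4),
                         role = "killed_control")
  for (q in c(0.1, 0.5, 0.999)) {
    expect_equal(derive_threshold(const, "apc", q), 10)
  }
  perm <- sample(1000L)
  killed <- manual_events(rep(1, 1000), rep(1, 1000), rep(1, 1000),
                          apc = perm, role = "killed_control")
  # sort-based oracle for the nearest-rank quantile
  expect_equal(derive_threshold(killed, "apc", 0.999),
               sort(perm)[ceiling(0.999 * 1000)])
  # raising the quantile never lowers the threshold
  qs <- c(0.5, 0.9, 0.99, 0.999, 1)
  thr <- vapply(qs, function(q) derive_threshold(killed, "apc", q), numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("threshold derivation enforces control roles and data presence", {
  samp <- manual_events(1, 1, 1, 1)
  expect_error(derive_threshold(samp, "apc"),
               class = "soilBONCAT_invalid_parameter")
  hpg <- manual_events(rep(1, 3), rep(1, 3), fitc = c(5, 6, 7),
                       apc = c(1, 1, 1), role = "hpg_negative_control")
  # no SYTO+ events above the threshold -> insufficient data
  expect_error(derive_threshold(hpg, "fitc", restrict_to_syto_pos = TRUE,
                                syto_threshold = 10),
               class = "soilBONCAT_insufficient_data")
  expect_error(derive_threshold(hpg, "fitc", restrict_to_syto_pos = TRUE),
               class = "soilBONCAT_invalid_parameter")
})

test_that("apply_gates matches a hand-enumerated six-event table", {
  # events: (in scatter?, syto+?, boncat+?)
  ev <- manual_events(
    fsc = c(10, 10, 10, 10, 100, 1),  # last two outside scatter [5, 50]
    ssc = c(10, 10, 10, 10, 10, 10),
    fitc = c(500, 5, 500, 5, 500, 500),
    apc = c(100, 100, 2, 2, 100, 100))
  gates <- gate_set(structure(list(fsc = c(5, 50), ssc = c(5, 50)),
                              class = "scatter_gate"),
                    syto_threshold = 10, boncat_threshold = 50)
  got <- apply_gates(ev, gates)
  oracle <- scan_oracle(ev, gates)
  expect_equal(got$n_events_total, 4)
  expect_equal(got$n_syto_pos, 2)
  expect_equal(got$n_boncat_pos, 1)
  expect_equal(got[c("n_events_total", "n_syto_pos", "n_boncat_pos")],
               oracle[c("n_events_total", "n_syto_pos", "n_boncat_pos")],
               ignore_attr = TRUE)
})

test_that("gate-count edge rules hold", {
  ev <- manual_events(numeric(0), numeric(0), numeric(0), numeric(0))
  gates <- gate_set(NULL, 0, 0)
  got <- apply_gates(ev, gates)
  expect_equal(c(got$n_events_total, got$n_syto_pos, got$n_boncat_pos),
               c(0, 0, 0))
  ev2 <- manual_events(1:3, 1:3, c(10, 20, 30), c(10, 20, 30))
  expect_equal(apply_gates(ev2, gate_set(NULL, Inf, 0))$n_syto_pos, 0)
  # events exactly at a threshold count as negative
  expect_equal(apply_gates(ev2, gate_set(NULL, 30, 0))$n_syto_pos, 0)
  expect_equal(apply_gates(ev2, gate_set(NULL, 0, 30))$n_boncat_pos, 0)
  expect_equal(apply_gates(ev2, gate_set(NULL, 0, 15))$n_boncat_pos, 2)
})

test_that("gate counts equal the linear-scan oracle on random tables", {
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(0:2000, 1)
      ev <- manual_events(rlnorm(n, 9, 1), rlnorm(n, 9, 1),
                          rlnorm(n, 4, 1.5), rlnorm(n, 4, 1.5))
      gates <- gate_set(
        structure(list(fsc = exp(9 + runif(2) * c(-2, 2)) |> sort(),
                       ssc = exp(9 + runif(2) * c(-2, 2)) |> sort()),
                  class = "scatter_gate"),
        syto_threshold = rlnorm(1, 4, 1), boncat_threshold = rlnorm(1, 4, 1))
      got <- apply_gates(ev, gates)
      oracle <- scan_oracle(ev, gates)
      expect_identical(got$n_events_total, oracle$n_events_total)
      expect_identical(got$n_syto_pos, oracle$n_syto_pos)
      expect_identical(got$n_boncat_pos, oracle$n_boncat_pos)
    }
  })
})

test_that("raising any threshold never increases any positive count", {
  withr::with_seed(7, {
    ev <- manual_events(rlnorm(500, 9, 1), rlnorm(500, 9, 1),
                        rlnorm(500, 4, 1.5), rlnorm(500, 4, 1.5))
  })
  syto_grid <- quantile(ev$apc, c(0.1, 0.3, 0.5, 0.7, 0.9))
  boncat_grid <- quantile(ev$fitc, c(0.1, 0.3, 0.5, 0.7, 0.9))
  syto_counts <- vapply(syto_grid, function(s)
    apply_gates(ev, gate_set(NULL, s, 0))$n_syto_pos, numeric(1))
  expect_true(all(diff(syto_counts) <= 0))
  boncat_counts <- vapply(boncat_grid, function(b)
    apply_gates(ev, gate_set(NULL, 0, b))$n_boncat_pos, numeric(1))
  expect_true(all(diff(boncat_counts) <= 0))
})

test_that("background subtraction applies the zeroing and clamping rules", {
  gates <- gate_set(NULL, 0, 0, syto_background_events = 20,
                    boncat_background_events = 5)
  s <- structure(list(n_events_total = 600, n_syto_pos = 500,
                      n_boncat_pos = 50, batch_id = "batch1"),
                 class = "gated_counts")
  got <- subtract_background(s, gates)
  expect_equal(got$total_events_corrected, 480)
  expect_equal(got$active_events_corrected, 45)
  expect_false(got$zeroed_active)
  expect_false(got$clamped_total)

  # boncat equal to background -> zero active, flagged
  s$n_boncat_pos <- 5
  z <- subtract_background(s, gates)
  expect_equal(z$active_events_corrected, 0)
  expect_true(z$zeroed_active)

  # syto below background -> total clamped to zero, and active <= total
  s2 <- structure(list(n_events_total = 30, n_syto_pos = 10,
                       n_boncat_pos = 30, batch_id = "batch1"),
                  class = "gated_counts")
  gates2 <- gate_set(NULL, 0, 0, syto_background_events = 25,
                     boncat_background_events = 1)
  c2 <- subtract_background(s2, gates2)
  expect_equal(c2$total_events_corrected, 0)
  expect_true(c2$clamped_total)
  expect_lte(c2$active_events_corrected, c2$total_events_corrected)
})

test_that("derive_gates builds a usable per-batch gate set", {
  ctl <- simulate_controls(sep_truth(), small_acq(), seed = 21,
                           batch_id = "b7")
  gates <- derive_gates(ctl$killed, ctl$hpg_negative)
  expect_s3_class(gates, "gate_set")
  expect_identical(gates$batch_id, "b7")
  expect_true(is.finite(gates$syto_threshold))
  expect_true(is.finite(gates$boncat_threshold))
  expect_gte(gates$syto_background_events, 0)
  expect_gte(gates$boncat_background_events, 0)
  # the SYTO threshold from a killed control sits above particle APC bulk
  expect_gt(gates$syto_threshold, exp(log(20)))
})
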