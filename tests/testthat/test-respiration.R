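test_that("calibration recovers exact lines", {
  std <- tibble::tibble(reading = c(0, 1, 2, 3),
                        known_micromol = 2 * c(0, 1, 2, 3))
  cv <- fit_co2_calibration(std)
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$n_standards, 4)

  std2 <- tibble::tibble(reading = c(10, 20, 40),
                         known_micromol = 1 + 0.5 * c(10, 20, 40))
  cv2 <- fit_co2_calibration(std2)
  expect_equal(cv2$slope, 0.5, tolerance = 1e-12)
  expect_equal(cv2$intercept, 1, tolerance = 1e-12)
})

test_that("calibration rejects degenerate standards", {
  expect_error(fit_co2_calibration(
    tibble::tibble(reading = 5, known_micromol = 1)),
    class = "soilBONCAT_insufficient_data")
  expect_error(fit_co2_calibration(
    tibble::tibble(reading = c(5, 5, 5), known_micromol = c(1, 2, 3))),
    class = "soilBONCAT_singular_fit")
})

test_that("respiration rate applies calibration, ambient and clamping", {
  cv <- fit_co2_calibration(
    tibble::tibble(reading = c(0, 500, 1000), known_micromol = c(0, 1, 2)))
  # reading mapping to 1.02 umol, ambient 0.02, 1 g, 2 h -> 0.5 umol/g/h
  rr <- respiration_rate(510, cv, 0.02, dry_mass = 1, accumulation_h = 2)
  expect_equal(rr$rate, 0.5)
  expect_equal(rr$corrected_micromol, 1.0)
  expect_false(rr$clamped)
  # reading mapping exactly to ambient -> zero
  expect_equal(respiration_rate(10, cv, 0.02, 1, 2)$rate, 0)
  # reading below ambient -> clamped zero
  low <- respiration_rate(5, cv, 0.02, 1, 2)
  expect_equal(low$rate, 0)
  expect_true(low$clamped)
  bad <- structure(list(slope = 1, intercept = 0, n_standards = 1),
                   class = "calibration_curve")
  expect_error(respiration_rate(10, bad, 0, 1, 1),
               class = "soilBONCAT_invalid_parameter")
})

test_that("rate scales linearly in content and inversely in mass and time", {
  cv <- fit_co2_calibration(
    tibble::tibble(reading = c(0, 1000), known_micromol = c(0, 2)))
  r1 <- respiration_rate(500, cv, 0, 1, 1)$rate
  expect_equal(respiration_rate(1000, cv, 0, 1, 1)$rate, 2 * r1)
  expect_equal(respiration_rate(500, cv, 0, 2, 1)$rate, r1 / 2)
  expect_equal(respiration_rate(500, cv, 0, 1, 4)$rate, r1 / 4)
})

test_that("noiseless headspace round trip is the identity on the rate", {
  acq <- acquisition_settings(dry_soil_mass = 1.13)
  for (rate in c(0, 0.17, 0.5, 2.4)) {
    hs <- simulate_headspace(rate, acq, accumulation_h = 2,
                             ambient_micromol = 0.17, noise_sd = 0)
    cv <- fit_co2_calibration(hs$standards)
    ambient <- calibrate_micromol(cv, hs$ambient_reading)
    got <- respiration_rate(hs$reading, cv, ambient, acq$dry_soil_mass, 2)
    expect_equal(got$rate, rate, tolerance = 1e-10)
  }
})

test_that("amendment arithmetic reproduces the MicroResp convention", {
  # 100 uL of 3 mol C/L glucose into 1.2 g moist / 1.0 g dry soil
  conc <- substrate_concentration(100, 3, 6, 180.16, 1.2, 1.0)
  expect_equal(conc, (100e-6 * 3 / 6 * 180.16 * 1000) / 0.3)
  expect_equal(conc, 30, tolerance = 0.002)
  # galactose is an isomer: same stoichiometry, same concentration
  expect_equal(substrate_concentration(100, 3, 6, 180.16, 1.2, 1.0), conc)
  expect_equal(substrate_concentration(100, 0, 6, 180.16, 1.2, 1.0), 0)
  expect_error(substrate_concentration(100, 3, 6, 180.16, 0.9, 1.0),
               class = "soilBONCAT_invalid_parameter")
})

test_that("gravimetric water content counts field water plus additions", {
  expect_equal(gravimetric_water_content(1.2, 1.0, 100), 30)
  expect_equal(gravimetric_water_content(1.2, 1.0, c(100, 250)), 55)
  expect_equal(gravimetric_water_content(1.0, 1.0), 0)
  expect_error(gravimetric_water_content(0.9, 1.0),
               class = "soilBONCAT_invalid_parameter")
})

test_that("AWHC fractions are reported unrounded", {
  expect_equal(fraction_of_awhc(62.2, 62.2), 100)
  expect_equal(fraction_of_awhc(30, 62.2), 100 * 30 / 62.2) # 48.2%
  expect_equal(fraction_of_awhc(55, 62.2), 100 * 55 / 62.2) # 88.4%
  expect_equal(round(fraction_of_awhc(30, 62.2), 1), 48.2)
  expect_equal(round(fraction_of_awhc(55, 62.2), 1), 88.4)
})
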