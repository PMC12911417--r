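#' Fit the CO2 calibration curve
#'
#' Ordinary least-squares line mapping detector reading to micromoles CO2,
#' fitted on standards of known CO2 content. The detector's response over
#' the standards' range is treated as linear; the reading unit is whatever
#' the standards table uses (the fit is unit-agnostic).
#'
#' @param standards Tibble/data frame with columns `known_micromol` and
#'   `reading`, at least two distinct readings.
#' @return An object of class `calibration_curve`: `slope` (umol per
#'   detector unit), `intercept` (umol), `r_squared`, `n_standards`.
#' @examples
#' std <- tibble::tibble(known_micromol = c(0, 2, 4), reading = c(0, 1, 2))
#' fit_co2_calibration(std) # slope 2, intercept 0
#' @export
fit_co2_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("known_micromol", "reading") %in% names(standards)))
  if (nrow(standards) < 2L) {
    abort("need at least two calibration standards",
          class = "soilBONCAT_insufficient_data")
  }
  if (length(unique(standards$reading)) < 2L) {
    abort("all standard readings identical: calibration fit is singular",
          class = "soilBONCAT_singular_fit")
  }
  fit <- lm(known_micromol ~ reading, data = standards)
  # summary.lm warns on noiseless (exactly collinear) standards; harmless here
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_standards = nrow(standards)),
            class = "calibration_curve")
}

#' Convert a calibration curve to micromoles
#' @param curve A `calibration_curve`.
#' @param reading Detector reading(s).
#' @return Micromoles CO2.
#' @export
calibrate_micromol <- function(curve, reading) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$intercept + curve$slope * reading
}

#' Headspace reading to per-gram respiration rate
#'
#' Maps the detector reading through the calibration curve, subtracts the
#' ambient CO2 recorded for the measurement session, clamps negative
#' corrected contents to zero (flagged), and divides by soil mass and the
#' sealed accumulation time.
#'
#' @param reading Detector reading for the tube headspace.
#' @param curve A [fit_co2_calibration()] result.
#' @param ambient_micromol Ambient CO2, umol, subtracted from the headspace
#'   content.
#' @param dry_mass Dry soil mass, g.
#' @param accumulation_h Sealed accumulation time, hours.
#' @return A list of class `respiration_result`: `headspace_micromol`,
#'   `ambient_micromol`, `corrected_micromol`, `rate` (umol CO2 per g dry
#'   soil per h), `accumulation_h`, `clamped`.
#' @examples
#' std <- tibble::tibble(known_micromol = c(0, 1, 2), reading = c(0, 500, 1000))
#' cv <- fit_co2_calibration(std)
#' respiration_rate(510, cv, ambient_micromol = 0.02,
#'                  dry_mass = 1, accumulation_h = 2)$rate # 0.5
#' @export
respiration_rate <- function(reading, curve, ambient_micromol, dry_mass,
                             accumulation_h) {
  if (!inherits(curve, "calibration_curve") || curve$n_standards < 2L) {
    abort("`curve` must be a calibration_curve fitted on >= 2 standards",
          class = "soilBONCAT_invalid_parameter")
  }
  assert_nonneg(ambient_micromol, "ambient_micromol")
  assert_positive(dry_mass, "dry_mass")
  assert_positive(accumulation_h, "accumulation_h")
  headspace <- calibrate_micromol(curve, reading)
  corrected <- headspace - ambient_micromol
  clamped <- corrected < 0
  corrected <- max(0, corrected)
  structure(list(headspace_micromol = headspace,
                 ambient_micromol = ambient_micromol,
                 corrected_micromol = corrected,
                 rate = corrected / (dry_mass * accumulation_h),
                 accumulation_h = accumulation_h, clamped = clamped),
            class = "respiration_result")
}

#' Substrate concentration per gram soil water
#'
#' Amendment arithmetic for carbon-normalized substrate solutions: the
#' substrate mass delivered by the added solution divided by the soil water
#' present after addition (field water plus the solution itself, density
#' 1 g/mL). With 100 uL of a 3 mol C/L glucose solution added to 1.2 g
#' field-moist (1.0 g dry) soil this gives the 30 mg glucose per g soil
#' water convention of substrate-induced-respiration assays.
#'
#' @param solution_volume Added solution volume, uL.
#' @param carbon_molarity Carbon concentration of the solution, mol C per L.
#' @param carbons_per_molecule Carbon atoms per substrate molecule (6 for
#'   glucose and galactose).
#' @param molar_mass Substrate molar mass, g/mol (180.16 for glucose).
#' @param field_moist_mass,dry_mass Soil masses, g.
#' @return mg substrate per g soil water.
#' @examples
#' substrate_concentration(100, 3, 6, 180.16, 1.2, 1.0) # ~30
#' @export
substrate_concentration <- function(solution_volume, carbon_molarity,
                                    carbons_per_molecule, molar_mass,
                                    field_moist_mass, dry_mass) {
  assert_positive(solution_volume, "solution_volume")
  assert_nonneg(carbon_molarity, "carbon_molarity")
  assert_positive(carbons_per_molecule, "carbons_per_molecule")
  assert_positive(molar_mass, "molar_mass")
  assert_positive(field_moist_mass, "field_moist_mass")
  assert_positive(dry_mass, "dry_mass")
  if (field_moist_mass < dry_mass) {
    abort("field-moist mass cannot be below dry mass",
          class = "soilBONCAT_invalid_parameter")
  }
  substrate_mg <- solution_volume * 1e-6 * carbon_molarity /
    carbons_per_molecule * molar_mass * 1000
  water_g <- (field_moist_mass - dry_mass) + solution_volume * 1e-6 * 1000
  if (water_g <= 0) {
    abort("no soil water present", class = "soilBONCAT_invalid_parameter")
  }
  substrate_mg / water_g
}

#' Gravimetric water content after liquid additions
#'
#' Water mass per unit oven-dry soil mass, as percent, counting the field
#' water plus any added volumes (density 1 g/mL).
#'
#' @param field_moist_mass,dry_mass Soil masses, g.
#' @param added_volumes Numeric vector of added liquid volumes, uL.
#' @return Gravimetric water content, percent of dry mass.
#' @examples
#' gravimetric_water_content(1.2, 1.0, 100) # 30
#' @export
gravimetric_water_content <- function(field_moist_mass, dry_mass,
                                      added_volumes = numeric()) {
  assert_positive(dry_mass, "dry_mass")
  assert_positive(field_moist_mass, "field_moist_mass")
  if (field_moist_mass < dry_mass) {
    abort("field-moist mass cannot be below dry mass",
          class = "soilBONCAT_invalid_parameter")
  }
  if (any(added_volumes < 0)) {
    abort("added volumes must be non-negative",
          class = "soilBONCAT_invalid_parameter")
  }
  water_g <- (field_moist_mass - dry_mass) + sum(added_volumes) * 1e-6 * 1000
  100 * water_g / dry_mass
}

#' Water content as a fraction of available water-holding capacity
#'
#' @param gwc_pct Gravimetric water content, percent.
#' @param awhc_pct Available water-holding capacity (capillary method),
#'   percent.
#' @return 100 * gwc / awhc, percent of AWHC (unrounded).
#' @examples
#' fraction_of_awhc(30, 62.2) # 48.23
#' @export
fraction_of_awhc <- function(gwc_pct, awhc_pct) {
  assert_nonneg(gwc_pct, "gwc_pct")
  assert_positive(awhc_pct, "awhc_pct")
  100 * gwc_pct / awhc_pct
}
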