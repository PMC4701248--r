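#' @title Daily insulin dose calculator
#' @name dose-calculator
NULL

#' Calculate daily insulin doses from the patient profile
#'
#' Functional component that programs the three pump doses from the patient's
#' current condition. The default formulas are conventional weight-based
#' rules of thumb, stated as this package's defaults and fully configurable:
#' total daily dose TDD = `tdd_factor` U/kg body weight; the basal share
#' `basal_fraction` of TDD is spread uniformly over 24 h; the bolus share is
#' split over `meals_per_day` meals; the corrective bolus is
#' (current glucose - target) / correction factor, with the 1800-rule
#' correction factor 1800/TDD. Outputs are clamped to the pump bounds (basal
#' in \[0.1, 25.0\] U/h, boluses at most 25 U).
#'
#' @param profile A `patient_profile` (weight must be > 0).
#' @param gl Current blood glucose (mg/dL).
#' @param tdd_factor U/kg for the total daily dose (default 0.5).
#' @param basal_fraction Fraction of TDD given as basal (default 0.5).
#' @param meals_per_day Meals over which the bolus share is split (default 3).
#' @param target_gl Correction target (mg/dL, default 100).
#' @return `list(baid =, boid =, cboid =)`: basal rate (U/h), standard bolus
#'   (U) and corrective bolus (U).
#' @export
insulin_dose_calculator <- function(profile, gl,
                                    tdd_factor = 0.5, basal_fraction = 0.5,
                                    meals_per_day = 3, target_gl = 100) {
  if (profile$weight <= 0) stop("insulin_dose_calculator: weight must be > 0")
  tdd <- tdd_factor * profile$weight
  baid <- tdd * basal_fraction / 24
  baid <- min(max(baid, 0.1), 25.0)
  boid <- tdd * (1 - basal_fraction) / meals_per_day
  boid <- min(boid, 25.0)
  correction_factor <- 1800 / tdd
  cboid <- max(gl - target_gl, 0) / correction_factor
  cboid <- min(cboid, 25.0)
  list(baid = baid, boid = boid, cboid = cboid)
}
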