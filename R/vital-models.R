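#' @title Default vital-sign models fitted on a cohort
#' @name vital-models
NULL

#' Fit the default set of vital-sign GLMs on a cohort
#'
#' The respiratory rate is fitted as an inverse-Gaussian GLM (canonical
#' eta = mu^-2) on hr, sbp, pt, gl, the three group dummies and the hr x sbp
#' and hr x gl interactions (10 design columns including the intercept).
#' Heart rate, systolic pressure and temperature are fitted as Gamma GLMs
#' with the canonical inverse link, each regressed on the other three signs,
#' glucose and the group dummies. The fits are packaged as `glm_spec` objects
#' usable by [predict_vital()]; thresholds come from the cohort's observed
#' ranges.
#'
#' @param cohort A cohort tibble (validated: at least 30 rows).
#' @param spec The `cohort_spec` used for validation.
#' @return Named list of `glm_spec` for `rr`, `hr`, `sbp`, `pt`, with the
#'   underlying `mcps_glm` fits attached as attribute `"fits"`.
#' @export
default_vital_models <- function(cohort, spec = cohort_spec()) {
  validate_cohort(cohort, spec)
  d <- as.data.frame(cohort)
  d$group2 <- as.numeric(d$group == 2)
  d$group3 <- as.numeric(d$group == 3)
  d$group4 <- as.numeric(d$group == 4)

  designs <- list(
    rr = rr ~ hr + sbp + pt + gl + group2 + group3 + group4 + hr:sbp + hr:gl,
    hr = hr ~ rr + sbp + pt + gl + group2 + group3 + group4,
    sbp = sbp ~ hr + rr + pt + gl + group2 + group3 + group4,
    pt = pt ~ hr + rr + sbp + gl + group2 + group3 + group4)
  families <- c(rr = "inverse.gaussian", hr = "Gamma", sbp = "Gamma",
                pt = "Gamma")
  links <- c(rr = "inverse.square", hr = "inverse", sbp = "inverse",
             pt = "inverse")
  rounding <- list(rr = 0, hr = 0, sbp = 0, pt = 1)

  fits <- list()
  specs <- list()
  for (sign in names(designs)) {
    fit <- fit_glm_irls(designs[[sign]], d, family = families[[sign]])
    fits[[sign]] <- fit
    specs[[sign]] <- glm_spec(
      response = sign, family = families[[sign]], link = links[[sign]],
      coefficients = fit$coefficients,
      use_absolute = families[[sign]] == "inverse.gaussian",
      round_digits = rounding[[sign]])
  }
  attr(specs, "fits") <- fits
  specs
}
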