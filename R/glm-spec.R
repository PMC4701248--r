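#' @title GLM-based vital-sign generation
#' @description The ICU patient model generates heart rate (hr, beats/min),
#'   respiratory rate (rr, breaths/min), systolic blood pressure (sbp, mmHg),
#'   body temperature (pt, degrees C) and blood glucose (gl, mg/dL) from
#'   per-sign generalized linear models with inverse-Gaussian (eta = mu^-2) or
#'   Gamma (eta = mu^-1) canonical links, followed by optional absolute value,
#'   rounding and threshold clamping.
#' @name patient-vitals
NULL

#' Default per-sign thresholds
#'
#' Minimum/maximum admissible values for each signal; predictions are clamped
#' into these ranges and interventions outside them are rejected. Defaults are
#' the observed ranges of the ICU reference population.
#'
#' @return Named list `list(sign = c(min, max))`.
#' @export
default_sign_thresholds <- function() {
  list(hr = c(40, 150), sbp = c(48, 212), rr = c(8, 38),
       pt = c(31.70, 41.44), gl = c(47, 188))
}

#' Patient profile
#'
#' @param gender `"female"` or `"male"`.
#' @param weight Body weight in kg (admissible range 33-200 unless
#'   `check = FALSE`).
#' @param height Height in cm (admissible range 124.5-231.1).
#' @param group Integer patient-classification group, 1 = baseline. Groups
#'   2-4 switch on the corresponding dummy predictor.
#' @param check Validate demographic ranges (default `TRUE`).
#' @return A `patient_profile`.
#' @export
patient_profile <- function(gender = c("female", "male"), weight = 84.3,
                            height = 169.8, group = 1L, check = TRUE) {
  gender <- match.arg(gender)
  if (check) {
    if (weight < 33 || weight > 200) stop("weight outside [33, 200] kg")
    if (height < 124.5 || height > 231.1) stop("height outside [124.5, 231.1] cm")
  }
  if (!group %in% 1:4) stop("group must be 1 (baseline), 2, 3 or 4")
  structure(list(gender = gender, weight = weight, height = height,
                 group = as.integer(group)), class = "patient_profile")
}

#' Vital-signs state
#'
#' @param hr,rr,sbp,pt,gl Current signal values.
#' @return Named numeric vector of class `vital_state`.
#' @export
vital_state <- function(hr = 87, rr = 19, sbp = 117, pt = 37.3, gl = 119) {
  structure(c(hr = hr, rr = rr, sbp = sbp, pt = pt, gl = gl),
            class = "vital_state")
}

#' Specify one vital sign's regression model
#'
#' @param response Sign the model predicts (`"hr"`, `"rr"`, `"sbp"`, `"pt"`).
#' @param family `"inverse.gaussian"` or `"Gamma"`.
#' @param link `"inverse.square"` (eta = mu^-2, canonical for
#'   inverse-Gaussian) or `"inverse"` (eta = mu^-1, canonical for Gamma).
#' @param coefficients Named numeric vector. Recognised predictor names:
#'   `(Intercept)`, the signs `hr`/`sbp`/`pt`/`gl`, group dummies
#'   `group2`/`group3`/`group4`, and interactions written `a:b`.
#' @param use_absolute Take |eta| before inverting the link (needed when the
#'   fitted linear predictor can cross zero).
#' @param round_digits Round the predicted value to this many digits
#'   (`NULL` = no rounding). Integer-valued signs use 0; body temperature is
#'   conventionally kept at one decimal.
#' @param coefficient_strings Optional character vector preserving the exact
#'   printed decimal form of each coefficient for serialization round trips.
#' @return A `glm_spec`.
#' @export
glm_spec <- function(response, family = c("inverse.gaussian", "Gamma"),
                     link = c("inverse.square", "inverse"),
                     coefficients, use_absolute = FALSE, round_digits = 0,
                     coefficient_strings = NULL) {
  family <- match.arg(family)
  link <- match.arg(link)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("glm_spec: coefficients must be a fully named numeric vector")
  }
  structure(list(response = response, family = family, link = link,
                 coefficients = coefficients, use_absolute = use_absolute,
                 round_digits = round_digits,
                 coefficient_strings = coefficient_strings),
            class = "glm_spec")
}

#' The bundled respiratory-rate model (GLM_RR)
#'
#' Inverse-Gaussian GLM with canonical inverse-square link for the respiratory
#' rate, with the exact published coefficients: main effects hr, sbp, pt, gl,
#' three group dummies, and the hr x sbp and hr x gl interactions. The linear
#' predictor can be negative on realistic inputs, so the absolute value is
#' taken before the link is inverted, and the output is rounded to the nearest
#' integer.
#'
#' @return A `glm_spec` for `rr`.
#' @export
glm_rr <- function() {
  cs <- c("(Intercept)" = "0.002556",
          "hr" = "-0.00005756",
          "sbp" = "0.00005381",
          "pt" = "-0.0001206",
          "gl" = "-0.00001715",
          "group2" = "-0.0009802",
          "group3" = "-0.002567",
          "group4" = "0.001027",
          "hr:sbp" = "-0.0000004994",
          "hr:gl" = "0.0000001579")
  glm_spec("rr", family = "inverse.gaussian", link = "inverse.square",
           coefficients = stats::setNames(as.numeric(cs), names(cs)),
           use_absolute = TRUE, round_digits = 0,
           coefficient_strings = cs)
}

#' Build the predictor vector for a patient state
#'
#' Expands the current vital signs, the profile's group dummies (exactly one
#' dummy is 1, or none in the baseline group) and any `a:b` interaction terms
#' (computed as the product of their factors).
#'
#' @param state A `vital_state`.
#' @param profile A `patient_profile`.
#' @param interactions Character vector of interaction names to materialise,
#'   e.g. `c("hr:sbp", "hr:gl")`.
#' @return Named numeric vector including `(Intercept) = 1`.
#' @export
predictor_vector <- function(state, profile,
                             interactions = c("hr:sbp", "hr:gl")) {
  x <- c("(Intercept)" = 1,
         hr = unname(state[["hr"]]), sbp = unname(state[["sbp"]]),
         pt = unname(state[["pt"]]), gl = unname(state[["gl"]]),
         rr = unname(state[["rr"]]),
         group2 = as.numeric(profile$group == 2L),
         group3 = as.numeric(profile$group == 3L),
         group4 = as.numeric(profile$group == 4L),
         weight = profile$weight, height = profile$height,
         gender_female = as.numeric(profile$gender == "female"))
  for (term in interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(x))) {
      stop("interaction '", term, "' references unknown predictors")
    }
    x[term] <- prod(x[parts])
  }
  x
}

#' Evaluate the linear predictor eta
#'
#' eta = beta0 + sum beta_i X_i over main effects, group dummies and
#' interactions.
#'
#' @param glm A `glm_spec`.
#' @param x Named predictor vector (see [predictor_vector()]).
#' @return The linear predictor value.
#' @export
eval_linear_predictor <- function(glm, x) {
  need <- names(glm$coefficients)
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("missing predictor(s) for ", glm$response, " model: ",
         paste(missing, collapse = ", "))
  }
  sum(glm$coefficients * x[need])
}

#' Invert a canonical link
#'
#' @param link `"inverse.square"` (mu = eta^(-1/2)) or `"inverse"`
#'   (mu = eta^(-1)).
#' @param eta Linear predictor.
#' @param use_absolute Replace eta by |eta| first.
#' @return The mean response mu.
#' @export
apply_inverse_link <- function(link = c("inverse.square", "inverse"), eta,
                               use_absolute = FALSE) {
  link <- match.arg(link)
  if (use_absolute) eta <- abs(eta)
  if (eta == 0) stop("link domain error: eta = 0")
  if (link == "inverse.square") {
    if (eta < 0) stop("link domain error: negative eta with inverse-square link")
    eta^(-1 / 2)
  } else {
    eta^(-1)
  }
}

#' Predict one vital sign
#'
#' Composes linear predictor, inverse link, optional rounding, and clamping
#' into the sign's threshold range.
#'
#' @param glm A `glm_spec`.
#' @param state Current `vital_state` (predictors).
#' @param profile A `patient_profile`.
#' @param thresholds Named list of per-sign `c(min, max)` ranges
#'   (default [default_sign_thresholds()]).
#' @return The predicted sign value, guaranteed inside its range.
#' @export
predict_vital <- function(glm, state, profile,
                          thresholds = default_sign_thresholds()) {
  ints <- grep(":", names(glm$coefficients), fixed = TRUE, value = TRUE)
  x <- predictor_vector(state, profile, interactions = ints)
  eta <- eval_linear_predictor(glm, x)
  mu <- tryCatch(apply_inverse_link(glm$link, eta, glm$use_absolute),
                 error = function(e) {
                   stop("prediction for sign '", glm$response, "' failed: ",
                        conditionMessage(e))
                 })
  if (!is.null(glm$round_digits)) mu <- round(mu, glm$round_digits)
  rng <- thresholds[[glm$response]]
  if (is.null(rng)) stop("no thresholds declared for sign '", glm$response, "'")
  min(max(mu, rng[1]), rng[2])
}

#' Apply a user intervention to one vital sign
#'
#' Holds the intervened sign at the given value and recomputes every other
#' modeled sign once from the post-intervention state (single pass, no
#' fixed-point iteration: mutual model dependence could cycle).
#'
#' @param state Current `vital_state`.
#' @param sign Name of the sign being set.
#' @param value New value; must lie within the sign's thresholds, otherwise the
#'   intervention is rejected with the valid range.
#' @param models List of `glm_spec` objects for the remaining signs.
#' @param profile A `patient_profile`.
#' @param thresholds Per-sign ranges.
#' @return The updated `vital_state`.
#' @export
apply_intervention <- function(state, sign, value, models, profile,
                               thresholds = default_sign_thresholds()) {
  rng <- thresholds[[sign]]
  if (is.null(rng)) stop("unknown sign '", sign, "'")
  if (value < rng[1] || value > rng[2]) {
    stop(sprintf("intervention rejected: %s = %g outside valid range [%g, %g]",
                 sign, value, rng[1], rng[2]))
  }
  new_state <- state
  new_state[[sign]] <- value
  snapshot <- new_state  # all recomputations read the same post-intervention state
  for (m in models) {
    if (m$response == sign) next
    new_state[[m$response]] <- predict_vital(m, snapshot, profile, thresholds)
  }
  new_state
}

#' Serialize a GLM specification to structured text (YAML)
#'
#' Coefficients are written with their exact decimal strings when the spec
#' carries them, so the bundled model round-trips verbatim.
#'
#' @param glm A `glm_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glm_spec <- function(glm, path) {
  co <- if (!is.null(glm$coefficient_strings)) as.list(glm$coefficient_strings)
        else as.list(format(glm$coefficients, digits = 17))
  yaml::write_yaml(list(response = glm$response, family = glm$family,
                        link = glm$link, coefficients = co,
                        use_absolute = glm$use_absolute,
                        round_digits = glm$round_digits), path)
  invisible(path)
}

#' Read a GLM specification from structured text
#' @param path File written by [write_glm_spec()].
#' @return A `glm_spec`.
#' @export
read_glm_spec <- function(path) {
  d <- yaml::read_yaml(path)
  cs <- unlist(d$coefficients)
  glm_spec(d$response, family = d$family, link = d$link,
           coefficients = stats::setNames(as.numeric(cs), names(cs)),
           use_absolute = isTRUE(d$use_absolute),
           round_digits = d$round_digits, coefficient_strings = cs)
}
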