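#' @title Synthetic ICU patient cohort
#' @description Generates patient cohorts whose summary measures (means, SDs,
#'   ranges, female fraction) reproduce the ICU reference population used to
#'   calibrate the vital-sign regression models. Values are drawn from a
#'   truncated multivariate normal (rejection resampling into the per-variable
#'   ranges), which keeps the target moments because the truncation bounds sit
#'   several SDs from each mean.
#' @name cohort
NULL

COHORT_VARS <- c("hr", "sbp", "rr", "pt", "gl", "weight", "height")

default_cohort_targets <- function() {
  tibble::tibble(
    variable = COHORT_VARS,
    mean = c(87.315, 116.518, 19.216, 37.251, 118.761, 84.300, 169.804),
    sd = c(14.263, 20.049, 5.628, 0.739, 27.802, 20.730, 10.379),
    min = c(40.00, 48.00, 8.00, 31.70, 47.00, 33.00, 124.50),
    max = c(150.00, 212.00, 38.00, 41.44, 188.00, 200.00, 231.10))
}

default_cohort_correlation <- function() {
  R <- diag(7)
  dimnames(R) <- list(COHORT_VARS, COHORT_VARS)
  # mild positive couplings so the hr x sbp / hr x gl interaction terms are
  # informative; the reference table prints no correlations, so these are
  # this package's documented choices
  R["hr", "rr"] <- R["rr", "hr"] <- 0.30
  R["hr", "gl"] <- R["gl", "hr"] <- 0.25
  R["hr", "sbp"] <- R["sbp", "hr"] <- 0.15
  R
}

#' Cohort specification
#'
#' @param targets Tibble with columns `variable`, `mean`, `sd`, `min`, `max`;
#'   defaults to the ICU reference summary measures.
#' @param female_fraction Probability a patient is female (default 0.374).
#' @param correlation 7x7 positive-definite correlation matrix over
#'   `hr, sbp, rr, pt, gl, weight, height`.
#' @param group_rule Function `cohort_tibble -> integer group vector` (1 =
#'   baseline); default [severity_group_rule()].
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(targets = default_cohort_targets(),
                        female_fraction = 0.374,
                        correlation = default_cohort_correlation(),
                        group_rule = severity_group_rule) {
  stopifnot(all(c("variable", "mean", "sd", "min", "max") %in% names(targets)))
  if (any(targets$sd <= 0)) stop("cohort spec: SD must be > 0")
  bad <- targets$mean <= targets$min | targets$mean >= targets$max
  if (any(bad)) {
    stop("infeasible cohort spec: mean outside (min, max) for ",
         paste(targets$variable[bad], collapse = ", "))
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite")
  structure(list(targets = targets, female_fraction = female_fraction,
                 correlation = correlation, group_rule = group_rule),
            class = "cohort_spec")
}

#' Default group-assignment rule: clinical severity score
#'
#' Counts, per patient, the vital signs outside conventional guideline normal
#' bands (hr 60-100, rr 12-20, sbp 90-120, pt 36.1-37.2, gl 70-140) and maps
#' the count to four groups: 0 abnormal signs = group 1 (baseline), 1 = group
#' 2, 2 = group 3, 3 or more = group 4.
#'
#' @param cohort Cohort tibble with the vital-sign columns.
#' @return Integer group vector in 1..4.
#' @export
severity_group_rule <- function(cohort) {
  score <- (cohort$hr < 60 | cohort$hr > 100) +
    (cohort$rr < 12 | cohort$rr > 20) +
    (cohort$sbp < 90 | cohort$sbp > 120) +
    (cohort$pt < 36.1 | cohort$pt > 37.2) +
    (cohort$gl < 70 | cohort$gl > 140)
  as.integer(pmin(score, 3) + 1)
}

# moments of a normal(m, s) truncated to [a, b]
truncnorm_moments <- function(m, s, a, b) {
  al <- (a - m) / s; be <- (b - m) / s
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  mean_t <- m + s * (da - db) / Z
  var_t <- s^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = mean_t, sd = sqrt(var_t))
}

# solve for the underlying normal (m, s) whose [a, b]-truncation has the
# target mean and SD, so rejection sampling reproduces the targets even when
# a bound sits close to the mean
calibrate_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mo[["mean"]] - target_mean)^2 / target_sd^2 +
      (mo[["sd"]] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(m = fit$par[1], s = exp(fit$par[2]))
}

.calibration_cache <- new.env(parent = emptyenv())

# Calibrate the underlying multivariate-normal moments so the *jointly
# truncated* sample reproduces the target means and SDs: univariate
# truncated-normal matching as a starting point, then a short Monte-Carlo
# fixed-point iteration (a row is rejected when any variable leaves its
# range, so a bound on one variable also shifts the variables correlated
# with it). Deterministic: fixed internal calibration seed, memoized per
# specification.
calibrate_generator <- function(spec, n_cal = 40000L, iters = 4L) {
  tg <- spec$targets
  key <- paste(c(tg$mean, tg$sd, tg$min, tg$max, spec$correlation),
               collapse = ",")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)

  cal <- t(mapply(calibrate_truncnorm, tg$mean, tg$sd, tg$min, tg$max))
  mu <- stats::setNames(cal[, "m"], tg$variable)
  sds <- stats::setNames(cal[, "s"], tg$variable)
  lo <- stats::setNames(tg$min, tg$variable)
  hi <- stats::setNames(tg$max, tg$variable)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(987654321L)
  for (it in seq_len(iters)) {
    Sigma <- diag(sds) %*% spec$correlation %*% diag(sds)
    batch <- MASS::mvrnorm(n_cal, mu = mu, Sigma = Sigma)
    keep <- apply(batch, 1L, function(row) all(row >= lo & row <= hi))
    kept <- batch[keep, , drop = FALSE]
    obs_mean <- colMeans(kept)
    obs_sd <- apply(kept, 2L, stats::sd)
    mu <- mu + (tg$mean - obs_mean)
    sds <- sds * tg$sd / obs_sd
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- list(mu = mu, sds = sds)
  .calibration_cache[[key]] <- out
  out
}

#' Generate a synthetic cohort
#'
#' Rows are drawn from a multivariate normal and rejection-resampled until
#' every variable lies inside its \[min, max\] range. The underlying normal
#' moments are calibrated (analytic univariate truncation correction plus a
#' deterministic Monte-Carlo fixed point over the joint rejection) so the
#' truncated sample hits the spec's means and SDs; truncation would
#' otherwise bias variables whose bounds sit within about two SDs of the
#' mean, such as the respiratory rate, and their correlated partners.
#' Gender is Bernoulli(female fraction); groups come from the spec's rule.
#' Deterministic given the seed.
#'
#' @param spec A `cohort_spec`.
#' @param n Number of patients.
#' @param seed Integer seed (mandatory).
#' @return A tibble with columns `patient_id, gender, weight, height, group,
#'   hr, rr, sbp, pt, gl`.
#' @export
generate_cohort <- function(spec = cohort_spec(), n, seed) {
  if (missing(seed)) stop("generate_cohort: seed is mandatory")
  tg <- spec$targets
  cal <- calibrate_generator(spec)
  mu <- cal$mu
  sds <- cal$sds
  Sigma <- diag(sds) %*% spec$correlation %*% diag(sds)
  set.seed(as.integer(seed %% .Machine$integer.max))
  lo <- stats::setNames(tg$min, tg$variable)
  hi <- stats::setNames(tg$max, tg$variable)

  draws <- matrix(NA_real_, nrow = 0, ncol = length(mu))
  while (nrow(draws) < n) {
    batch <- MASS::mvrnorm(max(2L * (n - nrow(draws)), 100L), mu = mu,
                           Sigma = Sigma)
    keep <- apply(batch, 1L, function(row) all(row >= lo & row <= hi))
    draws <- rbind(draws, batch[keep, , drop = FALSE])
  }
  draws <- draws[seq_len(n), , drop = FALSE]
  colnames(draws) <- tg$variable

  cohort <- tibble::as_tibble(as.data.frame(draws))
  cohort$gender <- ifelse(stats::runif(n) < spec$female_fraction,
                          "female", "male")
  cohort$group <- spec$group_rule(cohort)
  cohort$patient_id <- seq_len(n)
  cohort <- cohort[, c("patient_id", "gender", "weight", "height", "group",
                       "hr", "rr", "sbp", "pt", "gl")]
  class(cohort) <- c("mcps_cohort", class(cohort))
  cohort
}

#' Validate a cohort for regression fitting
#'
#' Multiple-regression fitting requires at least 30 patient records; every
#' value must lie within its declared range.
#'
#' @param cohort A cohort tibble.
#' @param spec The `cohort_spec` declaring the ranges.
#' @return The cohort, invisibly, or an error.
#' @export
validate_cohort <- function(cohort, spec = cohort_spec()) {
  if (nrow(cohort) < 30) {
    stop("cohort has ", nrow(cohort),
         " records; at least 30 patient records are required for regression fitting")
  }
  tg <- spec$targets
  for (i in seq_len(nrow(tg))) {
    v <- cohort[[tg$variable[i]]]
    if (any(v < tg$min[i] | v > tg$max[i])) {
      stop("cohort variable '", tg$variable[i], "' has values outside [",
           tg$min[i], ", ", tg$max[i], "]")
    }
  }
  invisible(cohort)
}

#' Write / read a cohort CSV
#'
#' Columns `patient_id,gender,weight,height,group,hr,rr,sbp,pt,gl`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `path` invisibly (write); the cohort tibble (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(d)
}
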