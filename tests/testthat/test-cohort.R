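test_that("generated cohorts respect ranges, determinism and the record floor", {
  spec <- cohort_spec()
  co <- generate_cohort(spec, n = 30, seed = 4)
  expect_equal(nrow(co), 30)
  tg <- spec$targets
  for (i in seq_len(nrow(tg))) {
    v <- co[[tg$variable[i]]]
    expect_true(all(v >= tg$min[i] & v <= tg$max[i]), info = tg$variable[i])
  }
  expect_true(all(co$group %in% 1:4))
  expect_true(all(co$gender %in% c("female", "male")))

  expect_identical(generate_cohort(spec, n = 50, seed = 9),
                   generate_cohort(spec, n = 50, seed = 9))

  # the 30-record floor for regression fitting
  small <- generate_cohort(spec, n = 29, seed = 2)
  expect_error(validate_cohort(small), "at least 30")
  expect_error(default_vital_models(small), "at least 30")
  expect_silent(validate_cohort(co))
})

test_that("an infeasible specification is rejected", {
  tg <- default_cohort_targets <- cohort_spec()$targets
  tg$mean[tg$variable == "hr"] <- 300   # outside [40, 150]
  expect_error(cohort_spec(targets = tg), "infeasible.*hr")
  R <- diag(7); R[1, 2] <- R[2, 1] <- 1.2
  expect_error(cohort_spec(correlation = R), "positive definite")
})

test_that("large-cohort moments and correlations match the specification", {
  spec <- cohort_spec()
  co <- generate_cohort(spec, n = 10000, seed = 42)
  tg <- spec$targets
  n <- nrow(co)
  for (i in seq_len(nrow(tg))) {
    v <- co[[tg$variable[i]]]
    expect_lt(abs(mean(v) - tg$mean[i]), 3 * tg$sd[i] / sqrt(n))
    expect_lt(abs(stats::sd(v) - tg$sd[i]) / tg$sd[i], 0.05)
    # coefficient of variation follows from matched mean and SD
    expect_equal(stats::sd(v) / mean(v), tg$sd[i] / tg$mean[i],
                 tolerance = 0.06)
  }
  expect_equal(mean(co$gender == "female"), 0.374, tolerance = 0.05)
  # configured correlations are recovered up to truncation attenuation;
  # unspecified pairs stay near zero
  expect_lt(abs(stats::cor(co$hr, co$rr) - 0.30), 0.05)
  expect_lt(abs(stats::cor(co$pt, co$weight)), 4 / sqrt(n) + 0.03)
})

test_that("an identity-correlation cohort has vanishing sample correlations", {
  spec <- cohort_spec(correlation = diag(7))
  co <- generate_cohort(spec, n = 4000, seed = 13)
  vars <- c("hr", "sbp", "rr", "pt", "gl")
  cm <- stats::cor(as.data.frame(co[vars]))
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 4 / sqrt(4000) + 0.02))
})

test_that("IRLS agrees with the reference GLM fitter on both families", {
  co <- generate_cohort(cohort_spec(), n = 250, seed = 17)
  d <- as.data.frame(co)
  d$group2 <- as.numeric(d$group == 2)
  d$group3 <- as.numeric(d$group == 3)
  d$group4 <- as.numeric(d$group == 4)

  f_ig <- fit_glm_irls(
    rr ~ hr + sbp + pt + gl + group2 + group3 + group4 + hr:sbp + hr:gl,
    d, family = "inverse.gaussian")
  ref_ig <- stats::glm(
    rr ~ hr + sbp + pt + gl + group2 + group3 + group4 + hr:sbp + hr:gl,
    data = d, family = stats::inverse.gaussian(link = "1/mu^2"))
  expect_true(f_ig$converged)
  expect_equal(f_ig$coefficients, stats::coef(ref_ig), tolerance = 1e-7)
  expect_equal(f_ig$deviance, stats::deviance(ref_ig), tolerance = 1e-7)
  expect_equal(unname(f_ig$se),
               unname(summary(ref_ig)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)

  f_g <- fit_glm_irls(hr ~ rr + sbp + gl, d, family = "Gamma")
  ref_g <- stats::glm(hr ~ rr + sbp + gl, data = d,
                      family = stats::Gamma(link = "inverse"))
  expect_equal(f_g$coefficients, stats::coef(ref_g), tolerance = 1e-8)
})

test_that("intercept-only Gamma fit solves to the reciprocal sample mean", {
  set.seed(3)
  y <- rgamma(40, shape = 5, scale = 4)
  f <- fit_glm_irls(y ~ 1, data.frame(y = y), family = "Gamma")
  expect_equal(unname(f$coefficients[["(Intercept)"]]), 1 / mean(y),
               tolerance = 1e-10)
})

test_that("IRLS refuses underdetermined and degenerate designs", {
  d <- data.frame(y = rgamma(5, 4, 1), x1 = 1:5, x2 = 5:1, x3 = runif(5),
                  x4 = runif(5), x5 = runif(5), x6 = runif(5), x7 = runif(5))
  expect_error(fit_glm_irls(y ~ x1 + x2 + x3 + x4 + x5 + x6 + x7, d,
                            family = "Gamma"),
               "at least")
  d2 <- data.frame(y = rgamma(30, 4, 1), a = rnorm(30))
  d2$b <- 2 * d2$a
  expect_error(fit_glm_irls(y ~ a + b, d2, family = "Gamma"), "collinear.*b")
  d3 <- data.frame(y = c(-1, rgamma(29, 4, 1)), a = rnorm(30))
  expect_error(fit_glm_irls(y ~ a, d3, family = "Gamma"), "strictly positive")
})

test_that("IRLS matches direct likelihood maximization on tiny instances", {
  d <- tiny_gamma_data(n = 15, seed = 11)
  f <- fit_glm_irls(y ~ x, d, family = "Gamma")
  X <- cbind(1, d$x)
  opt <- stats::optim(f$coefficients * 1.3, glm_negloglik, gr = glm_negloglik_grad,
                      X = X, y = d$y,
                      family = "Gamma", method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(max(abs(opt$par - f$coefficients)) / max(abs(f$coefficients)),
            1e-6)

  set.seed(21)
  x <- runif(18); mu <- 1 / sqrt(0.002 + 0.001 * x)
  y <- rinvgauss(18, mu, lambda = 200)
  d2 <- data.frame(x = x, y = y)
  f2 <- fit_glm_irls(y ~ x, d2, family = "inverse.gaussian")
  X2 <- cbind(1, x)
  opt2 <- stats::optim(f2$coefficients * 1.2, glm_negloglik, gr = glm_negloglik_grad,
                       X = X2, y = y,
                       family = "inverse.gaussian", method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(max(abs(opt2$par - f2$coefficients)) / max(abs(f2$coefficients)),
            1e-6)
})

test_that("IRLS recovers known coefficients from simulated GLM data", {
  set.seed(101)
  n <- 2000
  x1 <- runif(n, 60, 110); x2 <- runif(n, 80, 160)
  # inverse-Gaussian truth
  beta_ig <- c(0.004, 2e-5, -1e-5)
  eta <- beta_ig[1] + beta_ig[2] * x1 + beta_ig[3] * x2
  mu <- 1 / sqrt(eta)
  y <- rinvgauss(n, mu, lambda = 500)
  f <- fit_glm_irls(y ~ x1 + x2, data.frame(x1, x2, y),
                    family = "inverse.gaussian")
  expect_true(all(abs(f$coefficients - beta_ig) < 3 * f$se))
  # Gamma truth
  beta_g <- c(0.008, 5e-5)
  mu_g <- 1 / (beta_g[1] + beta_g[2] * x1)
  y_g <- rgamma(n, shape = 25, scale = mu_g / 25)
  f_g <- fit_glm_irls(y ~ x1, data.frame(x1, y = y_g), family = "Gamma")
  expect_true(all(abs(f_g$coefficients - beta_g) < 3 * f_g$se))

  # repeated-replicate bias: small relative to the standard error
  reps <- 40
  est <- matrix(NA_real_, reps, 2)
  for (b in seq_len(reps)) {
    yb <- rgamma(n, shape = 25, scale = mu_g / 25)
    est[b, ] <- fit_glm_irls(y ~ x1, data.frame(x1, y = yb),
                             family = "Gamma")$coefficients
  }
  bias <- colMeans(est) - beta_g
  expect_true(all(abs(bias) < 0.5 * f_g$se))
})

test_that("diagnostics satisfy the hat-trace identity and flag influential rows", {
  co <- generate_cohort(cohort_spec(), n = 120, seed = 3)
  d <- as.data.frame(co)
  f <- fit_glm_irls(hr ~ sbp + gl, d, family = "Gamma")
  dg <- glm_diagnostics(f, B = 20, seed = 5)
  expect_equal(sum(dg$residuals$hat), f$p, tolerance = 1e-8)
  expect_true(all(dg$residuals$hat > 0 & dg$residuals$hat < 1))

  # a well-specified model keeps most ordered residuals inside the envelope
  inside <- mean(dg$envelope$observed >= dg$envelope$lower &
                   dg$envelope$observed <= dg$envelope$upper)
  expect_gte(inside, 0.85)

  # an implanted extreme row carries a large Cook's distance
  d2 <- d
  d2$hr[1] <- 150; d2$sbp[1] <- 48; d2$gl[1] <- 188
  f2 <- fit_glm_irls(hr ~ sbp + gl, d2, family = "Gamma")
  dg2 <- glm_diagnostics(f2, B = 5, seed = 5)
  expect_gt(dg2$residuals$cooks[1], stats::median(dg2$residuals$cooks) * 10)
})

test_that("default vital models use the published rr design and are deterministic", {
  co <- generate_cohort(cohort_spec(), n = 300, seed = 7)
  models <- default_vital_models(co)
  expect_named(models, c("rr", "hr", "sbp", "pt"))
  fits <- attr(models, "fits")
  # intercept + 4 mains + 3 dummies + 2 interactions = 10 columns
  expect_equal(fits$rr$p, 10)
  expect_identical(models$rr$family, "inverse.gaussian")
  expect_identical(models$hr$family, "Gamma")
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))

  co2 <- generate_cohort(cohort_spec(), n = 300, seed = 7)
  models2 <- default_vital_models(co2)
  expect_identical(models$rr$coefficients, models2$rr$coefficients)

  # the packaged specs predict through predict_vital
  pred <- predict_vital(models$rr, ref_state(), patient_profile())
  th <- default_sign_thresholds()
  expect_gte(pred, th$rr[1]); expect_lte(pred, th$rr[2])
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(cohort_spec(), n = 40, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_equal(names(co2), names(co))
  expect_equal(co2$hr, co$hr, tolerance = 1e-12)
})
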