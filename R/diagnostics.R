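#' @title Regression diagnostics for the vital-sign fits
#' @name diagnostics
NULL

#' Random inverse-Gaussian deviates
#'
#' Michael-Schucany-Haas transformation: mean `mu`, shape `lambda`
#' (Var = mu^3 / lambda).
#'
#' @param n Number of draws. @param mu Mean (vectorised).
#' @param lambda Shape parameter.
#' @return Numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mu, lambda) {
  mu <- rep_len(mu, n)
  nu <- stats::rnorm(n)^2
  x1 <- mu + mu^2 * nu / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * nu + mu^2 * nu^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x1), x1, mu^2 / x1)
}

simulate_response <- function(fit, mu = fit$fitted) {
  phi <- fit$dispersion
  if (fit$family == "inverse.gaussian") {
    rinvgauss(length(mu), mu, lambda = 1 / phi)
  } else {
    stats::rgamma(length(mu), shape = 1 / phi, scale = mu * phi)
  }
}

#' Diagnostics for an IRLS fit
#'
#' Pearson and deviance residuals, leverages (hat values; their sum equals
#' the number of coefficients), Cook's distances, and a simulated envelope
#' for the half-normal Q-Q plot of absolute deviance residuals: `B` replicate
#' datasets are drawn from the fitted model, refitted, and the per-rank
#' envelope quantiles recorded.
#'
#' @param fit A converged `mcps_glm`.
#' @param B Number of envelope replicates (default 50).
#' @param level Envelope coverage (default 0.95).
#' @param seed Optional seed for the envelope simulation.
#' @return A list with `residuals` (tibble: `pearson`, `deviance`, `hat`,
#'   `cooks`) and `envelope` (tibble: `rank`, `lower`, `median`, `upper`,
#'   `observed`).
#' @export
glm_diagnostics <- function(fit, B = 50, level = 0.95, seed = NULL) {
  if (!fit$converged) stop("glm_diagnostics requires a converged fit")
  if (!is.null(seed)) set.seed(seed)
  fam <- irls_family(fit$family)
  w <- fit$weights
  X <- fit$X
  WX <- X * sqrt(w)
  H <- WX %*% solve(crossprod(WX), t(WX))
  hat <- diag(H)
  phi <- fit$dispersion
  pearson <- (fit$y - fit$fitted) / sqrt(fam$variance(fit$fitted))
  devres <- sign(fit$y - fit$fitted) * sqrt(fam$dev.resid(fit$y, fit$fitted))
  std_pearson <- pearson / sqrt(phi * (1 - hat))
  cooks <- std_pearson^2 * hat / (fit$p * (1 - hat))

  obs <- sort(abs(devres / sqrt(phi)))
  sims <- matrix(NA_real_, nrow = B, ncol = fit$n)
  for (b in seq_len(B)) {
    yb <- simulate_response(fit)
    fb <- tryCatch(
      fit_glm_irls(fit$formula,
                   within_data(fit, yb),
                   family = fit$family),
      error = function(e) NULL)
    mub <- if (is.null(fb)) fit$fitted else fb$fitted
    rb <- sign(yb - mub) * sqrt(fam$dev.resid(yb, mub))
    phib <- if (is.null(fb)) phi else fb$dispersion
    sims[b, ] <- sort(abs(rb / sqrt(phib)))
  }
  alpha <- (1 - level) / 2
  envelope <- tibble::tibble(
    rank = seq_len(fit$n),
    lower = apply(sims, 2, stats::quantile, probs = alpha),
    median = apply(sims, 2, stats::median),
    upper = apply(sims, 2, stats::quantile, probs = 1 - alpha),
    observed = obs)

  list(residuals = tibble::tibble(pearson = pearson, deviance = devres,
                                  hat = hat, cooks = cooks),
       envelope = envelope)
}

# the stored model frame with a replacement response: same design, new y
within_data <- function(fit, y_new) {
  d <- fit$model
  d[[1]] <- y_new  # first model-frame column is the response
  d
}

#' Envelope Q-Q diagnostic plot
#'
#' @param diag Output of [glm_diagnostics()].
#' @return A ggplot object: observed ordered absolute residuals with the
#'   simulated envelope band.
#' @export
plot_envelope <- function(diag) {
  env <- diag$envelope
  ggplot2::ggplot(env, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = "rank", y = "|deviance residual|",
                  title = "Simulated envelope")
}
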