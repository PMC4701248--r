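#' @title GLM fitting by iteratively reweighted least squares
#' @description In-package IRLS for the two exponential families used by the
#'   vital-sign models, each with its canonical link: inverse-Gaussian with
#'   eta = mu^-2 (variance function mu^3) and Gamma with eta = mu^-1
#'   (variance function mu^2). Dispersion is estimated by the Pearson
#'   statistic.
#' @name irls
NULL

irls_family <- function(family) {
  switch(family,
    inverse.gaussian = list(
      linkfun = function(mu) 1 / mu^2,
      linkinv = function(eta) 1 / sqrt(eta),
      mu.eta = function(eta) -0.5 * eta^(-1.5),     # d mu / d eta
      variance = function(mu) mu^3,
      dev.resid = function(y, mu) (y - mu)^2 / (mu^2 * y),
      eta_ok = function(eta) all(eta > 0)),
    Gamma = list(
      linkfun = function(mu) 1 / mu,
      linkinv = function(eta) 1 / eta,
      mu.eta = function(eta) -1 / eta^2,
      variance = function(mu) mu^2,
      dev.resid = function(y, mu) -2 * (log(ifelse(y == 0, 1, y / mu)) -
                                          (y - mu) / mu),
      eta_ok = function(eta) all(eta > 0)),
    stop("unsupported family '", family, "'"))
}

#' Fit a GLM by IRLS
#'
#' Canonical-link IRLS with step halving to keep the linear predictor inside
#' the link domain. Convergence is declared when the relative change in the
#' coefficient vector falls below `tol`.
#'
#' @param formula Model formula (interactions written `a:b` are supported by
#'   the usual formula machinery).
#' @param data Data frame holding response and predictors. The response must
#'   be strictly positive.
#' @param family `"inverse.gaussian"` (eta = mu^-2) or `"Gamma"`
#'   (eta = mu^-1).
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return An `mcps_glm` object with coefficients, standard errors, deviance,
#'   dispersion, iteration count and a convergence flag. Methods: `print`,
#'   [tidy.mcps_glm()], [glance.mcps_glm()].
#' @export
fit_glm_irls <- function(formula, data,
                         family = c("inverse.gaussian", "Gamma"),
                         tol = 1e-8, max_iter = 100) {
  family <- match.arg(family)
  fam <- irls_family(family)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (any(y <= 0)) stop("response must be strictly positive for ", family)
  if (n < p + 1) {
    stop("need at least ", p + 1, " rows to fit ", p, " coefficients, got ", n)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }

  mu <- y
  eta <- fam$linkfun(mu)
  beta <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu_eta <- fam$mu.eta(eta)
    w <- mu_eta^2 / fam$variance(mu)           # IRLS weights
    z <- eta + (y - mu) / mu_eta               # working response
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    eta_new <- drop(X %*% beta_new)
    # step-halve back into the link domain
    halvings <- 0L
    while (!fam$eta_ok(eta_new) && halvings < 50L) {
      if (is.null(beta)) {
        eta_new <- (eta + eta_new) / 2
      } else {
        beta_new <- (beta + beta_new) / 2
        eta_new <- drop(X %*% beta_new)
      }
      halvings <- halvings + 1L
    }
    if (!fam$eta_ok(eta_new)) {
      stop("IRLS left the link domain and step halving failed")
    }
    if (!is.null(beta)) {
      rel <- max(abs(beta_new - beta)) / max(abs(beta), 1e-10)
      if (rel < tol) {
        beta <- beta_new; eta <- eta_new; mu <- fam$linkinv(eta)
        converged <- TRUE
        break
      }
    }
    beta <- beta_new
    eta <- eta_new
    mu <- fam$linkinv(eta)
  }

  pearson <- sum((y - mu)^2 / fam$variance(mu))
  dispersion <- pearson / (n - p)
  mu_eta <- fam$mu.eta(eta)
  w <- mu_eta^2 / fam$variance(mu)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- dispersion * solve(XtWX)
  se <- sqrt(diag(vcov))
  deviance <- sum(fam$dev.resid(y, mu))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vcov, deviance = deviance, dispersion = dispersion,
    iterations = iter, converged = converged, family = family,
    formula = formula, fitted = mu, linear_predictor = eta,
    y = y, X = X, model = mf, weights = w, n = n, p = p),
    class = "mcps_glm")
}

#' @export
print.mcps_glm <- function(x, ...) {
  cat(sprintf("GLM (%s, canonical link), %d obs, %d coefficients\n",
              x$family, x$n, x$p))
  cat(sprintf("deviance %.4g, dispersion %.4g, %d IRLS iterations%s\n",
              x$deviance, x$dispersion, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(round(rbind(estimate = x$coefficients, se = x$se), 7))
  invisible(x)
}

#' Tidy an IRLS fit
#'
#' @param x An `mcps_glm`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.mcps_glm <- function(x, ...) {
  stat <- x$coefficients / x$se
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(stat),
                 p.value = 2 * stats::pt(-abs(unname(stat)), df = x$n - x$p))
}

#' One-row fit summary
#'
#' @param x An `mcps_glm`.
#' @param ... Unused.
#' @return Tibble with `deviance`, `dispersion`, `iterations`, `converged`,
#'   `nobs`, `df.residual`.
#' @export
glance.mcps_glm <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, dispersion = x$dispersion,
                 iterations = x$iterations, converged = x$converged,
                 nobs = x$n, df.residual = x$n - x$p)
}

#' Negative log-likelihood of a fitted family (for cross-validation of IRLS
#' against direct maximization)
#'
#' For a fixed dispersion phi: inverse-Gaussian density with Var = phi mu^3;
#' Gamma with shape 1/phi and mean mu. Used by the tests to maximize the same
#' likelihood IRLS solves.
#'
#' @param beta Coefficient vector.
#' @param X Design matrix. @param y Response.
#' @param family Family name. @param phi Dispersion (fixed).
#' @return Scalar negative log-likelihood (Inf outside the link domain).
#' @export
glm_negloglik <- function(beta, X, y, family, phi = 1) {
  fam <- irls_family(family)
  eta <- drop(X %*% beta)
  if (!fam$eta_ok(eta)) return(Inf)
  mu <- fam$linkinv(eta)
  if (family == "inverse.gaussian") {
    lambda <- 1 / phi
    -sum(0.5 * log(lambda / (2 * pi * y^3)) -
           lambda * (y - mu)^2 / (2 * mu^2 * y))
  } else {
    shape <- 1 / phi
    -sum(stats::dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
  }
}

#' @rdname glm_negloglik
#' @export
glm_negloglik_grad <- function(beta, X, y, family, phi = 1) {
  fam <- irls_family(family)
  eta <- drop(X %*% beta)
  if (!fam$eta_ok(eta)) return(rep(NA_real_, length(beta)))
  mu <- fam$linkinv(eta)
  # canonical links: the score in beta is proportional to X'(y - mu)
  scale <- if (family == "inverse.gaussian") 1 / (2 * phi) else 1 / phi
  drop(scale * crossprod(X, y - mu))
}
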