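#' @title Bergman minimal-model glucose-insulin kinetics
#' @description Three-compartment model: blood glucose G (mg/dL), effective
#'   insulin action X (min^-1), and plasma insulin I (uU/mL). Includes the
#'   nonlinear field, its linearization about an operating point, equilibrium
#'   computation, and transfer-function gains of the linear model.
#' @name bergman
NULL

#' Bergman minimal-model parameters
#'
#' Defaults are canonical minimal-model literature values, documented in the
#' methods vignette; every parameter is overridable.
#'
#' @param p1 Glucose effectiveness at basal insulin (min^-1).
#' @param p2 Insulin-action decay rate (min^-1).
#' @param p3 Insulin sensitivity coupling (min^-2 per uU/mL).
#' @param n Plasma-insulin clearance rate (min^-1).
#' @param gamma Endogenous insulin release rate above the glucose threshold.
#' @param h Glucose threshold for endogenous secretion (mg/dL).
#' @param Gb Basal glucose (mg/dL).
#' @param Ib Basal insulin (uU/mL).
#' @param tau Unit-conversion factor applied to the controller output r(t).
#' @return A `bergman_params` list.
#' @export
bergman_params <- function(p1 = 0.028735, p2 = 0.028344, p3 = 5.035e-5,
                           n = 0.0926, gamma = 0.0039, h = 79.0,
                           Gb = 81.3, Ib = 15, tau = 1) {
  if (p1 <= 0 || p2 <= 0 || n <= 0) stop("p1, p2, n must be > 0")
  if (p3 < 0) stop("p3 must be >= 0")
  if (Gb <= 0 || Ib <= 0) stop("Gb, Ib must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(p1 = p1, p2 = p2, p3 = p3, n = n, gamma = gamma, h = h,
                 Gb = Gb, Ib = Ib, tau = tau), class = "bergman_params")
}

#' Glucose-insulin state
#' @param G Glucose (mg/dL). @param X Insulin action (min^-1).
#' @param I Plasma insulin (uU/mL).
#' @return Named numeric vector.
#' @export
gi_state <- function(G, X = 0, I) {
  c(G = G, X = X, I = I)
}

#' Disturbance / control input
#' @param D Meal glucose absorption rate (mg/dL/min, >= 0).
#' @param C Glucagon infusion rate (mg/dL/min, >= 0).
#' @param r Exogenous insulin infusion (controller output, uU/mL/min).
#' @return Named numeric vector.
#' @export
gi_input <- function(D = 0, C = 0, r = 0) {
  if (D < 0 || C < 0) stop("disturbances D and C must be >= 0")
  c(D = D, C = C, r = r)
}

#' Nonlinear minimal-model derivatives
#'
#' dG/dt = -p1 (G - Gb) - X G + D + C;
#' dX/dt = -p2 X + p3 (I - Ib);
#' dI/dt = -n (I - Ib) + tau r, plus, when `include_gamma` is on, the
#' endogenous secretion term gamma * max(G - h, 0) * t.
#'
#' @param state `c(G =, X =, I =)`.
#' @param params A `bergman_params`.
#' @param u `c(D =, C =, r =)`.
#' @param t Time in minutes (only used by the endogenous term).
#' @param include_gamma Include the endogenous insulin release term (default
#'   off, matching the linearized model and the equilibrium equations).
#' @return Named derivative vector `c(G =, X =, I =)`.
#' @export
bmm_derivatives <- function(state, params, u = gi_input(), t = 0,
                            include_gamma = FALSE) {
  G <- state[["G"]]; X <- state[["X"]]; I <- state[["I"]]
  dG <- -params$p1 * (G - params$Gb) - X * G + (u[["D"]] + u[["C"]])
  dX <- -params$p2 * X + params$p3 * (I - params$Ib)
  dI <- -params$n * (I - params$Ib) + params$tau * u[["r"]]
  if (include_gamma) dI <- dI + params$gamma * max(G - params$h, 0) * t
  c(G = dG, X = dX, I = dI)
}

#' Linearized minimal-model derivatives
#'
#' The bilinear term X*G is replaced by its first-order expansion about the
#' operating-point averages Gbar and Xbar:
#' dG/dt = -p1 (G - Gb) - Xbar G - Gbar X + Gbar Xbar + D + C.
#'
#' @param state,params,u As [bmm_derivatives()].
#' @param op An `operating_point` supplying Gbar = G0 and Xbar = X0.
#' @return Named derivative vector.
#' @export
linearized_derivatives <- function(state, params, u, op) {
  G <- state[["G"]]; X <- state[["X"]]; I <- state[["I"]]
  Gbar <- op$x0[["G"]]; Xbar <- op$x0[["X"]]
  dG <- -params$p1 * (G - params$Gb) - Xbar * G - Gbar * X + Gbar * Xbar +
    (u[["D"]] + u[["C"]])
  dX <- -params$p2 * X + params$p3 * (I - params$Ib)
  dI <- -params$n * (I - params$Ib) + params$tau * u[["r"]]
  c(G = dG, X = dX, I = dI)
}

#' Equilibrium (operating point) of the minimal model
#'
#' Closed-form rest point of the gamma-free field for constant inputs
#' u0 = (D0, C0, r0):
#' X0 = p3 tau r0 / (p2 n); I0 = Ib + tau r0 / n;
#' G0 = (p1 Gb + D0 + C0) / (p1 + X0).
#'
#' @param params A `bergman_params`.
#' @param u0 Constant input vector `c(D =, C =, r =)`.
#' @return An `operating_point` with fields `x0`, `u0`.
#' @export
equilibrium_point <- function(params, u0 = gi_input()) {
  X0 <- params$p3 * params$tau * u0[["r"]] / (params$p2 * params$n)
  denom <- params$p1 + X0
  if (abs(denom) < 1e-14) stop("degenerate equilibrium: p1 + X0 is zero")
  G0 <- (params$p1 * params$Gb + u0[["D"]] + u0[["C"]]) / denom
  I0 <- params$Ib + params$tau * u0[["r"]] / params$n
  op <- structure(list(x0 = c(G = G0, X = X0, I = I0), u0 = u0),
                  class = "operating_point")
  res <- bmm_derivatives(op$x0, params, u0, include_gamma = FALSE)
  if (max(abs(res)) > 1e-9) {
    stop("equilibrium residual check failed: max |f(x0,u0)| = ",
         format(max(abs(res))))
  }
  op
}

#' Linearize the minimal model about an operating point
#'
#' Returns the Jacobian state matrix and input matrix
#' A = [[-p1 - X0, -G0, 0], [0, -p2, p3], [0, 0, -n]],
#' B = [[1, 1, 0], [0, 0, 0], [0, 0, tau]] (columns for D, C, r), with the
#' glucose channel as output. A is upper triangular, so its eigenvalues are
#' read off the diagonal.
#'
#' @param params A `bergman_params`.
#' @param op An `operating_point`.
#' @return A `state_space_model` with fields `A`, `B`, `C`, `op`.
#' @export
linearize <- function(params, op) {
  G0 <- op$x0[["G"]]; X0 <- op$x0[["X"]]
  A <- matrix(c(-params$p1 - X0, -G0, 0,
                0, -params$p2, params$p3,
                0, 0, -params$n),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G", "X", "I"), c("G", "X", "I")))
  B <- matrix(c(1, 1, 0,
                0, 0, 0,
                0, 0, params$tau),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G", "X", "I"), c("D", "C", "r")))
  Cmat <- matrix(c(1, 0, 0), nrow = 1, dimnames = list("G", c("G", "X", "I")))
  structure(list(A = A, B = B, C = Cmat, op = op, params = params),
            class = "state_space_model")
}

# multiply polynomials given as coefficient vectors, constant term first
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Transfer-function gains of one input channel to the glucose output
#'
#' Computes numerator and denominator polynomial coefficients (constant term
#' first) of C (sI - A)^-1 B_channel. Because A is upper triangular the
#' denominator is (s + p1 + X0)(s + p2)(s + n); the D and C channels share the
#' numerator (s + p2)(s + n), and the r channel numerator is the constant
#' -G0 p3 tau.
#'
#' @param model A `state_space_model`.
#' @param channel `"D"`, `"C"` or `"r"`.
#' @return `list(num =, den =)` coefficient vectors (constant term first).
#' @export
ss_to_transfer_gains <- function(model, channel = c("D", "C", "r")) {
  channel <- match.arg(channel)
  p <- model$params
  X0 <- model$op$x0[["X"]]; G0 <- model$op$x0[["G"]]
  q1 <- p$p1 + X0
  den <- poly_mult(poly_mult(c(q1, 1), c(p$p2, 1)), c(p$n, 1))
  num <- switch(channel,
    D = poly_mult(c(p$p2, 1), c(p$n, 1)),
    C = poly_mult(c(p$p2, 1), c(p$n, 1)),
    r = c(-G0 * p$p3 * p$tau))
  list(num = num, den = den)
}

#' Eigenvalues of the linearized model
#' @param model A `state_space_model`.
#' @return The three eigenvalues (real, from the triangular diagonal).
#' @export
ss_poles <- function(model) {
  diag(model$A)
}
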