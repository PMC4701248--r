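#' @title PID glucose control
#' @description Parallel PID controller
#'   C(s) = Kp + Ki/s + Kd N s / (s + N), discretized with a backward-Euler
#'   integral and a first-order filtered derivative. The error signal is
#'   e = G - setpoint, so rising glucose increases the insulin command; the
#'   command is clipped at r >= 0 (insulin cannot be withdrawn) with
#'   conditional-integration anti-windup.
#' @name pid
NULL

#' PID parameters
#'
#' @param Kp,Ki,Kd Proportional, integral and derivative gains.
#' @param N Derivative-filter coefficient (> 0): pole of the filtered
#'   derivative at -N.
#' @param setpoint Glucose reference (mg/dL).
#' @return A `pid_params` list.
#' @export
pid_params <- function(Kp, Ki, Kd, N = 0.3, setpoint = 81.3) {
  if (N <= 0) stop("derivative filter coefficient N must be > 0")
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd, N = N, setpoint = setpoint),
            class = "pid_params")
}

#' Fresh PID internal state
#' @return A `pid_state` with zero integral, filter state and previous error.
#' @export
pid_state <- function() {
  structure(list(integral = 0, deriv = 0, e_prev = 0, primed = FALSE),
            class = "pid_state")
}

#' One discrete PID update
#'
#' Backward-Euler integral I_k = I_{k-1} + Ki e_k dt; filtered derivative
#' D_k = (D_{k-1} + Kd N (e_k - e_{k-1})) / (1 + N dt) (first-order filter
#' with pole at -N). When the raw command is negative the output saturates at
#' 0 and the integral is not advanced (anti-windup).
#'
#' @param pid A `pid_params`.
#' @param state A `pid_state`.
#' @param error Current error e = G - setpoint (mg/dL).
#' @param dt Step size in minutes (> 0).
#' @return `list(r =, state =)` with r >= 0.
#' @export
pid_step <- function(pid, state, error, dt) {
  if (dt <= 0) stop("pid_step: dt must be > 0")
  e_prev <- if (state$primed) state$e_prev else error
  integral_new <- state$integral + pid$Ki * error * dt
  deriv_new <- (state$deriv + pid$Kd * pid$N * (error - e_prev)) /
    (1 + pid$N * dt)
  r_raw <- pid$Kp * error + integral_new + deriv_new
  if (r_raw < 0) {
    r <- 0
    integral_new <- state$integral  # clamp: do not wind up while saturated
  } else {
    r <- r_raw
  }
  state$integral <- integral_new
  state$deriv <- deriv_new
  state$e_prev <- error
  state$primed <- TRUE
  list(r = r, state = state)
}

#' Tune default PID gains on the linearized insulin channel
#'
#' Documented analytic procedure (SIMC-style): the linearized r -> G plant
#' G0 p3 tau / ((s + p1 + X0)(s + p2)(s + n)) (sign absorbed by the error
#' convention) is approximated by a second-order-plus-delay model whose two
#' dominant time constants are the two slowest plant poles and whose
#' effective delay is the fastest pole's time constant. The SIMC rules for a
#' second-order process then give a series PID, converted to parallel form.
#' The closed-loop time constant defaults to half the effective delay.
#'
#' @param params A `bergman_params`.
#' @param op Operating point (default: basal equilibrium with zero inputs).
#' @param tauc_factor Closed-loop time constant as a multiple of the effective
#'   delay (default 0.5).
#' @param setpoint Glucose reference; defaults to the operating-point glucose.
#' @return A `pid_params`.
#' @export
tune_pid <- function(params, op = equilibrium_point(params),
                     tauc_factor = 0.5, setpoint = NULL) {
  X0 <- op$x0[["X"]]; G0 <- op$x0[["G"]]
  poles <- sort(c(params$p1 + X0, params$p2, params$n))  # ascending rate
  K <- G0 * params$p3 * params$tau / prod(poles)         # static gain magnitude
  tau1 <- 1 / poles[1]; tau2 <- 1 / poles[2]; theta <- 1 / poles[3]
  tauc <- tauc_factor * theta
  Kc <- (1 / K) * tau1 / (tauc + theta)
  tauI <- min(tau1, 4 * (tauc + theta))
  tauD <- tau2
  # series -> parallel conversion
  Kp <- Kc * (1 + tauD / tauI)
  Ki <- Kc / tauI
  Kd <- Kc * tauD
  N <- 10 / tauD
  pid_params(Kp = Kp, Ki = Ki, Kd = Kd, N = N,
             setpoint = if (is.null(setpoint)) G0 else setpoint)
}

#' Closed-loop poles of the linearized loop
#'
#' Roots of the characteristic polynomial
#' d(s) s (s + N) + K3 (Kp s (s + N) + Ki (s + N) + Kd N s^2), where d(s) is
#' the plant denominator and K3 = G0 p3 tau the loop gain magnitude.
#'
#' @param params A `bergman_params`.
#' @param pid A `pid_params`.
#' @param op Operating point (default basal).
#' @return Complex vector of closed-loop poles.
#' @export
closed_loop_poles <- function(params, pid, op = equilibrium_point(params)) {
  model <- linearize(params, op)
  tf <- ss_to_transfer_gains(model, "r")
  K3 <- abs(tf$num[1])
  d <- tf$den                                  # cubic, constant first
  s_sN <- poly_mult(c(0, 1), c(pid$N, 1))      # s (s + N)
  char <- poly_mult(d, s_sN)
  ctrl <- pid$Kp * s_sN + pid$Ki * c(pid$N, 1, 0) +
    pid$Kd * pid$N * c(0, 0, 1)
  char[seq_along(ctrl)] <- char[seq_along(ctrl)] + K3 * ctrl
  polyroot(char)
}
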