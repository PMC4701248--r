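#' @title Closed-loop diabetic patient simulation
#' @name closed-loop
NULL

#' Disturbance schedule
#'
#' @param time Pulse onset times (minutes).
#' @param channel `"D"` (meal glucose absorption) or `"C"` (glucagon).
#' @param magnitude Rate during the pulse (mg/dL/min, >= 0).
#' @param duration Pulse duration (minutes, > 0).
#' @return A tibble schedule; rows are rectangular pulses that sum where they
#'   overlap.
#' @export
disturbance_schedule <- function(time = numeric(0), channel = character(0),
                                 magnitude = numeric(0), duration = numeric(0)) {
  if (length(magnitude) && any(magnitude < 0)) stop("disturbance magnitudes must be >= 0")
  if (length(channel) && !all(channel %in% c("D", "C"))) {
    stop("disturbance channel must be 'D' or 'C'")
  }
  tibble::tibble(time = time, channel = channel,
                 magnitude = magnitude, duration = duration)
}

#' Read a disturbance schedule from CSV
#' @param path CSV with columns `time,channel,magnitude,duration`.
#' @return A disturbance schedule tibble.
#' @export
read_disturbance_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  disturbance_schedule(d$time, d$channel, d$magnitude, d$duration)
}

disturbance_at <- function(schedule, t, channel) {
  if (nrow(schedule) == 0) return(0)
  sel <- schedule$channel == channel & schedule$time <= t &
    t < schedule$time + schedule$duration
  sum(schedule$magnitude[sel])
}

#' Simulate the closed-loop glucose control system
#'
#' Advances the minimal model (nonlinear or linearized) by RK4 with the PID
#' command held constant over each step (zero-order hold); the controller is
#' updated once per step from the measured glucose. When vital-sign models and
#' a patient profile are supplied, the glucose state is written into the
#' vital-signs state each step and the remaining signs are recomputed through
#' their regression models, so glucose control co-adjusts hr/rr/sbp/pt.
#'
#' @param params A `bergman_params`.
#' @param pid A `pid_params` (default: [tune_pid()] at the basal operating
#'   point).
#' @param disturbances A [disturbance_schedule()] tibble.
#' @param init Initial `c(G =, X =, I =)` state (default: basal equilibrium).
#' @param horizon Simulation horizon in minutes.
#' @param dt Step size in minutes (default 0.1).
#' @param model `"nonlinear"` or `"linear"` dynamics.
#' @param include_gamma Include the endogenous secretion term (nonlinear model
#'   only).
#' @param vitals_models Optional list of `glm_spec`s to co-simulate.
#' @param profile Optional `patient_profile` for the vitals models.
#' @param vitals_init Initial `vital_state` when co-simulating vitals.
#' @param thresholds Per-sign ranges for the vitals models.
#' @return A `closed_loop_trace` tibble with columns `time, G, X, I, r, D, C`
#'   (plus `hr, rr, sbp, pt, gl` when vitals are coupled).
#' @export
simulate_closed_loop <- function(params, pid = NULL,
                                 disturbances = disturbance_schedule(),
                                 init = NULL, horizon = 600, dt = 0.1,
                                 model = c("nonlinear", "linear"),
                                 include_gamma = FALSE,
                                 vitals_models = NULL, profile = NULL,
                                 vitals_init = vital_state(),
                                 thresholds = default_sign_thresholds()) {
  model <- match.arg(model)
  op <- equilibrium_point(params)
  if (is.null(pid)) pid <- tune_pid(params, op)
  if (is.null(init)) init <- op$x0
  state <- init
  cstate <- pid_state()
  with_vitals <- !is.null(vitals_models) && !is.null(profile)
  vstate <- vitals_init

  times <- seq(0, horizon, by = dt)
  nT <- length(times)
  out <- matrix(NA_real_, nrow = nT, ncol = 7,
                dimnames = list(NULL, c("time", "G", "X", "I", "r", "D", "C")))
  vout <- if (with_vitals) matrix(NA_real_, nrow = nT, ncol = 5,
                                  dimnames = list(NULL, c("hr", "rr", "sbp", "pt", "gl")))

  field <- function(t, s, u) {
    if (model == "nonlinear") {
      bmm_derivatives(s, params, u, t, include_gamma = include_gamma)
    } else {
      linearized_derivatives(s, params, u, op)
    }
  }
  comp <- sim_component("bmm", "continuous", state = state,
                        derivs = function(t, s, inputs) field(t, s, inputs$u))

  for (i in seq_len(nT)) {
    t <- times[[i]]
    D <- disturbance_at(disturbances, t, "D")
    C <- disturbance_at(disturbances, t, "C")
    ctrl <- pid_step(pid, cstate, state[["G"]] - pid$setpoint, dt)
    cstate <- ctrl$state
    r <- ctrl$r
    out[i, ] <- c(t, state[["G"]], state[["X"]], state[["I"]], r, D, C)
    if (with_vitals) {
      gl_clamped <- min(max(state[["G"]], thresholds$gl[1]), thresholds$gl[2])
      vstate <- apply_intervention(vstate, "gl", gl_clamped, vitals_models,
                                   profile, thresholds)
      vout[i, ] <- vstate[c("hr", "rr", "sbp", "pt", "gl")]
    }
    if (i < nT) {
      u <- gi_input(D = D, C = C, r = r)
      state <- advance_continuous(comp, state, list(u = u), dt, t)
      if (state[["G"]] < 0) {
        warning("glucose clamped at 0 at t = ", times[[i + 1]], " min")
        state[["G"]] <- 0
      }
      if (!all(is.finite(state))) {
        stop("closed-loop integration blew up at t = ", times[[i + 1]],
             "; state: ", paste(sprintf("%.3g", state), collapse = ", "))
      }
    }
  }
  trace <- tibble::as_tibble(as.data.frame(out))
  if (with_vitals) trace <- dplyr::bind_cols(trace, tibble::as_tibble(as.data.frame(vout)))
  attr(trace, "dt") <- dt
  attr(trace, "horizon") <- horizon
  attr(trace, "model") <- model
  class(trace) <- c("closed_loop_trace", class(trace))
  trace
}

#' Plot a closed-loop glucose trajectory
#'
#' Glucose, insulin command and disturbances against time.
#'
#' @param trace A `closed_loop_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_glucose <- function(trace, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(trace), dplyr::all_of(c("time", "G", "r", "D"))),
    -"time", names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$signal), scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Closed-loop glucose control")
}

#' @export
autoplot.closed_loop_trace <- function(object, ...) plot_glucose(object, ...)
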