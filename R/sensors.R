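#' @title Periodic medical sensors
#' @description Sensor models sample one patient signal on a fixed period; the
#'   local sampling clock is aligned to the global simulation clock, so
#'   measurements fall exactly on multiples of the period.
#' @name sensors
NULL

KNOWN_SIGNALS <- c("hr", "rr", "sbp", "pt", "gl", "G", "X", "I")

#' Sensor configuration
#'
#' @param signal Monitored signal name (one of the patient signals).
#' @param period Sampling period in minutes (> 0).
#' @param id Sensor id; defaults to `"<signal>_sensor"`.
#' @return A `sensor_config`.
#' @export
sensor_config <- function(signal, period, id = paste0(signal, "_sensor")) {
  if (!signal %in% KNOWN_SIGNALS) {
    stop("unknown signal '", signal, "'; known signals: ",
         paste(KNOWN_SIGNALS, collapse = ", "))
  }
  if (period <= 0) stop("sensor period must be > 0")
  structure(list(signal = signal, period = period, id = id),
            class = "sensor_config")
}

#' Sample the patient signal at a time point
#'
#' Emits one measurement iff `t` falls on the sensor's sampling grid
#' (a multiple of the period); otherwise returns `NULL`.
#'
#' @param sensor A `sensor_config`.
#' @param signal_value Current value of the monitored signal at `t`.
#' @param t Time in minutes (>= 0).
#' @return A one-row measurement tibble `(time, signal, value, sensor)`, or
#'   `NULL` off-grid.
#' @export
sensor_sample <- function(sensor, signal_value, t) {
  stopifnot(t >= 0)
  on_grid <- abs(t / sensor$period - round(t / sensor$period)) < 1e-9
  if (!on_grid) return(NULL)
  tibble::tibble(time = t, signal = sensor$signal,
                 value = signal_value, sensor = sensor$id)
}

#' Wrap a sensor as a simulation component
#'
#' @param sensor A `sensor_config`.
#' @return A discrete `sim_component` with input port `value_in` and output
#'   port `measurement`.
#' @export
sensor_component <- function(sensor) {
  sim_component(
    id = sensor$id, kind = "discrete",
    inputs = "value_in", outputs = "measurement",
    state = list(), period = sensor$period,
    step = function(t, state, inputs) {
      list(state = state, outputs = list(measurement = inputs$value_in))
    })
}
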