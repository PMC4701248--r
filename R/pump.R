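#' @title Insulin-pump timed state machine
#' @description Insulin pump with STOP/EXECUTING operation modes, a cartridge
#'   with FULL/NORMAL/LOW/EMPTY status, three delivery strategies (basal,
#'   standard bolus, corrective bolus) and the safety behavior: the pump stops
#'   when the cartridge is empty, too low, or insufficient for the next
#'   scheduled dose. Decision and condition outcomes of the controller logic
#'   are recorded through the coverage instrumentation hooks.
#' @name pump
NULL

#' Insulin-pump configuration
#'
#' Bounds follow the device technical specification: basal rates in
#' \[0.1, 25.0\] U/h, standard bolus at most 25 U, cartridge 3.15 mL of U100
#' insulin = 315 units. The standard basal profile delivers one fixed dose
#' every 3 minutes (480/day); the customized profile delivers one flexible
#' dose per hour (24/day).
#'
#' @param capacity_ml Cartridge capacity in mL of U100 insulin (default 3.15).
#' @param basal_profile `"standard"` or `"customized"`.
#' @param basal_rate Basal rate in U/h (standard profile).
#' @param basal_rates_hourly 24 per-hour basal rates in U/h (customized
#'   profile); defaults to `rep(basal_rate, 24)`.
#' @param standard_bolus Standard (meal) bolus dose in U (<= 25).
#' @param corrective_bolus Corrective bolus dose in U (<= 25).
#' @param bolus_times Programmed meal-bolus times (minutes from start).
#' @param low_threshold Cartridge level at or below which status is LOW
#'   (units; default 10% of capacity, boundary inclusive).
#' @param warn_only_on_low If `TRUE`, a LOW cartridge only raises the warning
#'   and the pump keeps executing; the default (`FALSE`) stops the pump.
#' @return A `pump_config`.
#' @export
pump_config <- function(capacity_ml = 3.15,
                        basal_profile = c("standard", "customized"),
                        basal_rate = 1.0, basal_rates_hourly = NULL,
                        standard_bolus = 6, corrective_bolus = 2,
                        bolus_times = numeric(0),
                        low_threshold = NULL, warn_only_on_low = FALSE) {
  basal_profile <- match.arg(basal_profile)
  capacity <- capacity_ml * 100  # U100: 100 units per mL
  if (is.null(basal_rates_hourly)) basal_rates_hourly <- rep(basal_rate, 24)
  if (length(basal_rates_hourly) != 24) {
    stop("customized basal profile requires 24 hourly rates")
  }
  rates <- c(basal_rate, basal_rates_hourly)
  if (any(rates < 0.1) || any(rates > 25.0)) {
    stop("basal rate outside [0.1, 25.0] U/h")
  }
  if (standard_bolus < 0 || standard_bolus > 25.0) {
    stop("standard bolus outside [0, 25.0] U")
  }
  if (corrective_bolus < 0 || corrective_bolus > 25.0) {
    stop("corrective bolus outside [0, 25.0] U")
  }
  if (is.null(low_threshold)) low_threshold <- 0.1 * capacity
  if (low_threshold <= 0 || low_threshold >= capacity) {
    stop("low threshold must lie strictly inside (0, capacity)")
  }
  structure(list(capacity = capacity, basal_profile = basal_profile,
                 basal_rate = basal_rate,
                 basal_rates_hourly = basal_rates_hourly,
                 standard_bolus = standard_bolus,
                 corrective_bolus = corrective_bolus,
                 bolus_times = bolus_times,
                 low_threshold = low_threshold,
                 warn_only_on_low = warn_only_on_low),
            class = "pump_config")
}

#' Initial pump runtime state
#'
#' @param config A `pump_config`.
#' @param level Initial cartridge level in units (default full).
#' @param mode `"STOP"` or `"EXECUTING"`.
#' @return A `pump_state`.
#' @export
pump_state <- function(config, level = config$capacity, mode = "STOP") {
  st <- check_cartridge_level(level, config)
  structure(list(mode = mode, level = level, level0 = level,
                 status = st$status, alert = st$alert, cumulative = 0,
                 dose_count = 0L),
            class = "pump_state")
}

#' Classify the cartridge level
#'
#' level = 0 is EMPTY ("Cartridge Empty!"); 0 < level <= low threshold is LOW
#' ("Cartridge Low Warning!"); above the threshold the status is NORMAL, or
#' FULL at capacity (both "Cartridge Ok!"). The status enumeration is
#' single-valued, so EMPTY and LOW can never hold simultaneously.
#'
#' @param level Cartridge level in units.
#' @param config A `pump_config`.
#' @param recorder Optional coverage recorder: the `[level == 0]` and
#'   `[level <= low]` decisions are logged per evaluation.
#' @return `list(status =, alert =)`.
#' @export
check_cartridge_level <- function(level, config, recorder = NULL) {
  if (level < 0 || level > config$capacity) {
    stop(sprintf("cartridge state corrupted: level %g outside [0, %g]",
                 level, config$capacity))
  }
  is_empty <- level == 0
  if (!is.null(recorder)) {
    record_decision(recorder, "checkCartridgeLevel/[level == 0]",
                    c(empty = is_empty), is_empty)
  }
  if (is_empty) {
    return(list(status = "EMPTY", alert = "Cartridge Empty!"))
  }
  is_low <- level <= config$low_threshold
  if (!is.null(recorder)) {
    record_decision(recorder, "checkCartridgeLevel/[level <= low]",
                    c(low = is_low), is_low)
  }
  if (is_low) {
    list(status = "LOW", alert = "Cartridge Low Warning!")
  } else if (level == config$capacity) {
    list(status = "FULL", alert = "Cartridge Ok!")
  } else {
    list(status = "NORMAL", alert = "Cartridge Ok!")
  }
}

#' Select the delivery strategy due at a time
#'
#' A corrective request wins immediately; otherwise a programmed meal bolus at
#' its scheduled time; otherwise a basal slot when due (standard profile:
#' every 3 minutes; customized: on the hour). Times are minutes on a 1-minute
#' tick grid.
#'
#' @param t Time in minutes.
#' @param config A `pump_config`.
#' @param corrective Corrective-bolus request flag.
#' @param recorder Optional coverage recorder.
#' @return A `delivery_command` `list(strategy =, dose =)`, or `NULL` when
#'   nothing is due.
#' @export
get_strategy_adm_insulin <- function(t, config, corrective = FALSE,
                                     recorder = NULL) {
  bolus_due <- any(abs(config$bolus_times - t) < 1e-9)
  # a basal slot's dose is delivered at the end of the slot (t = 3, 6, ...)
  basal_due <- t > 0 && if (config$basal_profile == "standard") {
    abs(t / 3 - round(t / 3)) < 1e-9
  } else {
    abs(t / 60 - round(t / 60)) < 1e-9
  }
  if (!is.null(recorder)) {
    record_decision(recorder, "getStrategyAdmInsulin/[corrective]",
                    c(corrective = corrective), corrective)
    record_decision(recorder, "getStrategyAdmInsulin/[bolus_due]",
                    c(bolus_due = bolus_due), bolus_due)
    record_decision(recorder, "getStrategyAdmInsulin/[basal_due]",
                    c(basal_due = basal_due), basal_due)
  }
  if (corrective) {
    cmd <- list(strategy = "CORREC_BOLUS", dose = config$corrective_bolus)
  } else if (bolus_due) {
    cmd <- list(strategy = "STAND_BOLUS", dose = config$standard_bolus)
  } else if (basal_due) {
    cmd <- list(strategy = "BASAL", dose = basal_dose_at(t, config))
  } else {
    return(NULL)
  }
  if (!is.null(recorder)) {
    record_decision(recorder, "getAdmDose/[strategy == BASAL]",
                    c(basal = cmd$strategy == "BASAL"),
                    cmd$strategy == "BASAL")
    record_decision(recorder, "getAdmDose/[strategy == STAND_BOLUS]",
                    c(stand = cmd$strategy == "STAND_BOLUS"),
                    cmd$strategy == "STAND_BOLUS")
    record_decision(recorder, "getAdmDose/[strategy == CORREC_BOLUS]",
                    c(correc = cmd$strategy == "CORREC_BOLUS"),
                    cmd$strategy == "CORREC_BOLUS")
  }
  structure(cmd, class = "delivery_command")
}

basal_dose_at <- function(t, config) {
  if (config$basal_profile == "standard") {
    config$basal_rate * 3 / 60  # rate U/h over a 3-minute slot
  } else {
    hour <- ((ceiling(t / 60) - 1L) %% 24) + 1L
    config$basal_rates_hourly[[hour]]  # rate U/h over a 1-hour slot
  }
}

#' Administer one insulin dose
#'
#' If the cartridge holds at least the programmed dose, the full dose is
#' delivered (administered = programmed, never partial) and the level and
#' cumulative totals are updated. If the level is insufficient, nothing is
#' delivered and the pump stops.
#'
#' @param state A `pump_state` in EXECUTING mode.
#' @param cmd A `delivery_command`.
#' @param recorder Optional coverage recorder.
#' @return The updated `pump_state`, with fields `last_dose` (delivered
#'   units) and `last_programmed` set for the monitors.
#' @export
administer_dose <- function(state, cmd, recorder = NULL) {
  if (cmd$dose < 0) stop("administer_dose: negative dose")
  enough <- state$level >= cmd$dose
  if (!is.null(recorder)) {
    record_decision(recorder, "administerInsulinDose/[level >= dose]",
                    c(enough = enough), enough)
  }
  state$last_programmed <- cmd$dose
  state$last_strategy <- cmd$strategy
  if (enough) {
    state$cumulative <- state$cumulative + cmd$dose
    # level derived from the running total so that
    # initial level - final level == cumulative delivery holds exactly
    state$level <- max(state$level0 - state$cumulative, 0)
    state$dose_count <- state$dose_count + 1L
    state$last_dose <- cmd$dose
  } else {
    state$last_dose <- 0
    state$mode <- "STOP"
  }
  state
}

#' Pump mode transition
#'
#' Run is accepted only while the cartridge status is FULL or NORMAL;
#' EXECUTING falls to STOP within one tick of the status entering LOW or
#' EMPTY (LOW stops only when `warn_only_on_low` is off); Stop is always
#' accepted.
#'
#' @param state A `pump_state`.
#' @param command `"Run"`, `"Stop"` or `NULL`.
#' @param config A `pump_config`.
#' @param recorder Optional coverage recorder.
#' @return The updated `pump_state`.
#' @export
pump_transition <- function(state, command = NULL, config,
                            recorder = NULL) {
  is_low <- state$status == "LOW"
  is_empty <- state$status == "EMPTY"
  is_full <- state$status == "FULL"
  is_normal <- state$status == "NORMAL"
  if (!is.null(recorder)) {
    record_decision(recorder, "Controller/[status == LOW || status == EMPTY]",
                    c(low = is_low, empty = is_empty), is_low || is_empty)
    record_decision(recorder, "Controller/[status == FULL || status == NORMAL]",
                    c(full = is_full, normal = is_normal), is_full || is_normal)
  }
  if (!is.null(command) && command == "Stop") {
    state$mode <- "STOP"
    return(state)
  }
  stop_status <- is_empty || (is_low && !config$warn_only_on_low)
  if (state$mode == "EXECUTING" && stop_status) {
    state$mode <- "STOP"
  } else if (!is.null(command) && command == "Run") {
    if (is_full || is_normal) state$mode <- "EXECUTING"
  }
  state
}

#' One pump tick
#'
#' Per-tick order: mode transition on the previous tick's status (so stopping
#' on LOW/EMPTY happens one tick after the status change), then, while
#' executing, strategy selection, dose administration and cartridge-level
#' check.
#'
#' @param state A `pump_state`.
#' @param config A `pump_config`.
#' @param t Tick time in minutes.
#' @param command Optional user command (`"Run"`/`"Stop"`).
#' @param corrective Corrective-bolus request flag.
#' @param recorder Optional coverage recorder.
#' @return `list(state =, outputs =)` where outputs carries
#'   `insulinPumpStatus`, `cartridgeStatus`, `administered`, `programmed`,
#'   `strategy`, `level`, `alert`.
#' @export
pump_step <- function(state, config, t, command = NULL, corrective = FALSE,
                      recorder = NULL) {
  state <- pump_transition(state, command, config, recorder)
  administered <- 0; programmed <- NA_real_; strategy <- NA_character_
  if (state$mode == "EXECUTING") {
    cmd <- get_strategy_adm_insulin(t, config, corrective, recorder)
    if (!is.null(cmd)) {
      state <- administer_dose(state, cmd, recorder)
      administered <- state$last_dose
      programmed <- state$last_programmed
      strategy <- state$last_strategy
    }
  }
  # daily dose-counter reset
  reset_due <- t > 0 && abs(t / 1440 - round(t / 1440)) < 1e-9
  if (!is.null(recorder)) {
    record_decision(recorder, "resetCount/[day elapsed]",
                    c(day = reset_due), reset_due)
  }
  if (reset_due) state$dose_count <- 0L
  st <- check_cartridge_level(state$level, config, recorder)
  state$status <- st$status
  state$alert <- st$alert
  list(state = state,
       outputs = list(insulinPumpStatus = state$mode,
                      cartridgeStatus = state$status,
                      administered = administered,
                      programmed = programmed,
                      strategy = strategy,
                      level = state$level,
                      alert = st$alert))
}

#' Simulate the pump over a horizon
#'
#' Runs the pump on a 1-minute tick grid from t = 0 to `horizon`, starting
#' with a Run command.
#'
#' @param config A `pump_config`.
#' @param horizon Horizon in minutes (default 1440 = 24 h).
#' @param level Initial cartridge level (default full).
#' @param corrective_times Times at which a corrective bolus is requested.
#' @param recorder Optional coverage recorder.
#' @return A `pump_trace` tibble, one row per tick:
#'   `time, mode, status, level, strategy, dose_programmed,
#'   dose_administered, cumulative, alert`.
#' @export
simulate_pump <- function(config, horizon = 1440, level = config$capacity,
                          corrective_times = numeric(0), recorder = NULL) {
  state <- pump_state(config, level = level)
  times <- 0:horizon
  n <- length(times)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t <- times[[i]]
    res <- pump_step(state, config, t,
                     command = if (t == 0) "Run" else NULL,
                     corrective = any(abs(corrective_times - t) < 1e-9),
                     recorder = recorder)
    state <- res$state
    o <- res$outputs
    rows[[i]] <- tibble::tibble(
      time = t, mode = o$insulinPumpStatus, status = o$cartridgeStatus,
      level = o$level, strategy = o$strategy,
      dose_programmed = o$programmed, dose_administered = o$administered,
      cumulative = state$cumulative, alert = o$alert)
  }
  trace <- dplyr::bind_rows(rows)
  class(trace) <- c("pump_trace", class(trace))
  trace
}

#' Delivery log from a pump trace
#'
#' @param trace A `pump_trace`.
#' @return Tibble `time,strategy,dose,level_after` of delivered doses.
#' @export
delivery_log <- function(trace) {
  d <- dplyr::filter(trace, !is.na(.data$strategy), .data$dose_administered > 0)
  tibble::tibble(time = d$time, strategy = d$strategy,
                 dose = d$dose_administered, level_after = d$level)
}

#' Plot cartridge insulin consumption over time
#' @param trace A `pump_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_insulin_consumption <- function(trace, ...) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (min)", y = "cartridge level (U)",
                  title = "Insulin consumption")
}

#' @export
autoplot.pump_trace <- function(object, ...) plot_insulin_consumption(object, ...)
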