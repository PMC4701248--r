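#' @title Bundled clinical scenarios
#' @description Three proof-of-concept clinical contexts: continuous ICU
#'   monitoring (patient + five sensors + centralizer + bedside monitor),
#'   insulin-pump usage with a daily-dose calculator (safety monitoring and
#'   coverage), and the closed-loop diabetic patient under PID glucose
#'   control with meal disturbances.
#' @name scenarios
NULL

SCENARIO_IDS <- c("icu_monitoring", "insulin_pump", "diabetic_closed_loop",
                  "custom")

#' Load and validate a scenario configuration
#'
#' Hierarchical YAML; the seed is mandatory and all pump bounds / threshold
#' invariants are checked at load time (a basal rate outside
#' \[0.1, 25.0\] U/h, for example, is rejected citing the limit).
#'
#' @param path YAML scenario file.
#' @return A validated `scenario_config` list.
#' @export
load_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario) || !cfg$scenario %in% SCENARIO_IDS) {
    stop("scenario: missing or unknown scenario id (field 'scenario'); ",
         "expected one of ", paste(SCENARIO_IDS, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("scenario '", cfg$scenario, "': seed is mandatory")
  if (is.null(cfg$horizon) || cfg$horizon <= 0) {
    stop("scenario: horizon must be present and > 0")
  }
  if (is.null(cfg$dt)) cfg$dt <- 0.1
  if (cfg$dt <= 0) stop("scenario: dt must be > 0")
  # construct (and thereby bound-check) device configs now
  if (!is.null(cfg$pump)) {
    cfg$pump_config <- do.call(pump_config, cfg$pump)
  }
  if (!is.null(cfg$patient$profile)) {
    cfg$profile <- do.call(patient_profile, cfg$patient$profile)
  }
  if (!is.null(cfg$sensors)) {
    cfg$sensor_configs <- lapply(cfg$sensors, function(s) {
      do.call(sensor_config, s)
    })
  }
  if (!is.null(cfg$disturbances)) {
    d <- dplyr::bind_rows(lapply(cfg$disturbances, tibble::as_tibble))
    cfg$disturbance_schedule <- disturbance_schedule(
      d$time, d$channel, d$magnitude, d$duration)
  } else {
    cfg$disturbance_schedule <- disturbance_schedule()
  }
  structure(cfg, class = "scenario_config")
}

#' Path to a bundled scenario file
#' @param id Scenario id.
#' @return Path inside the installed package.
#' @export
bundled_scenario <- function(id = c("icu_monitoring", "insulin_pump",
                                    "diabetic_closed_loop")) {
  id <- match.arg(id)
  system.file("extdata", "scenarios", paste0(id, ".yaml"),
              package = "mcpsim", mustWork = TRUE)
}

fit_models_for_scenario <- function(cfg) {
  n <- if (!is.null(cfg$cohort$n)) cfg$cohort$n else 200
  cohort <- generate_cohort(cohort_spec(), n = n, seed = cfg$seed)
  default_vital_models(cohort)
}

#' Run a clinical-context scenario
#'
#' Dispatches on the scenario id and returns everything the context
#' produces: the simulation trace, safety verdicts, the coverage report and
#' the delivery/measurement logs (components not applicable to a context are
#' `NULL`).
#'
#' @param config A `scenario_config` from [load_scenario()], or a path.
#' @return An `mcps_results` list: `trace`, `verdicts`, `coverage`,
#'   `delivery_log`, `measurements`, `config`.
#' @export
run_clinical_context <- function(config) {
  if (is.character(config)) config <- load_scenario(config)
  res <- switch(config$scenario,
                icu_monitoring = run_context_icu(config),
                insulin_pump = run_context_pump(config),
                diabetic_closed_loop = run_context_closed_loop(config),
                stop("custom scenarios are run through run_scenario()"))
  res$config <- config
  class(res) <- "mcps_results"
  res
}

run_context_icu <- function(cfg) {
  models <- fit_models_for_scenario(cfg)
  profile <- if (!is.null(cfg$profile)) cfg$profile else patient_profile()
  init <- if (!is.null(cfg$patient$initial)) {
    do.call(vital_state, cfg$patient$initial)
  } else vital_state()
  sensors <- if (!is.null(cfg$sensor_configs)) cfg$sensor_configs else {
    lapply(c("hr", "rr", "sbp", "pt", "gl"), sensor_config, period = 3)
  }
  interventions <- cfg$interventions  # list of {time, sign, value}

  times <- seq(0, cfg$horizon, by = cfg$dt)
  state <- init
  rows <- vector("list", length(times))
  meas <- list()
  for (i in seq_along(times)) {
    t <- times[[i]]
    iv <- Filter(function(x) abs(x$time - t) < 1e-9, interventions %||% list())
    for (x in iv) {
      state <- apply_intervention(state, x$sign, x$value, models, profile)
    }
    # regression models regenerate each modeled sign from the current state
    snapshot <- state
    for (m in models) {
      state[[m$response]] <- predict_vital(m, snapshot, profile)
    }
    rows[[i]] <- tibble::tibble(time = t, component = "icu_patient",
                                signal = names(state),
                                value = as.numeric(state))
    for (s in sensors) {
      m <- sensor_sample(s, state[[s$signal]], t)
      if (!is.null(m)) meas[[length(meas) + 1L]] <- m
    }
  }
  trace <- dplyr::bind_rows(rows)
  attr(trace, "seed") <- cfg$seed
  attr(trace, "horizon") <- cfg$horizon
  attr(trace, "dt") <- cfg$dt
  class(trace) <- c("sim_trace", class(trace))
  measurements <- dplyr::bind_rows(meas)
  # centralizer relays each sensor channel to the bedside monitor unchanged
  measurements$relayed_to <- "bedside_monitor"
  list(trace = trace, verdicts = NULL, coverage = NULL,
       delivery_log = NULL, measurements = measurements)
}

run_context_pump <- function(cfg) {
  profile <- if (!is.null(cfg$profile)) cfg$profile else patient_profile()
  gl <- cfg$patient$initial$gl %||% 119
  doses <- insulin_dose_calculator(profile, gl)
  pc <- cfg$pump_config %||% pump_config()
  # program the pump from the calculator unless the config pins the doses
  if (is.null(cfg$pump$basal_rate)) pc$basal_rate <- min(max(doses$baid, 0.1), 25)
  if (is.null(cfg$pump$standard_bolus)) pc$standard_bolus <- min(doses$boid, 25)
  if (is.null(cfg$pump$corrective_bolus)) pc$corrective_bolus <- min(doses$cboid, 25)
  rec <- decision_recorder()
  trace <- simulate_pump(pc, horizon = cfg$horizon,
                         corrective_times = unlist(cfg$corrective_times) %||% numeric(0),
                         recorder = rec)
  verdicts <- monitor_all(trace)
  list(trace = trace, verdicts = verdicts, coverage = compute_coverage(rec),
       delivery_log = delivery_log(trace), measurements = NULL)
}

run_context_closed_loop <- function(cfg) {
  params <- if (!is.null(cfg$bergman)) do.call(bergman_params, cfg$bergman)
            else bergman_params()
  pid <- if (!is.null(cfg$pid)) do.call(pid_params, cfg$pid)
         else tune_pid(params)
  models <- fit_models_for_scenario(cfg)
  profile <- if (!is.null(cfg$profile)) cfg$profile else patient_profile()
  trace <- simulate_closed_loop(
    params, pid, disturbances = cfg$disturbance_schedule,
    horizon = cfg$horizon, dt = cfg$dt,
    vitals_models = models, profile = profile)
  list(trace = trace, verdicts = NULL, coverage = NULL,
       delivery_log = NULL, measurements = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export scenario results to files
#'
#' Writes the trace CSV (time to six decimals), delivery log, coverage table
#' (plain text and CSV) and verdict summary into a directory; re-exporting
#' identical results is byte-identical.
#'
#' @param results An `mcps_results`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_outputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  tr <- results$trace
  if (!is.null(tr)) {
    p <- file.path(dir, "trace.csv")
    if (all(c("component", "signal") %in% names(tr))) {
      write_trace_csv(tr, p)
    } else {
      df <- as.data.frame(tr)
      df$time <- sprintf("%.6f", df$time)
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    }
    written["trace"] <- p
  }
  if (!is.null(results$delivery_log)) {
    p <- file.path(dir, "delivery_log.csv")
    utils::write.csv(as.data.frame(results$delivery_log), p,
                     row.names = FALSE, quote = FALSE)
    written["delivery_log"] <- p
  }
  if (!is.null(results$coverage)) {
    p <- file.path(dir, "coverage.txt")
    format_coverage(results$coverage, p)
    written["coverage"] <- p
    p2 <- file.path(dir, "coverage.csv")
    utils::write.csv(as.data.frame(results$coverage), p2, row.names = FALSE)
    written["coverage_csv"] <- p2
  }
  if (!is.null(results$verdicts)) {
    p <- file.path(dir, "verdicts.csv")
    utils::write.csv(as.data.frame(results$verdicts), p, row.names = FALSE,
                     quote = FALSE)
    written["verdicts"] <- p
  }
  if (!is.null(results$measurements) && nrow(results$measurements)) {
    p <- file.path(dir, "measurements.csv")
    utils::write.csv(as.data.frame(results$measurements), p,
                     row.names = FALSE, quote = FALSE)
    written["measurements"] <- p
  }
  invisible(written)
}

#' Did any safety verdict fail?
#' @param results An `mcps_results`.
#' @return `TRUE` when a monitored property is violated.
#' @export
any_violation <- function(results) {
  !is.null(results$verdicts) && any(!results$verdicts$holds)
}
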