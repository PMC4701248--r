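#' @title Runtime safety monitoring of pump traces
#' @description Trace-based verification of the pump safety requirements:
#'   SR1 - an empty cartridge (level 0) makes the status EMPTY on the same
#'   tick and stops the pump within a bounded delay; SR2 - a delivery attempt
#'   with insufficient level delivers nothing and stops the pump; SR3 - every
#'   executed basal delivery administers exactly the programmed dose; A1 -
#'   the cartridge status is never EMPTY and LOW at the same instant.
#' @name safety
NULL

#' Declare a safety property
#'
#' @param id `"SR1"`, `"SR2"`, `"SR3"` or `"A1"`.
#' @param delay SR1 stop-delay bound in ticks (default 1).
#' @return A `safety_property`.
#' @export
safety_property <- function(id = c("SR1", "SR2", "SR3", "A1"), delay = 1L) {
  id <- match.arg(id)
  structure(list(id = id, delay = as.integer(delay)), class = "safety_property")
}

require_signals <- function(trace, property, cols) {
  missing <- setdiff(cols, names(trace))
  if (length(missing)) {
    stop(property, " monitor: trace is missing signal(s) ",
         paste(missing, collapse = ", "))
  }
}

verdict <- function(id, holds, first_violation = NA_real_, witness = NULL,
                    worst_delay = NA_integer_) {
  structure(list(property = id, holds = holds,
                 first_violation = first_violation, witness = witness,
                 worst_delay = worst_delay), class = "safety_verdict")
}

#' Monitor a pump trace against a safety property
#'
#' An empty trace holds vacuously for every property (no antecedent instant).
#' A failing verdict carries the earliest counterexample rows as witness.
#'
#' @param trace A `pump_trace` tibble (columns `time`, `mode`, `status`,
#'   `level`, `dose_programmed`, `dose_administered`, `strategy` as each
#'   property requires).
#' @param property A `safety_property` or one of the ids
#'   `"SR1","SR2","SR3","A1"`.
#' @return A `safety_verdict`: property id, holds yes/no, first violation
#'   time and witness rows, and (SR1) the observed worst-case stop delay.
#' @export
monitor_trace <- function(trace, property) {
  if (is.character(property)) property <- safety_property(property)
  switch(property$id,
         SR1 = monitor_sr1(trace, property),
         SR2 = monitor_sr2(trace, property),
         SR3 = monitor_sr3(trace, property),
         A1 = monitor_a1(trace, property))
}

monitor_sr1 <- function(trace, property) {
  require_signals(trace, "SR1", c("time", "mode", "status", "level"))
  idx <- which(trace$level == 0)
  worst <- NA_integer_
  for (i in idx) {
    if (trace$status[i] != "EMPTY") {
      return(verdict("SR1", FALSE, trace$time[i], trace[i, ]))
    }
    upper <- min(i + property$delay, nrow(trace))
    stops <- which(trace$mode[i:upper] == "STOP")
    if (length(stops) == 0) {
      return(verdict("SR1", FALSE, trace$time[i], trace[i:upper, ]))
    }
    d <- stops[1] - 1L
    worst <- if (is.na(worst)) d else max(worst, d)
  }
  verdict("SR1", TRUE, worst_delay = worst)
}

monitor_sr2 <- function(trace, property) {
  require_signals(trace, "SR2",
                  c("time", "mode", "level", "dose_programmed",
                    "dose_administered"))
  # level is recorded after administration; recover the pre-delivery level
  level_before <- trace$level + dplyr::coalesce(trace$dose_administered, 0)
  attempts <- which(!is.na(trace$dose_programmed) &
                      level_before < trace$dose_programmed)
  for (i in attempts) {
    delivered_any <- trace$dose_administered[i] > 0
    upper <- min(i + property$delay, nrow(trace))
    stopped <- any(trace$mode[i:upper] == "STOP")
    if (delivered_any || !stopped) {
      return(verdict("SR2", FALSE, trace$time[i], trace[i, ]))
    }
  }
  verdict("SR2", TRUE)
}

monitor_sr3 <- function(trace, property) {
  require_signals(trace, "SR3",
                  c("time", "strategy", "dose_programmed",
                    "dose_administered"))
  basal <- which(!is.na(trace$strategy) & trace$strategy == "BASAL" &
                   trace$dose_administered > 0)
  for (i in basal) {
    if (trace$dose_administered[i] != trace$dose_programmed[i]) {
      return(verdict("SR3", FALSE, trace$time[i], trace[i, ]))
    }
  }
  verdict("SR3", TRUE)
}

monitor_a1 <- function(trace, property) {
  require_signals(trace, "A1", c("time", "status"))
  by_time <- split(trace$status, trace$time)
  for (tm in names(by_time)) {
    st <- by_time[[tm]]
    if (any(st == "EMPTY") && any(st == "LOW")) {
      t_num <- as.numeric(tm)
      return(verdict("A1", FALSE, t_num, trace[trace$time == t_num, ]))
    }
  }
  verdict("A1", TRUE)
}

#' Run all four safety monitors
#'
#' @param trace A `pump_trace`.
#' @param delay SR1 stop-delay bound in ticks.
#' @return A tibble with one row per property: `property`, `holds`,
#'   `first_violation`.
#' @export
monitor_all <- function(trace, delay = 1L) {
  ids <- c("SR1", "SR2", "SR3", "A1")
  rows <- lapply(ids, function(id) {
    v <- monitor_trace(trace, safety_property(id, delay = delay))
    tibble::tibble(property = v$property, holds = v$holds,
                   first_violation = v$first_violation)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.safety_verdict <- function(x, ...) {
  cat(sprintf("<%s> %s%s\n", x$property,
              if (x$holds) "holds" else "VIOLATED",
              if (!x$holds) sprintf(" (first violation at t = %g)",
                                    x$first_violation) else ""))
  invisible(x)
}
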