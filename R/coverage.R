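#' @title Structural coverage of instrumented decision logic
#' @description Decision (DC), condition (CC) and modified condition/decision
#'   (MC/DC) coverage measured over the recorded evaluations of registered
#'   decision sites. A site is one boolean decision inside a named function
#'   (e.g. `checkCartridgeLevel/[level == 0]`); each evaluation stores the
#'   truth vector of its sub-conditions and the decision outcome.
#' @name coverage
NULL

#' Create a decision recorder
#'
#' A mutable accumulator (environment-backed) that collects decision
#' evaluations for coverage reporting.
#'
#' @return A `decision_recorder`.
#' @export
decision_recorder <- function() {
  e <- new.env(parent = emptyenv())
  e$sites <- list()    # site id -> list(fn, conditions)
  e$records <- list()  # appended evaluations
  structure(e, class = "decision_recorder")
}

#' Register an instrumentation site
#'
#' @param recorder A `decision_recorder`.
#' @param site Site id, conventionally `"function/[decision label]"`.
#' @param conditions Character vector of sub-condition names at the site.
#' @return The recorder, invisibly.
#' @export
register_site <- function(recorder, site, conditions) {
  fn <- sub("/.*$", "", site)
  recorder$sites[[site]] <- list(fn = fn, conditions = conditions)
  invisible(recorder)
}

#' Record one decision evaluation
#'
#' The decision outcome must be a pure function of the condition vector; the
#' recorded outcome is asserted against the disjunction/conjunction-free
#' contract by storing the vector verbatim and refusing a vector/outcome
#' mismatch for single-condition sites.
#'
#' @param recorder A `decision_recorder`.
#' @param site Registered site id. Unregistered sites are registered lazily
#'   when `auto` is `TRUE` (the device models use this), otherwise an error.
#' @param conditions Named logical vector of sub-condition values.
#' @param outcome Logical decision outcome.
#' @param t Optional evaluation time.
#' @param auto Auto-register unknown sites.
#' @return The recorder, invisibly.
#' @export
record_decision <- function(recorder, site, conditions, outcome, t = NA_real_,
                            auto = TRUE) {
  if (is.null(recorder$sites[[site]])) {
    if (!auto) stop("record_decision: site '", site, "' is not registered")
    register_site(recorder, site, names(conditions))
  }
  if (length(conditions) == 1L && !identical(unname(conditions), outcome)) {
    stop("instrumentation bug at site '", site,
         "': outcome disagrees with its single condition")
  }
  recorder$records[[length(recorder$records) + 1L]] <-
    list(site = site, conditions = as.logical(conditions),
         outcome = isTRUE(outcome), t = t)
  invisible(recorder)
}

site_records <- function(recorder, site) {
  Filter(function(r) r$site == site, recorder$records)
}

#' Compute the coverage report
#'
#' Per site: DC = observed decision outcomes / 2; CC per condition = observed
#' truth values / 2, averaged over the site's conditions; MC/DC per condition
#' is satisfied when some observed pair of evaluations differs only in that
#' condition and flips the decision outcome. Sites with a single condition
#' have no independent sub-conditions, so CC and MC/DC are reported NA there,
#' and only multi-condition sites enter the CC/MCDC rollup. Function-level
#' rows aggregate a function's sites with uniform weights; cyclomatic
#' complexity is decision count + 1.
#'
#' @param recorder A `decision_recorder` with registered sites.
#' @return A `coverage_report` tibble with columns `hierarchy`, `level`
#'   (`"function"`/`"site"`), `cyclomatic`, `dc`, `cc`, `mcdc` (percent, NA
#'   where not applicable) and `uncovered` (semicolon-separated outcomes not
#'   yet observed).
#' @export
compute_coverage <- function(recorder) {
  if (length(recorder$sites) == 0L) stop("no instrumentation sites registered")
  site_ids <- names(recorder$sites)

  site_rows <- lapply(site_ids, function(sid) {
    info <- recorder$sites[[sid]]
    recs <- site_records(recorder, sid)
    outcomes <- vapply(recs, `[[`, logical(1), "outcome")
    dc <- 100 * length(unique(outcomes)) / 2
    uncovered <- character(0)
    if (!TRUE %in% outcomes) uncovered <- c(uncovered, "decision true")
    if (!FALSE %in% outcomes) uncovered <- c(uncovered, "decision false")
    k <- length(info$conditions)
    if (k >= 2) {
      vecs <- do.call(rbind, lapply(recs, `[[`, "conditions"))
      cc_per <- vapply(seq_len(k), function(j) {
        if (is.null(vecs)) return(0)
        100 * length(unique(vecs[, j])) / 2
      }, numeric(1))
      mcdc_per <- vapply(seq_len(k), function(j) {
        mcdc_satisfied(vecs, outcomes, j)
      }, logical(1))
      for (j in seq_len(k)) {
        if (cc_per[j] < 100) {
          uncovered <- c(uncovered,
                         paste0("condition '", info$conditions[j], "' not both ways"))
        }
        if (!mcdc_per[j]) {
          uncovered <- c(uncovered,
                         paste0("MC/DC pair for '", info$conditions[j], "'"))
        }
      }
      cc <- mean(cc_per)
      mcdc <- 100 * mean(mcdc_per)
    } else {
      cc <- NA_real_
      mcdc <- NA_real_
    }
    tibble::tibble(hierarchy = sid, fn = info$fn, level = "site",
                   cyclomatic = 2, dc = dc, cc = cc, mcdc = mcdc,
                   uncovered = paste(uncovered, collapse = "; "))
  })
  sites <- dplyr::bind_rows(site_rows)

  fns <- split(sites, sites$fn)
  fn_rows <- lapply(names(fns), function(f) {
    s <- fns[[f]]
    tibble::tibble(hierarchy = paste0("Function:", f), fn = f,
                   level = "function",
                   cyclomatic = nrow(s) + 1,
                   dc = mean(s$dc),
                   cc = if (all(is.na(s$cc))) NA_real_ else mean(s$cc, na.rm = TRUE),
                   mcdc = if (all(is.na(s$mcdc))) NA_real_ else mean(s$mcdc, na.rm = TRUE),
                   uncovered = paste(s$uncovered[nzchar(s$uncovered)],
                                     collapse = "; "))
  })
  fns_tbl <- dplyr::bind_rows(fn_rows)
  total <- tibble::tibble(
    hierarchy = "Model:Insulin Pump Software Model", fn = NA_character_,
    level = "model",
    cyclomatic = nrow(sites) + 1,
    dc = mean(sites$dc),
    cc = if (all(is.na(sites$cc))) NA_real_ else mean(sites$cc, na.rm = TRUE),
    mcdc = if (all(is.na(sites$mcdc))) NA_real_ else mean(sites$mcdc, na.rm = TRUE),
    uncovered = "")
  report <- dplyr::bind_rows(total, fns_tbl, sites)
  class(report) <- c("coverage_report", class(report))
  report
}

#' Per-condition coverage at one site
#'
#' @param recorder A `decision_recorder`.
#' @param site Registered site id.
#' @return Tibble with one row per condition: `condition`, `cc` (percent of
#'   the two truth values observed) and `mcdc` (independent-effect pair
#'   observed).
#' @export
condition_coverage <- function(recorder, site) {
  info <- recorder$sites[[site]]
  if (is.null(info)) stop("unknown site '", site, "'")
  recs <- site_records(recorder, site)
  outcomes <- vapply(recs, `[[`, logical(1), "outcome")
  vecs <- if (length(recs)) do.call(rbind, lapply(recs, `[[`, "conditions"))
  k <- length(info$conditions)
  tibble::tibble(
    condition = info$conditions,
    cc = vapply(seq_len(k), function(j) {
      if (is.null(vecs)) 0 else 100 * length(unique(vecs[, j])) / 2
    }, numeric(1)),
    mcdc = vapply(seq_len(k), function(j) {
      mcdc_satisfied(vecs, outcomes, j)
    }, logical(1)))
}

# condition j independently affects the outcome: an observed pair of
# evaluations identical except in condition j, with opposite outcomes
mcdc_satisfied <- function(vecs, outcomes, j) {
  if (is.null(vecs) || nrow(vecs) < 2) return(FALSE)
  n <- nrow(vecs)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      same_others <- all(vecs[a, -j] == vecs[b, -j])
      if (same_others && vecs[a, j] != vecs[b, j] &&
          outcomes[a] != outcomes[b]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Render a coverage report as a plain-text table
#'
#' Columns Model Hierarchy, Cyclomatic Complexity, DC, CC, MCDC; NA rendered
#' literally.
#'
#' @param report A `coverage_report`.
#' @param path Optional file to write; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written.
#' @export
format_coverage <- function(report, path = NULL) {
  fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.0f%%", x))
  rows <- report[report$level != "site", ]
  lines <- c(
    sprintf("%-45s %10s %6s %6s %6s", "Model Hierarchy",
            "Cyclomatic", "DC", "CC", "MCDC"),
    sprintf("%-45s %10d %6s %6s %6s", rows$hierarchy, as.integer(rows$cyclomatic),
            fmt_pct(rows$dc), fmt_pct(rows$cc), fmt_pct(rows$mcdc)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
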