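nominal_trace <- function() {
  simulate_pump(pump_config(basal_rate = 1.2), horizon = 1440)
}

test_that("all four monitors hold on a nominal 24 h pump run", {
  tr <- nominal_trace()
  v <- monitor_all(tr)
  expect_true(all(v$holds))
  expect_equal(v$property, c("SR1", "SR2", "SR3", "A1"))
})

test_that("an empty trace holds vacuously for every property", {
  empty <- tibble::tibble(time = numeric(0), mode = character(0),
                          status = character(0), level = numeric(0),
                          strategy = character(0),
                          dose_programmed = numeric(0),
                          dose_administered = numeric(0))
  for (id in c("SR1", "SR2", "SR3", "A1")) {
    expect_true(monitor_trace(empty, id)$holds)
  }
})

test_that("a missing signal is reported with the property name", {
  tr <- nominal_trace()
  expect_error(monitor_trace(dplyr::select(tr, -"level"), "SR1"),
               "SR1.*level")
})

test_that("monitors flag every member of a fault-injected mutant trace family", {
  # the mutants and the classification oracle are built independently of the
  # monitor implementations
  base <- simulate_pump(pump_config(basal_rate = 1.25, low_threshold = 0.5,
                                        warn_only_on_low = TRUE),
                        horizon = 1440, level = 6.25)  # runs dry mid-day
  stopifnot("EMPTY" %in% base$status)
  i_empty <- which(base$level == 0)[1]
  i_deliv <- which(!is.na(base$strategy) & base$dose_administered > 0)[5]

  mutate_rows <- function(tr, what) {
    m <- tr
    if (what == "sr1_status") m$status[i_empty] <- "NORMAL"
    if (what == "sr1_mode") m$mode[i_empty:nrow(m)] <- "EXECUTING"
    if (what == "sr2_deliver") {
      # keep delivering past an insufficient level: programmed 0.0625 U but
      # only 0.01 U remained before the (mutated) delivery
      j <- which(m$level == 0)
      m$dose_programmed[j] <- 0.0625
      m$dose_administered[j] <- 0.01
      m$strategy[j] <- "BASAL"
      m$mode[j] <- "EXECUTING"
    }
    if (what == "sr3_partial") m$dose_administered[i_deliv] <-
        m$dose_programmed[i_deliv] / 2
    if (what == "a1_dual") m <- dplyr::bind_rows(
      m, dplyr::mutate(m[i_empty, ], status = "LOW"))
    m
  }

  cases <- list(sr1_status = "SR1", sr1_mode = "SR1", sr2_deliver = "SR2",
                sr3_partial = "SR3", a1_dual = "A1")
  for (what in names(cases)) {
    m <- mutate_rows(base, what)
    v <- monitor_trace(m, cases[[what]])
    expect_false(v$holds, info = what)
    expect_false(is.na(v$first_violation), info = what)
    expect_true(nrow(v$witness) >= 1, info = what)
  }

  # monitor and independent direct-scan oracle classify a perturbed family
  # identically
  set.seed(123)
  for (k in 1:20) {
    m <- base
    i <- sample(nrow(m), 1)
    field <- sample(c("dose_administered", "mode", "status"), 1)
    if (field == "dose_administered" && !is.na(m$dose_programmed[i])) {
      m$dose_administered[i] <- m$dose_programmed[i] * sample(c(0.5, 2), 1)
    } else if (field == "mode") {
      m$mode[i] <- if (m$mode[i] == "STOP") "EXECUTING" else "STOP"
    } else {
      m$status[i] <- sample(c("FULL", "NORMAL", "LOW", "EMPTY"), 1)
    }
    expect_equal(monitor_trace(m, "SR1")$holds, oracle_sr1_holds(m), info = k)
    expect_equal(monitor_trace(m, "SR2")$holds, oracle_sr2_holds(m), info = k)
    expect_equal(monitor_trace(m, "SR3")$holds, oracle_sr3_holds(m), info = k)
  }
})

test_that("SR1 verdict reports the observed worst-case stop delay", {
  base <- simulate_pump(pump_config(basal_rate = 1.25, low_threshold = 0.5,
                                        warn_only_on_low = TRUE),
                        horizon = 1440, level = 6.25)
  v <- monitor_trace(base, safety_property("SR1", delay = 1))
  expect_true(v$holds)
  expect_lte(v$worst_delay, 1)
})

test_that("decision recording validates outcome/vector consistency", {
  rec <- decision_recorder()
  register_site(rec, "f/[x > 0]", "x_pos")
  record_decision(rec, "f/[x > 0]", c(x_pos = FALSE), FALSE)
  record_decision(rec, "f/[x > 0]", c(x_pos = FALSE), FALSE)  # duplicates kept
  expect_length(rec$records, 2)
  expect_error(record_decision(rec, "f/[x > 0]", c(x_pos = TRUE), FALSE),
               "instrumentation bug")
  expect_error(record_decision(rec, "ghost/[y]", c(y = TRUE), TRUE,
                               auto = FALSE),
               "not registered")
})

test_that("a site observed only false reports 50% decision coverage", {
  rec <- decision_recorder()
  register_site(rec, "checkCartridgeLevel/[level == 0]", "empty")
  record_decision(rec, "checkCartridgeLevel/[level == 0]",
                  c(empty = FALSE), FALSE)
  rep <- compute_coverage(rec)
  site <- rep[rep$hierarchy == "checkCartridgeLevel/[level == 0]", ]
  expect_equal(site$dc, 50)
  expect_true(is.na(site$cc))       # single condition: CC/MCDC not applicable
  expect_true(is.na(site$mcdc))
  expect_match(site$uncovered, "decision true")
})

test_that("exhaustive evaluation of k-condition decisions yields 100% DC/CC/MCDC", {
  for (k in 2:4) {
    rec <- decision_recorder()
    site <- sprintf("f/[or%d]", k)
    register_site(rec, site, paste0("c", seq_len(k)))
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (i in seq_len(nrow(grid))) {
      vec <- as.logical(grid[i, ])
      names(vec) <- paste0("c", seq_len(k))
      record_decision(rec, site, vec, any(vec))
    }
    rep <- compute_coverage(rec)
    site_row <- rep[rep$level == "site", ]
    expect_equal(site_row$dc, 100)
    expect_equal(site_row$cc, 100)
    expect_equal(site_row$mcdc, 100)
  }
})

test_that("partially observed 'a || b' matches the brute-force oracle", {
  rec <- decision_recorder()
  register_site(rec, "f/[a || b]", c("a", "b"))
  vecs <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  outcomes <- c(TRUE, TRUE)
  for (i in 1:2) {
    record_decision(rec, "f/[a || b]",
                    stats::setNames(vecs[i, ], c("a", "b")), outcomes[i])
  }
  pc <- condition_coverage(rec, "f/[a || b]")
  expect_equal(pc$cc, c(50, 100))           # a seen only true; b both ways
  expect_equal(pc$mcdc, c(FALSE, FALSE))    # no outcome-flipping pair
  oracle <- brute_coverage(vecs, outcomes)
  expect_equal(pc$cc, oracle$cc)
  expect_equal(pc$mcdc, oracle$mcdc)
  site_row <- compute_coverage(rec)
  expect_equal(site_row$dc[site_row$level == "site"], oracle$dc)
})

test_that("coverage percentages never decrease as evaluations accumulate", {
  set.seed(55)
  rec <- decision_recorder()
  register_site(rec, "f/[a && b]", c("a", "b"))
  prev <- c(dc = 0, cc = 0, mcdc = 0)
  for (i in 1:12) {
    vec <- stats::setNames(sample(c(TRUE, FALSE), 2, replace = TRUE),
                           c("a", "b"))
    record_decision(rec, "f/[a && b]", vec, all(vec))
    rep <- compute_coverage(rec)
    row <- rep[rep$level == "site", ]
    now <- c(dc = row$dc, cc = row$cc, mcdc = row$mcdc)
    expect_true(all(now >= prev))
    prev <- now
  }
})

test_that("the instrumented pump controller produces the expected uncovered outcomes", {
  rec <- decision_recorder()
  tr <- simulate_pump(pump_config(basal_rate = 1.2), horizon = 720,
                      recorder = rec)
  rep <- compute_coverage(rec)
  # a healthy cartridge never empties: the [level == 0] decision stays false
  site <- rep[rep$hierarchy == "checkCartridgeLevel/[level == 0]", ]
  expect_equal(site$dc, 50)
  # the coverage table renders NA literally for condition-free sites
  txt <- format_coverage(rep)
  expect_true(any(grepl("NA", txt)))
})
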