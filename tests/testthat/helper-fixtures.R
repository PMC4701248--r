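# shared builders for the test suite

ref_state <- function() vital_state(hr = 87, rr = 19, sbp = 117, pt = 37, gl = 119)

# independent hand evaluation of the published rr polynomial (kept as a
# spelled-out sum so it cannot share code with eval_linear_predictor)
hand_eta_rr <- function(hr, sbp, pt, gl, g2 = 0, g3 = 0, g4 = 0) {
  0.002556 - 0.00005756 * hr + 0.00005381 * sbp - 0.0001206 * pt -
    0.00001715 * gl - 0.0009802 * g2 - 0.002567 * g3 + 0.001027 * g4 -
    0.0000004994 * (hr * sbp) + 0.0000001579 * (hr * gl)
}

random_bergman <- function() {
  bergman_params(p1 = runif(1, 0.01, 0.06), p2 = runif(1, 0.01, 0.06),
                 p3 = runif(1, 1e-5, 1e-4), n = runif(1, 0.05, 0.2),
                 Gb = runif(1, 70, 110), Ib = runif(1, 5, 20),
                 tau = runif(1, 0.5, 2))
}

# central finite-difference Jacobian of the gamma-free field
numerical_jacobian <- function(params, x0, u0, h = 1e-5) {
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    xp <- x0 + e; xm <- x0 - e
    names(xp) <- names(xm) <- c("G", "X", "I")
    J[, j] <- (bmm_derivatives(xp, params, u0) -
                 bmm_derivatives(xm, params, u0)) / (2 * h)
  }
  J
}

# direct scan oracles for the safety monitors, written independently of the
# monitor implementations (plain loops over rows)
oracle_sr2_holds <- function(trace) {
  lvl_before <- trace$level + ifelse(is.na(trace$dose_administered), 0,
                                     trace$dose_administered)
  for (i in seq_len(nrow(trace))) {
    if (!is.na(trace$dose_programmed[i]) &&
        lvl_before[i] < trace$dose_programmed[i]) {
      upper <- min(i + 1, nrow(trace))
      if (trace$dose_administered[i] > 0) return(FALSE)
      if (!any(trace$mode[i:upper] == "STOP")) return(FALSE)
    }
  }
  TRUE
}

oracle_sr3_holds <- function(trace) {
  for (i in seq_len(nrow(trace))) {
    if (!is.na(trace$strategy[i]) && trace$strategy[i] == "BASAL" &&
        trace$dose_administered[i] > 0 &&
        trace$dose_administered[i] != trace$dose_programmed[i]) {
      return(FALSE)
    }
  }
  TRUE
}

oracle_sr1_holds <- function(trace, delay = 1) {
  for (i in seq_len(nrow(trace))) {
    if (trace$level[i] == 0) {
      if (trace$status[i] != "EMPTY") return(FALSE)
      upper <- min(i + delay, nrow(trace))
      if (!any(trace$mode[i:upper] == "STOP")) return(FALSE)
    }
  }
  TRUE
}

# brute-force DC/CC/MCDC over an explicit evaluation list
brute_coverage <- function(vecs, outcomes) {
  k <- ncol(vecs)
  dc <- length(unique(outcomes)) / 2
  cc <- vapply(seq_len(k), function(j) length(unique(vecs[, j])) / 2,
               numeric(1))
  mcdc <- vapply(seq_len(k), function(j) {
    n <- nrow(vecs)
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        if (all(vecs[a, -j] == vecs[b, -j]) && vecs[a, j] != vecs[b, j] &&
            outcomes[a] != outcomes[b]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  list(dc = 100 * dc, cc = 100 * cc, mcdc = mcdc)
}

tiny_gamma_data <- function(n = 15, seed = 11) {
  set.seed(seed)
  x <- runif(n, 0, 1)
  mu <- 1 / (0.05 + 0.03 * x)
  data.frame(x = x, y = rgamma(n, shape = 20, scale = mu / 20))
}
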