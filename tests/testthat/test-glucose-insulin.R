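test_that("minimal-model derivatives match a term-by-term hand evaluation", {
  p <- bergman_params()
  # basal rest point
  expect_equal(bmm_derivatives(gi_state(G = p$Gb, X = 0, I = p$Ib), p),
               c(G = 0, X = 0, I = 0))

  # decoupled meal response
  d <- bmm_derivatives(gi_state(G = 120, X = 0, I = p$Ib), p,
                       gi_input(D = 2))
  expect_equal(unname(d[["G"]]), -p$p1 * (120 - p$Gb) + 2)
  expect_equal(unname(d[["X"]]), 0)
  expect_equal(unname(d[["I"]]), 0)

  # arbitrary state against the spelled-out equations
  set.seed(31)
  for (k in 1:20) {
    pr <- random_bergman()
    G <- runif(1, 40, 200); X <- runif(1, 0, 0.05); I <- runif(1, 1, 60)
    D <- runif(1, 0, 3); C <- runif(1, 0, 1); r <- runif(1, 0, 5)
    got <- bmm_derivatives(gi_state(G, X, I), pr, gi_input(D, C, r))
    expect_equal(unname(got[["G"]]),
                 -pr$p1 * (G - pr$Gb) - X * G + D + C, tolerance = 1e-12)
    expect_equal(unname(got[["X"]]),
                 -pr$p2 * X + pr$p3 * (I - pr$Ib), tolerance = 1e-12)
    expect_equal(unname(got[["I"]]),
                 -pr$n * (I - pr$Ib) + pr$tau * r, tolerance = 1e-12)
  }

  # endogenous secretion term engages only above the threshold and scales with t
  g_on <- bmm_derivatives(gi_state(p$h + 10, 0, p$Ib), p, t = 5,
                          include_gamma = TRUE)
  expect_equal(unname(g_on[["I"]]), p$gamma * 10 * 5)
  g_below <- bmm_derivatives(gi_state(p$h - 5, 0, p$Ib), p, t = 5,
                             include_gamma = TRUE)
  expect_equal(unname(g_below[["I"]]), 0)
})

test_that("equilibrium_point satisfies its closed form and zeroes the field", {
  p <- bergman_params()
  op0 <- equilibrium_point(p, gi_input())
  expect_equal(op0$x0, c(G = p$Gb, X = 0, I = p$Ib))

  # r0 = 0 with sustained disturbance: glucose shifts by (D0+C0)/p1
  op1 <- equilibrium_point(p, gi_input(D = 0.8, C = 0.2))
  expect_equal(unname(op1$x0[["G"]]), p$Gb + 1 / p$p1)
  expect_equal(unname(op1$x0[["X"]]), 0)
  expect_equal(unname(op1$x0[["I"]]), p$Ib)

  # residual check over random parameter sets and inputs
  set.seed(77)
  for (k in 1:100) {
    pr <- random_bergman()
    u0 <- gi_input(D = runif(1, 0, 2), C = runif(1, 0, 1), r = runif(1, 0, 3))
    op <- equilibrium_point(pr, u0)
    res <- bmm_derivatives(op$x0, pr, u0)
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("linearization has the closed-form Jacobian and first-order accuracy", {
  p <- bergman_params()
  op <- equilibrium_point(p, gi_input(r = 1))
  m <- linearize(p, op)

  expect_equal(unname(m$A[1, 1]), -p$p1 - op$x0[["X"]])
  expect_equal(unname(m$A[1, 2]), -op$x0[["G"]])
  expect_equal(unname(m$A[1, 3]), 0)
  expect_equal(unname(diag(m$A)), unname(c(-p$p1 - op$x0[["X"]], -p$p2, -p$n)))
  expect_equal(unname(m$B[, "D"]), c(1, 0, 0))
  expect_equal(unname(m$B[, "r"]), c(0, 0, p$tau))
  expect_true(all(Re(ss_poles(m)) < 0))

  # numerical Jacobian oracle
  J <- numerical_jacobian(p, op$x0, op$u0)
  expect_equal(J, unname(m$A), tolerance = 1e-6)

  # at X0 = 0 and G0 = Gb the top-left block reduces to (-p1, -Gb)
  m0 <- linearize(p, equilibrium_point(p, gi_input()))
  expect_equal(unname(m0$A[1, 1]), -p$p1)
  expect_equal(unname(m0$A[1, 2]), -p$Gb)
})

test_that("linearized field agrees with the nonlinear one to second order", {
  p <- bergman_params()
  op <- equilibrium_point(p, gi_input(r = 0.5))
  # the only nonlinearity is bilinear, so the error is exactly dG*dX and the
  # Richardson ratio at delta/2 is exactly 4
  expect_equal(linearized_derivatives(op$x0, p, op$u0, op),
               c(G = 0, X = 0, I = 0), tolerance = 1e-9)
  set.seed(5)
  for (k in 1:10) {
    delta <- runif(3, -1, 1) * c(5, 0.01, 2)
    err <- function(s) {
      x <- op$x0 + s * delta
      names(x) <- c("G", "X", "I")
      max(abs(bmm_derivatives(x, p, op$u0) -
                linearized_derivatives(x, p, op$u0, op)))
    }
    e1 <- err(1); e2 <- err(0.5)
    expect_equal(e1 / e2, 4, tolerance = 1e-6)
  }
  # with Xbar = 0 the bilinear correction vanishes on the X = 0 slice
  op0 <- equilibrium_point(p, gi_input())
  st <- gi_state(G = 150, X = 0, I = 30)
  expect_equal(linearized_derivatives(st, p, gi_input(D = 1), op0)[["G"]],
               bmm_derivatives(st, p, gi_input(D = 1))[["G"]])
})

test_that("transfer-function gains match symbolic expansion and a step-response oracle", {
  p <- bergman_params()
  op <- equilibrium_point(p, gi_input())
  m <- linearize(p, op)

  tfd <- ss_to_transfer_gains(m, "D")
  # with X0 = 0 the (s+p2)(s+n) factors cancel: T(s) = 1/(s+p1)
  expect_equal(tfd$num, c(p$p2 * p$n, p$p2 + p$n, 1))
  expect_equal(tfd$den,
               c(p$p1 * p$p2 * p$n,
                 p$p1 * p$p2 + p$p1 * p$n + p$p2 * p$n,
                 p$p1 + p$p2 + p$n, 1))
  expect_equal(tfd$num[1] / tfd$den[1], 1 / p$p1)

  # DC gain equals the steady-state gain of a long linearized simulation
  D0 <- 0.5
  st <- op$x0
  comp <- sim_component("lin", "continuous", state = st,
                        derivs = function(t, s, i) {
                          linearized_derivatives(s, p, gi_input(D = D0), op)
                        })
  for (k in 1:4000) st <- advance_continuous(comp, st, list(), 0.5)
  dc_sim <- (st[["G"]] - op$x0[["G"]]) / D0
  expect_equal(dc_sim, tfd$num[1] / tfd$den[1], tolerance = 1e-6)

  # r channel: numerator is the constant -G0 p3 tau, proportional to tau
  tfr <- ss_to_transfer_gains(m, "r")
  expect_equal(tfr$num, -op$x0[["G"]] * p$p3 * p$tau)
  p2x <- bergman_params(tau = 2)
  m2 <- linearize(p2x, equilibrium_point(p2x, gi_input()))
  expect_equal(ss_to_transfer_gains(m2, "r")$num, 2 * tfr$num)
})

test_that("PID terms follow their discrete closed forms and never emit negative insulin", {
  # pure proportional
  pid <- pid_params(Kp = 2, Ki = 0, Kd = 0)
  out <- pid_step(pid, pid_state(), error = 1.5, dt = 1)
  expect_equal(out$r, 3)

  # backward-Euler integral: constant error accumulates Ki*e*k*dt
  pid_i <- pid_params(Kp = 0, Ki = 0.2, Kd = 0)
  st <- pid_state()
  for (k in 1:7) {
    out <- pid_step(pid_i, st, error = 2, dt = 0.5)
    st <- out$state
    expect_equal(out$r, 0.2 * 2 * k * 0.5)
  }

  # filtered derivative decays geometrically with ratio 1/(1 + N dt)
  pid_d <- pid_params(Kp = 0, Ki = 0, Kd = 3, N = 0.4)
  st <- pid_state()
  st <- pid_step(pid_d, st, error = 0, dt = 1)$state   # prime at zero error
  dt <- 1; E <- 2
  expected <- pid_d$Kd * pid_d$N * E / (1 + pid_d$N * dt)
  for (k in 1:6) {
    out <- pid_step(pid_d, st, error = E, dt = dt)
    st <- out$state
    expect_equal(out$r, expected, tolerance = 1e-12)
    expected <- expected / (1 + pid_d$N * dt)
  }

  # saturation at zero with anti-windup: negative command clamps, integral holds
  pid_n <- pid_params(Kp = 1, Ki = 0.5, Kd = 0)
  st <- pid_state()
  out <- pid_step(pid_n, st, error = -10, dt = 1)
  expect_equal(out$r, 0)
  expect_equal(out$state$integral, 0)
})

test_that("default tuned gains stabilize the linearized loop", {
  p <- bergman_params()
  pid <- tune_pid(p)
  poles <- closed_loop_poles(p, pid)
  expect_true(all(Re(poles) < 0))
})

test_that("closed loop stays at basal without disturbance and recovers from a meal", {
  p <- bergman_params()
  tr0 <- simulate_closed_loop(p, horizon = 120, dt = 0.5)
  expect_lt(max(abs(tr0$G - p$Gb)), 1e-6)
  expect_true(all(tr0$r >= 0))

  dist <- disturbance_schedule(time = 60, channel = "D",
                               magnitude = 1.5, duration = 30)
  tr <- simulate_closed_loop(p, disturbances = dist, horizon = 600, dt = 0.5)
  expect_gt(max(tr$G), p$Gb + 5)   # the meal is visible
  late <- tr$G[tr$time > 500]
  expect_true(all(abs(late - p$Gb) < 0.05 * p$Gb))
  expect_true(all(tr$r >= 0))
})

test_that("linearized and nonlinear closed-loop responses share their curve shape", {
  p <- bergman_params()
  dist <- disturbance_schedule(time = 60, channel = "D",
                               magnitude = 1.5, duration = 30)
  trn <- simulate_closed_loop(p, disturbances = dist, horizon = 400, dt = 0.5)
  trl <- simulate_closed_loop(p, disturbances = dist, horizon = 400, dt = 0.5,
                              model = "linear")
  t_peak_n <- trn$time[which.max(trn$G)]
  t_peak_l <- trl$time[which.max(trl$G)]
  expect_lt(abs(t_peak_n - t_peak_l) / t_peak_n, 0.10)
})

test_that("glucose control co-adjusts the regression-model vitals", {
  p <- bergman_params()
  co <- generate_cohort(cohort_spec(), n = 120, seed = 8)
  models <- default_vital_models(co)
  dist <- disturbance_schedule(time = 30, channel = "D",
                               magnitude = 2, duration = 20)
  tr <- simulate_closed_loop(p, disturbances = dist, horizon = 120, dt = 1,
                             vitals_models = models,
                             profile = patient_profile())
  expect_true(all(c("hr", "rr", "sbp", "pt", "gl") %in% names(tr)))
  expect_equal(tr$gl, pmin(pmax(tr$G, 47), 188))
  # at least one modeled vital reacts to the glucose excursion
  expect_true(any(diff(tr$hr) != 0) || any(diff(tr$rr) != 0) ||
                any(diff(tr$sbp) != 0))
})
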