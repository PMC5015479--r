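test_that("zero input keeps the system at equilibrium", {
  p <- model_params(alpha = 2, k = 0.05, v_b0 = 4000)
  s <- fluid_schedule(0, u = 0, v = 0, duration = 120)
  sim <- simulate_volume(p, s, seq(0, 120, 10))
  for (col in c("dVB", "vb_frac", "rB", "eB", "q", "dVISF")) {
    expect_equal(sim[[col]], rep(0, nrow(sim)), info = col)
  }
  expect_equal(reconstruct_interstitial(sim)$dVISF, rep(0, nrow(sim)))
})

test_that("constant-infusion response matches the analytic solution", {
  p <- model_params(alpha = 2, k = 0.05, v_b0 = 4000)
  s <- fluid_schedule(0, u = 20, v = 0, duration = 400)
  tt <- seq(0, 10 / p$k, by = 2)
  sim <- simulate_volume(p, s, tt)
  expected <- oracle_const_infusion(p$alpha, p$k, 20, tt)
  expect_equal(sim$dVB, expected, tolerance = 1e-10)
  # frozen spot value from the closed form
  expect_equal(sim$dVB[sim$time == 30], 407.1653, tolerance = 1e-6)
})

test_that("a bolus settles at the 1/(1+alpha) share of the infused volume", {
  p <- model_params(alpha = 2, k = 0.05, v_b0 = 4000)
  s <- fluid_schedule(c(0, 30), u = c(50, 0), v = 0, duration = 30 + 12 / p$k)
  sim <- simulate_volume(p, s, c(0, schedule_duration(s)))
  expect_equal(tail(sim$dVB, 1), 1500 / 3, tolerance = 1e-4)
  expect_equal(tail(sim$q, 1), 0, tolerance = 1e-3)
})

test_that("volume is conserved between the two compartments", {
  p <- saline_params()
  s <- bolus_schedule(v = 0.5)
  tt <- seq(0, 240, by = 1)
  sim <- simulate_volume(p, s, tt)
  net <- cumulative_net_input(s, tt)
  # simulation-internal interstitial series is conservation-exact
  expect_equal(sim$dVB + sim$dVISF, net, tolerance = 1e-12)
  # quadrature reconstruction from q agrees within 0.5% of total infused
  isf_hat <- reconstruct_interstitial(sim)$dVISF
  total_infused <- 62.5 * 30
  expect_lt(max(abs(sim$dVB + isf_hat - net)), 0.005 * total_infused)
})

test_that("the controller regulates the interstitial:intravascular ratio at alpha", {
  for (alpha in c(0.45, 3)) {
    p <- model_params(alpha = alpha, k = 0.05, v_b0 = 4000)
    s <- fluid_schedule(c(0, 30), u = c(40, 0), v = 0, duration = 30 + 10 / p$k)
    sim <- simulate_volume(p, s, c(0, schedule_duration(s)))
    ratio <- tail(sim$dVISF, 1) / tail(sim$dVB, 1)
    expect_lt(abs(ratio - alpha) / alpha, 0.01)
  }
})

test_that("fluid shifts toward the interstitium exactly when dVB exceeds its target", {
  p <- model_params(alpha = 2.5, k = 0.06, v_b0 = 5000)
  s <- fluid_schedule(c(0, 30, 60), u = c(50, 0, 0), v = c(0, 0, 20),
                      duration = 200)
  sim <- simulate_volume(p, s, seq(0, 200, 0.5))
  nz <- abs(sim$eB) > 1e-9
  expect_true(all(sign(sim$q[nz]) == sign(sim$dVB[nz] - sim$rB[nz])))
  expect_equal(sim$q, -p$k * sim$eB)
})

test_that("the model is linear: doubling the inputs doubles the response", {
  p <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
  s1 <- fluid_schedule(c(0, 30), u = c(40, 0), v = c(2, 2), duration = 240)
  s2 <- fluid_schedule(c(0, 30), u = c(80, 0), v = c(4, 4), duration = 240)
  tt <- seq(0, 240, 5)
  expect_equal(simulate_volume(p, s2, tt)$dVB,
               2 * simulate_volume(p, s1, tt)$dVB,
               tolerance = 1e-12)
})

test_that("the piecewise closed form agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- model_params(alpha = 2.35, k = 0.047, v_b0 = 5560)
  s <- fluid_schedule(c(0, 30), u = c(62.5, 0), v = c(1, 2), duration = 240)
  tt <- seq(0, 240, 5)
  rhs <- function(t, y, parms) {
    r <- schedule_rates(s, t)
    cnet <- r$u - r$v
    list(c(cnet + p$k * (y[2] - y[1]), cnet / (1 + p$alpha)))
  }
  num <- deSolve::ode(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-8,
                      method = "lsoda")
  sim <- simulate_volume(p, s, tt)
  expect_lt(max(abs(num[, 2] - sim$dVB)), 1e-4)
})

test_that("simulation rejects invalid grids and parameters", {
  p <- model_params(2, 0.05, 4000)
  s <- fluid_schedule(0, u = 10, duration = 60)
  expect_error(simulate_volume(p, s, numeric(0)), class = "fluidshift_error_input")
  expect_error(simulate_volume(p, s, c(5, 10)), class = "fluidshift_error_input")
  expect_error(simulate_volume(p, s, c(0, 10, 90)), class = "fluidshift_error_range")
  expect_error(model_params(-1, 0.05, 4000), class = "fluidshift_error_domain")
  expect_error(model_params(2, 0, 4000), class = "fluidshift_error_domain")
})
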