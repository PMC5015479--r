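test_that("theta and model parameters are inverse mappings", {
  p <- model_params(alpha = 3, k = 0.05, v_b0 = 4000)
  th <- theta_from_params(p)
  expect_equal(th, c(0.05, 2.5e-4, 3.125e-6))
  back <- params_from_theta(th)
  expect_equal(back$alpha, 3)
  expect_equal(back$k, 0.05)
  expect_equal(back$v_b0, 4000)
  # a negative first element is read as the (positive) gain
  neg <- params_from_theta(c(-0.05, 2.5e-4, 3.125e-6))
  expect_equal(neg$k, 0.05)
  expect_equal(neg$alpha, 3)
})

test_that("inadmissible regression vectors are flagged", {
  # theta3 = theta1 * theta2 implies alpha = 0
  expect_error(params_from_theta(c(0.05, 2.5e-4, 0.05 * 2.5e-4)),
               class = "fluidshift_error_inadmissible")
  expect_error(params_from_theta(c(0.05, -2.5e-4, 3.125e-6)),
               class = "fluidshift_error_inadmissible")
  expect_error(params_from_theta(c(0, 2.5e-4, 3.125e-6)),
               class = "fluidshift_error_domain")
  expect_error(params_from_theta(c(0.05, 2.5e-4)),
               class = "fluidshift_error_input")
})

test_that("regression on a noiseless trace recovers the generating parameters", {
  p <- model_params(alpha = 3, k = 0.05, v_b0 = 4000)
  s <- fluid_schedule(c(0, 30), u = c(20, 0), v = 0, duration = 180)
  tr <- synthetic_trace(p, s, t_s = 1, noise_sd = 0)
  reg <- regression_design(tr, s)
  expect_false(is.null(reg$params))
  expect_lt(rel_err(reg$params$k, p$k), 0.02)
  expect_lt(rel_err(reg$params$v_b0, p$v_b0), 0.02)
  expect_lt(rel_err(reg$params$alpha, p$alpha), 0.02)
})

test_that("degenerate or malformed data are rejected by the regression", {
  s <- fluid_schedule(0, u = 0, v = 0, duration = 100)
  flat <- volume_trace(seq(0, 100, 10), rep(0, 11))
  expect_error(regression_design(flat, s), class = "fluidshift_error_noninformative")

  nonuniform <- volume_trace(c(0, 5, 15, 40, 80, 100), c(0, 1, 2, 3, 4, 5) / 100)
  expect_error(regression_design(nonuniform, s), class = "fluidshift_error_input")

  short <- volume_trace(c(0, 10, 20), c(0, 0.1, 0.15))
  expect_error(regression_design(short, s), class = "fluidshift_error_input")
})

test_that("noiseless fits recover reference-magnitude parameters within 1%", {
  p <- saline_params()
  s <- bolus_schedule()
  tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0)
  fit <- fit_blood_volume(tr, s, fit_options(n_starts = 4))
  expect_lt(rel_err(fit$params$alpha, p$alpha), 0.01)
  expect_lt(rel_err(fit$params$k, p$k), 0.01)
  expect_lt(rel_err(fit$params$v_b0, p$v_b0), 0.01)
  # the trace is the model's own output, so the optimum is an exact fit
  expect_lt(fit$objective, 1e-12)
  expect_lt(fit$rmsne, 1e-4)
})

test_that("the best objective never exceeds any start point's objective", {
  p <- saline_params()
  s <- bolus_schedule()
  tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.01, seed = 42)
  fit <- fit_blood_volume(tr, s, fit_options(n_starts = 5))
  expect_true(all(fit$objective <= fit$diagnostics$objective_start + 1e-12))
  done <- !is.na(fit$diagnostics$objective)
  expect_true(all(fit$diagnostics$objective[done] <=
                    fit$diagnostics$objective_start[done] + 1e-12))
})

test_that("multistart fits agree regardless of the random start seed", {
  p <- saline_params()
  s <- bolus_schedule()
  tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.005, seed = 7)
  f1 <- fit_blood_volume(tr, s, fit_options(n_starts = 4, seed = 101))
  f2 <- fit_blood_volume(tr, s, fit_options(n_starts = 4, seed = 202))
  expect_lt(rel_err(f1$params$alpha, f2$params$alpha), 1e-3)
  expect_lt(rel_err(f1$params$k, f2$params$k), 1e-3)
  expect_lt(rel_err(f1$params$v_b0, f2$params$v_b0), 1e-3)
})

test_that("flat traces are reported as non-informative", {
  s <- bolus_schedule()
  flat <- volume_trace(seq(0, 240, 10), rep(0, 25))
  expect_error(fit_blood_volume(flat, s), class = "fluidshift_error_noninformative")
})

test_that("normalized error metrics follow their definition", {
  g0 <- goodness_of_fit(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(g0$e, c(0, 0, 0))
  expect_equal(g0$rmsne, 0)

  g <- goodness_of_fit(rep(0.10, 6), rep(0.09, 6))
  expect_equal(g$e, rep(10, 6))
  expect_equal(g$rmsne, 10)

  expect_error(goodness_of_fit(c(-0.1, 0.1), c(0, 0)),
               class = "fluidshift_error_domain")
  expect_error(goodness_of_fit(c(0.1, 0.2), c(0.1, 0.2, 0.3)),
               class = "fluidshift_error_input")
})

test_that("RMSNE is scale-free", {
  obs <- c(0.05, 0.12, 0.18, 0.15, 0.11)
  mod <- c(0.06, 0.11, 0.17, 0.16, 0.10)
  base <- goodness_of_fit(obs, mod)$rmsne
  # jointly rescaling both traces changes nothing
  expect_equal(goodness_of_fit(5 * obs, 5 * mod)$rmsne, base)
  # the metric uses only sampled values, so relabelling the time unit of the
  # common clock cannot change it either
  t_min <- volume_trace(seq(0, 40, 10), c(0, obs[-1]), anchored = FALSE)
  t_hr <- volume_trace(seq(0, 40, 10) / 60, c(0, obs[-1]), anchored = FALSE)
  m_min <- volume_trace(seq(0, 40, 10), c(0, mod[-1]), anchored = FALSE)
  m_hr <- volume_trace(seq(0, 40, 10) / 60, c(0, mod[-1]), anchored = FALSE)
  expect_equal(goodness_of_fit(t_min, m_min)$rmsne,
               goodness_of_fit(t_hr, m_hr)$rmsne)
})

test_that("fit objects expose tidy, glance and diagnostics", {
  p <- saline_params()
  s <- bolus_schedule()
  tr <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.005, seed = 3)
  fit <- fit_blood_volume(tr, s, fit_options(n_starts = 2))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unit"))
  expect_equal(td$term, c("alpha", "k", "v_b0"))
  gl <- glance(fit)
  expect_equal(gl$n, 25L)
  expect_true(gl$converged)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
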