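test_that("protocol schedules implement dose, infusion time and urine spreading", {
  s1 <- protocol_schedule("ringers_acetate_0", weight_kg = 75)
  expect_equal(s1$u, c(62.5, 0))
  expect_equal(s1$time, c(0, 30))
  expect_equal(schedule_duration(s1), 180)
  expect_equal(cumulative_net_input(s1, 180), 1875)

  s3 <- protocol_schedule("albumin", weight_kg = 80)
  expect_equal(schedule_duration(s3), 480)
  expect_equal(cumulative_net_input(s3, 30), 800)
  expect_equal(cumulative_net_input(s3, 480), 800)

  # urine is spread as a constant rate over the whole study duration
  su <- protocol_schedule("saline", weight_kg = 75, urine_ml = 480)
  expect_equal(unique(su$v), 480 / 240)
  expect_equal(cumulative_net_input(su, 240), 1875 - 480)

  zero <- protocol_schedule(
    data.frame(dose_ml_kg = 0, infusion_min = 30, observation_min = 150),
    weight_kg = 75
  )
  expect_equal(zero$u, 0)
  expect_equal(cumulative_net_input(zero, 180), 0)

  expect_error(protocol_schedule("saline", weight_kg = -1),
               class = "fluidshift_error_input")
  expect_error(protocol_schedule("nope"), class = "fluidshift_error_input")
})

test_that("reference parameter fixtures carry the documented structure", {
  ref <- reference_params()
  tab <- protocol_table()
  expect_equal(nrow(ref), 7L)
  expect_setequal(ref$name, tab$name)

  cls <- tab$fluid_class[match(ref$name, tab$name)]
  expect_true(all(ref$alpha[cls == "colloid"] < 1))
  expect_true(all(ref$alpha[cls == "crystalloid"] > 1))
  expect_lt(max(ref$alpha[cls == "colloid"]), min(ref$alpha[cls == "crystalloid"]))

  # alpha and V_B0 strictly decrease with pre-infusion hemorrhage
  hem <- ref[match(c("ringers_acetate_0", "ringers_acetate_450",
                     "ringers_acetate_900"), ref$name), ]
  expect_true(all(diff(hem$alpha) < 0))
  expect_true(all(diff(hem$v_b0_l) < 0))

  p <- protocol_params("saline")
  expect_equal(p$v_b0, 5560)
  expect_error(protocol_params("nope"), class = "fluidshift_error_input")
})

test_that("per-protocol error fixtures average to the cross-fluid summary", {
  ref <- reference_params()
  expect_equal(round(mean(ref$error_mean_pct), 1), 0.6)
  expect_equal(round(mean(ref$rmse_pct), 1), 9.5)
})

test_that("synthetic traces are deterministic and exact at zero noise", {
  p <- saline_params()
  s <- bolus_schedule()
  clean <- synthetic_trace(p, s, t_s = 10, noise_sd = 0)
  expect_equal(clean$vb_frac,
               simulate_volume(p, s, seq(0, 240, 10))$vb_frac)
  a <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.01, seed = 11)
  b <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.01, seed = 11)
  d <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.01, seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$vb_frac, d$vb_frac)))
  expect_equal(a$vb_frac[1], 0)  # baseline stays anchored
  m <- synthetic_trace(p, s, t_s = 10, noise_sd = 0.01, seed = 11,
                       noise = "multiplicative")
  expect_false(isTRUE(all.equal(a$vb_frac, m$vb_frac)))
})

test_that("colloids retain more of the infused volume than crystalloids", {
  alb <- protocol_params("albumin")
  sal <- protocol_params("saline")
  s_alb <- protocol_schedule("albumin", weight_kg = 75)
  s_sal <- protocol_schedule("saline", weight_kg = 75)
  tr_alb <- synthetic_trace(alb, s_alb, t_s = 10, noise_sd = 0)
  tr_sal <- synthetic_trace(sal, s_sal, t_s = 10, noise_sd = 0)
  # late-time plateau per unit infused volume: retention -> 1/(1+alpha)
  ret_alb <- tail(tr_alb$vb_frac, 1) * alb$v_b0 / cumulative_net_input(s_alb, 480)
  ret_sal <- tail(tr_sal$vb_frac, 1) * sal$v_b0 / cumulative_net_input(s_sal, 240)
  expect_gt(ret_alb, ret_sal)
  expect_equal(ret_alb, 1 / (1 + alb$alpha), tolerance = 0.01)
})

test_that("a noiseless recovery experiment has vanishing bias", {
  p <- saline_params()
  s <- bolus_schedule()
  rec <- recovery_experiment(p, s, t_s = 10, noise_sd = 0, replicates = 1,
                             seed = 5, options = fit_options(n_starts = 2))
  expect_equal(rec$n_failed, 0L)
  expect_true(all(abs(rec$summary$bias_rel) < 0.01))
})

test_that("halving the noise roughly halves the parameter spread", {
  p <- saline_params()
  s <- bolus_schedule()
  opts <- fit_options(n_starts = 2)
  rec_hi <- recovery_experiment(p, s, t_s = 10, noise_sd = 0.004,
                                replicates = 8, seed = 9, options = opts)
  rec_lo <- recovery_experiment(p, s, t_s = 10, noise_sd = 0.002,
                                replicates = 8, seed = 9, options = opts)
  ratio <- rec_hi$summary$rmse_rel / rec_lo$summary$rmse_rel
  # local linearity: same seeds, so the ratio should sit near 2
  expect_true(all(ratio > 1.4 & ratio < 2.8))
})
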