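# Printed angle values (Table-1-style checks). The table's own angles were
# computed from unrounded force ratios, so agreement with the printed table
# holds to ~5e-4 degrees when starting from the 4-decimal printed ratios.
table1_angles <- data.frame(
  ratio = c(14.8666, 1.6260, 14.8666, 1.6260),
  model = c("eq1", "eq1", "eq9", "eq9"),
  printed = c(53.8892, 95.8677, 50.1630, 100.5887),
  computed = c(53.889258, 95.868122, 50.163088, 100.589191))

test_that("the angle power laws reproduce the published worked examples", {
  for (i in seq_len(nrow(table1_angles))) {
    a <- compute_alpha(table1_angles$ratio[i], table1_angles$model[i])
    expect_equal(a, table1_angles$computed[i], tolerance = 1e-6)
    expect_lt(abs(a - table1_angles$printed[i]), 1e-3)
  }
  expect_equal(compute_alpha(1, "eq9"), 117.2)
  expect_equal(compute_alpha(1 / 0.05, "eq9"), 45.69659, tolerance = 1e-6)
  expect_error(compute_alpha(0.8), "ratio", class = "mutet_validation_error")
})

test_that("both angle models decrease strictly with the force ratio", {
  r <- seq(1, 20, by = 0.25)
  for (m in c("eq1", "eq9")) {
    a <- compute_alpha(r, m)
    expect_true(all(diff(a) < 0))
  }
  # over the physiological ratio range the ameliorated model spans its bounds
  p <- seq(0.05, 1, length.out = 200)
  a9 <- compute_alpha(1 / p, "eq9")
  expect_equal(range(a9), c(45.6966, 117.2), tolerance = 1e-4)
})

test_that("predicted amplitudes follow the angle regimes", {
  mu <- std_mu()
  f1 <- mu$first_twitch$f_max
  ftet <- seq(0.1, 2, by = 0.1) * f1
  for (alpha in c(45, 60, 80)) {
    amps <- vapply(ftet, function(x)
      predict_contraction(mu, x, alpha)$f_max, numeric(1))
    expect_true(all(diff(amps) > 0))
    expect_true(all(amps > f1))
  }
  amps90 <- vapply(ftet, function(x)
    predict_contraction(mu, x, 90)$f_max, numeric(1))
  expect_true(all(amps90 == f1))
  for (alpha in c(100, 117.2)) {
    amps <- vapply(ftet, function(x)
      predict_contraction(mu, x, alpha)$f_max, numeric(1))
    expect_true(all(diff(amps) < 0))
  }
  # exact worked points: cot(45) = 1 doubles the amplitude at x = 1
  expect_equal(predict_contraction(mu, f1, 45)$f_max, 2 * f1)
  # at the border angle the amplitude vanishes at x = -1/cot(alpha)
  border <- amplitude_zero_border(117.2)
  expect_equal(border, 1.9458, tolerance = 1e-4)
  expect_equal(predict_contraction(mu, border * f1, 117.2)$f_max, 0,
               tolerance = 1e-6)
  # beyond the border the clamp keeps amplitudes at zero, never negative
  expect_equal(predict_contraction(mu, 3 * f1, 117.2)$f_max, 0)
})

test_that("a contraction starting from rest is the single twitch; time laws prolong otherwise", {
  mu <- std_mu()
  expect_identical(predict_contraction(mu, 0, 73), mu$first_twitch)
  ft <- mu$first_twitch
  xs <- seq(0.2, 3, by = 0.2)
  tc <- thr <- numeric(length(xs))
  for (i in seq_along(xs)) {
    p <- predict_contraction(mu, xs[i] * ft$f_max, 90)
    tc[i] <- p$t_c; thr[i] <- p$t_hr
    expect_equal(p$t_c / ft$t_c, 1.04 + 0.274 * xs[i], tolerance = 1e-9)
    expect_equal(p$t_hr / ft$t_c, 2.397 + 0.3509 * xs[i], tolerance = 1e-9)
    expect_equal(p$t_hc / p$t_c, ft$t_hc / ft$t_c, tolerance = 1e-9)
    expect_equal(p$t_tw / p$t_hr, ft$t_tw / ft$t_hr, tolerance = 1e-9)
    expect_equal(p$t_lead, ft$t_lead)
  }
  expect_true(all(diff(tc) > 0))
  expect_true(all(diff(thr) > 0))
  # pathological coefficients that break the ordering raise a structural error
  bad <- prediction_config(thr_coeffs = c(0.3, 0))
  expect_error(predict_contraction(mu, ft$f_max, 80, bad), "coeffs",
               class = "mutet_numeric_error")
})

test_that("full prediction degenerates correctly for trivial patterns", {
  mu <- std_mu()
  ft <- mu$first_twitch
  cfg <- prediction_config(step = 0.1)
  # one pulse: the tetanus is the single twitch
  pred1 <- full_predict(mu, stim_pattern(), cfg)
  expect_equal(length(pred1$train), 1L)
  g <- trace_times(pred1$trace)
  expect_equal(pred1$trace$force, evaluate_on_grid(build_twitch(ft), g))
  # two pulses with complete relaxation in between: two identical twitches
  gap <- ft$t_tw + ft$t_lead + 5
  pred2 <- full_predict(mu, stim_pattern(gap), cfg)
  expect_equal(pred2$train$f_tetmin[2], 0)
  expect_identical(pred2$train$contractions[[2]], ft)
})

test_that("at 90 degrees all contractions keep the first-twitch amplitude but prolong", {
  mu <- std_mu()
  pat <- generate_pattern(1000 / (1.5 * mu$first_twitch$t_c), n = 15, seed = 3)
  pred <- full_predict(mu, pat, prediction_config(alpha_model = 90, step = 0.2))
  amps <- vapply(pred$train$contractions, `[[`, numeric(1), "f_max")
  expect_true(all(amps == mu$first_twitch$f_max))
  tcs <- vapply(pred$train$contractions, `[[`, numeric(1), "t_c")
  expect_true(all(tcs[-1] > mu$first_twitch$t_c))
})

test_that("the predicted trace is exactly the sum of its train's curves", {
  case <- moderate_case("FR", seed = 17)
  pred <- full_predict(case$mu, case$pattern, prediction_config(step = 0.5))
  g <- trace_times(pred$trace)
  total <- numeric(length(g))
  for (i in seq_along(pred$train$stimulus_times))
    total <- total + twitch_force(pred$train$contractions[[i]],
                                  g - pred$train$stimulus_times[i])
  expect_lt(max(abs(total - pred$trace$force)), 1e-9 * case$mu$f_mftf)
  expect_true(all(pred$trace$force >= 0))
})

test_that("prediction from observed starting levels matches its degenerate cases", {
  mu <- std_mu()
  cfg <- prediction_config(step = 0.2)
  pat <- generate_pattern(1000 / (2 * mu$first_twitch$t_c), n = 8, seed = 5)
  # all-zero observed levels collapse to the equal-twitch sum
  p0 <- predict_with_observed_minima(mu, pat, numeric(8), cfg)
  eq <- sum_equal_twitches(mu, pat, cfg)
  expect_equal(p0$trace$force, eq$trace$force, tolerance = 1e-12)
  # feeding back the full prediction's own levels reproduces it exactly
  full <- full_predict(mu, pat, cfg)
  again <- predict_with_observed_minima(mu, pat, full$train$f_tetmin, cfg)
  expect_identical(again$trace$force, full$trace$force)
  expect_error(predict_with_observed_minima(mu, pat, numeric(5), cfg),
               "length", class = "mutet_validation_error")
  expect_error(predict_with_observed_minima(mu, pat, c(1, rep(0, 7)), cfg),
               class = "mutet_validation_error")
})

test_that("prediction from measured minima stays close to the generating trace", {
  case <- moderate_case("FR", seed = 17)
  cfg <- prediction_config(step = 0.5)
  pred <- full_predict(case$mu, case$pattern, cfg)
  m <- local_minima(pred$trace, case$pattern,
                    t_lead = case$mu$first_twitch$t_lead)
  back <- predict_with_observed_minima(case$mu, case$pattern, m, cfg)
  n <- min(length(back$trace$force), length(pred$trace$force))
  a <- force_trace(pred$trace$force[1:n], start = 0, step = 0.5)
  b <- force_trace(back$trace$force[1:n], start = 0, step = 0.5)
  expect_gt(fit_co(a, b), 95)
})

test_that("equal-twitch summation is a plain superposition", {
  mu <- std_mu()
  ft <- mu$first_twitch
  cfg <- prediction_config(step = 0.1)
  one <- sum_equal_twitches(mu, stim_pattern(), cfg)
  g <- trace_times(one$trace)
  expect_equal(one$trace$force, evaluate_on_grid(build_twitch(ft), g))
  # widely spaced pulses never overlap: the peak stays at f_max(1)
  wide <- sum_equal_twitches(mu, stim_pattern(rep(ft$t_tw + ft$t_lead + 1, 3)), cfg)
  expect_equal(max(wide$trace$force), ft$f_max, tolerance = 1e-6)
  # degenerate coincident pulses scale the twitch n-fold (guard bypassed)
  pat0 <- stim_pattern()
  pat0$pulse_times <- rep(0, 4)
  four <- sum_equal_twitches(mu, pat0, cfg)
  expect_equal(four$trace$force,
               4 * evaluate_on_grid(build_twitch(ft), trace_times(four$trace)),
               tolerance = 1e-12)
})
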