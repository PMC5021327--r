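test_that("a single recorded twitch is recovered almost exactly", {
  tw <- std_twitch()
  g <- seq(0, 1.3 * (tw$t_lead + tw$t_tw), by = 0.1)
  trace <- force_trace(evaluate_on_grid(build_twitch(tw), g),
                       start = 0, step = 0.1)
  init <- twitch_params(tw$f_max * 1.4, tw$t_lead * 0.7, tw$t_hc * 1.2,
                        tw$t_c * 1.2, tw$t_hr * 0.9, tw$t_tw * 1.1)
  train <- decompose_tetanus(trace, stim_pattern(), seed_twitch = init)
  fit <- train$contractions[[1]]
  for (p in c("f_max", "t_hc", "t_c", "t_hr", "t_tw"))
    expect_lt(abs(fit[[p]] - tw[[p]]) / tw[[p]], 0.01)
  expect_lt(abs(fit$t_lead - tw$t_lead), 0.1)
  expect_gt(attr(train, "similarity")$fit_co, 99.9)
})

test_that("a noiseless five-contraction tetanus is decomposed to within 2%", {
  case <- moderate_case("S", seed = 7, n = 5)
  pred <- full_predict(case$mu, case$pattern, prediction_config(step = 0.5))
  # a short train converges to the generating parameters with a few extra
  # alternating sweeps
  train <- decompose_tetanus(pred$trace, case$pattern,
                             seed_twitch = case$mu$first_twitch,
                             refine = 4, pair_refine = 6)
  truth <- as.data.frame(pred$train)
  fit <- as.data.frame(train)
  rel <- abs(fit[, 3:8] - truth[, 3:8]) / truth[, 3:8]
  expect_lt(max(rel), 0.02)
})

test_that("segment fitting recovers parameters from noisy residuals", {
  tw <- generate_motor_unit("S", seed = 7)$first_twitch
  g <- seq(0, 1.3 * (tw$t_lead + tw$t_tw), by = 0.1)
  clean <- twitch_force(tw, g)
  init <- twitch_params(tw$f_max * 1.3, tw$t_lead * 1.2, tw$t_hc * 0.8,
                        tw$t_c * 0.9, tw$t_hr * 1.1, tw$t_tw * 1.2)
  for (seed in c(42, 43, 44)) {
    noisy <- withr::with_seed(seed,
      clean + stats::rnorm(length(g), sd = 0.005 * tw$f_max))
    fit <- fit_twitch_segment(force_trace(noisy, start = 0, step = 0.1),
                              0, init)
    # shape and amplitude recover to a few percent; the onset is weakly
    # identified (the curve leaves zero with zero slope) so it is held to an
    # absolute sub-millisecond tolerance instead
    for (p in c("f_max", "t_hc", "t_c", "t_hr", "t_tw"))
      expect_lt(abs(fit[[p]] - tw[[p]]) / tw[[p]], 0.05)
    expect_lt(abs(fit$t_lead - tw$t_lead), 0.75)
  }
})

test_that("an exact model residual is a fixed point of the segment fit", {
  tw <- std_twitch()
  g <- seq(0, 250, by = 0.1)
  res <- force_trace(twitch_force(tw, g), start = 0, step = 0.1)
  fit <- fit_twitch_segment(res, 0, tw)
  expect_equal(unclass(fit)[1:6], unclass(tw)[1:6], tolerance = 1e-6)
  expect_lt(attr(fit, "rss"), 1e-12 * tw$f_max^2)
})

test_that("an all-zero residual yields the zero sentinel or an error, as configured", {
  zero <- force_trace(rep(0, 3000), start = 0, step = 0.1)
  tw <- std_twitch()
  fit <- fit_twitch_segment(zero, 0, tw)
  expect_equal(fit$f_max, 0)
  expect_error(fit_twitch_segment(zero, 0, tw, on_empty = "error"),
               "no signal", class = "mutet_numeric_error")
})

test_that("reconstruction is linear, order-invariant and handles empty trains", {
  g <- seq(0, 400, by = 0.5)
  empty <- contraction_train(numeric(0), list(), numeric(0))
  expect_true(all(reconstruct(empty, g)$force == 0))
  tw <- std_twitch()
  one <- contraction_train(0, list(tw), 0)
  expect_equal(reconstruct(one, g)$force,
               evaluate_on_grid(build_twitch(tw), g))
  tw2 <- std_twitch(f_max = 11, t_c = 30, t_hc = 16, t_hr = 60, t_tw = 200)
  ab <- contraction_train(c(0, 45), list(tw, tw2), c(0, 0))
  ba <- contraction_train(c(45, 0), list(tw2, tw), c(0, 0))
  expect_equal(reconstruct(ab, g)$force, reconstruct(ba, g)$force)
})

test_that("local minima behave on plateaus, relaxed trains and model traces", {
  # flat plateau: every minimum equals the plateau level
  flat <- force_trace(rep(7, 2000), start = 0, step = 0.5)
  pat <- stim_pattern(rep(100, 5))
  expect_equal(local_minima(flat, pat, t_lead = 2), c(0, rep(7, 5)))
  # full relaxation between pulses: all minima are zero
  mu <- std_mu()
  ft <- mu$first_twitch
  wide <- stim_pattern(rep(ft$t_tw + ft$t_lead + 10, 3))
  eq <- sum_equal_twitches(mu, wide, prediction_config(step = 0.5))
  expect_equal(local_minima(eq$trace, wide, t_lead = ft$t_lead), rep(0, 4))
  # forward-simulated trace: minima match the stored starting levels to
  # within one sampling step's force change (starting levels are read at the
  # contraction onset, one lead time after each pulse)
  case <- moderate_case("FR", seed = 17)
  cfg <- prediction_config(step = 0.5, lead_offset_in_sampling = TRUE)
  pred <- full_predict(case$mu, case$pattern, cfg)
  m <- local_minima(pred$trace, case$pattern,
                    t_lead = case$mu$first_twitch$t_lead)
  # the search window extends two samples past the onset, so allow the
  # force change of two sampling steps
  step_change <- max(abs(diff(pred$trace$force)))
  expect_lt(max(abs(m - pred$train$f_tetmin)), 2 * step_change)
})

test_that("decomposition validates coverage and a non-covering trace fails", {
  short <- force_trace(rep(1, 100), start = 0, step = 0.5)
  expect_error(decompose_tetanus(short, stim_pattern(rep(100, 4))),
               "cover", class = "mutet_validation_error")
})

test_that("parameter recovery degrades gracefully with noise", {
  case <- moderate_case("FF", seed = 23, n = 12)
  pred <- full_predict(case$mu, case$pattern, prediction_config(step = 0.5))
  truth <- as.data.frame(pred$train)
  err_at <- function(noise_sd) {
    tr <- pred$trace
    if (noise_sd > 0)
      tr$force <- withr::with_seed(99,
        pmax(0, tr$force + stats::rnorm(length(tr$force),
                                        sd = noise_sd * case$mu$f_mftf)))
    train <- decompose_tetanus(tr, case$pattern,
                               seed_twitch = case$mu$first_twitch)
    fit <- as.data.frame(train)
    mean(abs(as.matrix(fit[, 3:8] - truth[, 3:8])) / as.matrix(truth[, 3:8]))
  }
  errs <- vapply(c(0, 0.01, 0.05), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 0.02)
})
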