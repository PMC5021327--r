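#' Configuration of the tetanus prediction algorithm
#'
#' Collects the tunable constants of the prediction equations. Defaults are
#' the published values; every constant can be overridden, e.g. after a
#' recalibration on a new data set.
#'
#' @param alpha_model `"eq1"` for the original angle-ratio power law
#'   (108.8 x^-0.2603), `"eq9"` for the ameliorated one (117.2 x^-0.3144), or
#'   a single numeric angle in degrees to bypass the power law.
#' @param tc_coeffs Intercept and slope of the contraction-time line
#'   `t_c(i)/t_c(1) = p1 + p2 x`, `x = f_tetmin/f_max(1)`.
#' @param thr_coeffs Intercept and slope of the half-relaxation-time line
#'   `t_hr(i)/t_c(1) = p1 + p2 x` (note the normalization by `t_c(1)`).
#' @param lead_offset_in_sampling If `TRUE`, the starting force of contraction
#'   `n` is read at `t_pulse(n) + t_lead(1)` instead of at the pulse time —
#'   the contraction actually begins one lead time after its pulse.
#' @param step Sampling step of synthesized traces (ms).
#' @param clamp_negative_amplitude Clamp predicted amplitudes at 0 (they can
#'   go negative for angles above 90 degrees at high starting force).
#' @return An object of class `"prediction_config"`.
#' @export
prediction_config <- function(alpha_model = "eq1",
                              tc_coeffs = c(1.04, 0.274),
                              thr_coeffs = c(2.397, 0.3509),
                              lead_offset_in_sampling = FALSE,
                              step = 0.1,
                              clamp_negative_amplitude = TRUE) {
  if (is.numeric(alpha_model)) {
    if (length(alpha_model) != 1 || !is.finite(alpha_model) ||
        alpha_model <= 0 || alpha_model >= 180)
      stop_validation("explicit alpha must be a single angle in (0, 180) degrees")
  } else {
    alpha_model <- match.arg(alpha_model, c("eq1", "eq9"))
  }
  if (length(tc_coeffs) != 2 || any(!is.finite(tc_coeffs)))
    stop_validation("tc_coeffs must be two finite numbers")
  if (length(thr_coeffs) != 2 || any(!is.finite(thr_coeffs)))
    stop_validation("thr_coeffs must be two finite numbers")
  if (!is.finite(step) || step <= 0)
    stop_validation("sampling step must be positive")
  cfg <- list(alpha_model = alpha_model, tc_coeffs = tc_coeffs,
              thr_coeffs = thr_coeffs,
              lead_offset_in_sampling = isTRUE(lead_offset_in_sampling),
              step = step,
              clamp_negative_amplitude = isTRUE(clamp_negative_amplitude))
  class(cfg) <- "prediction_config"
  cfg
}

#' Motor-unit specific angle from the fused-tetanus to twitch force ratio
#'
#' The angle alpha between a motor unit's amplitude-versus-residual-force
#' line and the ordinate is predicted from the ratio
#' `x = f_mftf / f_max(1)` by a power law: the original model
#' `alpha = 108.8 x^(-0.2603)` or the ameliorated model
#' `alpha = 117.2 x^(-0.3144)` obtained after sensitivity analysis.
#'
#' @param ratio Fused-tetanus to first-twitch force ratio, at least 1.
#' @param model `"eq1"` (original) or `"eq9"` (ameliorated).
#' @return Angle in degrees. Strictly decreasing in `ratio`; the ameliorated
#'   model spans 117.2 degrees (at ratio 1) down to 45.6966 degrees at the
#'   minimal physiological twitch-to-tetanus ratio 0.05 (ratio 20).
#' @examples
#' compute_alpha(14.8666, "eq1")  # a slow unit: about 53.89 degrees
#' compute_alpha(1.6260, "eq1")   # a fast fatigable unit: about 95.87 degrees
#' @export
compute_alpha <- function(ratio, model = c("eq1", "eq9")) {
  model <- match.arg(model)
  if (any(!is.finite(ratio)) || any(ratio < 1))
    stop_validation("ratio f_mftf/f_max(1) must be >= 1 (the single twitch cannot exceed the fused tetanus)")
  switch(model,
         eq1 = 108.8 * ratio^(-0.2603),
         eq9 = 117.2 * ratio^(-0.3144))
}

# Cotangent of an angle in degrees; exactly 0 at 90 so the constant-amplitude
# regime is free of floating-point sign noise.
cot_deg <- function(alpha) {
  if (alpha == 90) return(0)
  a <- alpha * pi / 180
  cos(a) / sin(a)
}

#' Normalized starting force at which the predicted amplitude vanishes
#'
#' For an angle above 90 degrees the predicted contraction amplitude
#' decreases with the starting force level and reaches zero at
#' `f_tetmin / f_max(1) = -1 / cot(alpha)`: above this level the unit can no
#' longer respond with a new contraction. At the maximal physiological angle
#' of 117.2 degrees this border is about 1.94.
#'
#' @param alpha Angle in degrees, above 90.
#' @return The border value of `f_tetmin / f_max(1)`.
#' @export
amplitude_zero_border <- function(alpha) {
  if (!is.finite(alpha) || alpha <= 90 || alpha >= 180)
    stop_validation("the amplitude only vanishes for angles in (90, 180) degrees")
  -1 / cot_deg(alpha)
}

#' Predict the parameters of a successive contraction
#'
#' Given the force level `f_tetmin` at which a contraction starts, predicts
#' its six twitch parameters from the motor unit's first twitch:
#' amplitude `f_max(i) = (1 + cot(alpha) f_tetmin/f_max(1)) f_max(1)`;
#' contraction and half-relaxation times from the linear laws in
#' `x = f_tetmin/f_max(1)` (both normalized by `t_c(1)`); half-contraction
#' time and total duration scaled proportionally; lead time unchanged.
#' A contraction starting from a fully relaxed unit (`f_tetmin = 0`) is the
#' first twitch itself.
#'
#' @param mu A [motor_unit()].
#' @param f_tetmin Force level at which the contraction starts (mN), >= 0.
#' @param alpha Angle in degrees, in (0, 180).
#' @param cfg A [prediction_config()].
#' @return A [twitch_params()] object (possibly with `f_max = 0` when the
#'   amplitude is clamped).
#' @export
predict_contraction <- function(mu, f_tetmin, alpha, cfg = prediction_config()) {
  stopifnot(inherits(mu, "motor_unit"))
  if (!is.finite(f_tetmin) || f_tetmin < 0)
    stop_validation("f_tetmin must be non-negative (got %g)", f_tetmin)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 180)
    stop_validation("alpha must lie in (0, 180) degrees (got %g)", alpha)
  ft <- mu$first_twitch
  if (f_tetmin == 0) return(ft)
  x <- f_tetmin / ft$f_max
  f_max_i <- (1 + cot_deg(alpha) * x) * ft$f_max
  if (f_max_i < 0) {
    if (cfg$clamp_negative_amplitude) f_max_i <- 0
    else stop_numeric("predicted amplitude negative (%g mN) at f_tetmin = %g, alpha = %g",
                      f_max_i, f_tetmin, alpha)
  }
  t_c_i <- (cfg$tc_coeffs[1] + cfg$tc_coeffs[2] * x) * ft$t_c
  t_hr_i <- (cfg$thr_coeffs[1] + cfg$thr_coeffs[2] * x) * ft$t_c
  t_hc_i <- ft$t_hc * t_c_i / ft$t_c
  t_tw_i <- ft$t_tw * t_hr_i / ft$t_hr
  if (!(0 < t_hc_i && t_hc_i < t_c_i && t_c_i < t_hr_i && t_hr_i < t_tw_i))
    stop_numeric(paste0(
      "predicted time ordering violated at x = %g with tc_coeffs (%g, %g) and ",
      "thr_coeffs (%g, %g): t_hc = %g, t_c = %g, t_hr = %g, t_tw = %g"),
      x, cfg$tc_coeffs[1], cfg$tc_coeffs[2], cfg$thr_coeffs[1], cfg$thr_coeffs[2],
      t_hc_i, t_c_i, t_hr_i, t_tw_i)
  twitch_params(f_max_i, ft$t_lead, t_hc_i, t_c_i, t_hr_i, t_tw_i,
                allow_zero = TRUE)
}

# Angle used for a prediction run.
resolve_alpha <- function(mu, cfg) {
  if (is.numeric(cfg$alpha_model)) return(cfg$alpha_model)
  compute_alpha(mu$f_mftf / mu$first_twitch$f_max, cfg$alpha_model)
}

# Default sampling grid: from the first pulse to the end of the longest
# possible relaxation tail.
prediction_grid <- function(mu, pattern, train, cfg) {
  ft <- mu$first_twitch
  t_end <- max(vapply(seq_along(train$stimulus_times), function(i) {
    p <- train$contractions[[i]]
    train$stimulus_times[i] + p$t_lead + p$t_tw
  }, numeric(1)))
  seq(0, t_end + cfg$step, by = cfg$step)
}

# Shared engine: predict each contraction from a supplied or self-predicted
# starting force level.
predict_engine <- function(mu, pattern, cfg, observed_f_tetmin = NULL) {
  stopifnot(inherits(mu, "motor_unit"), inherits(pattern, "stim_pattern"))
  n <- length(pattern$pulse_times)
  if (n < 1) stop_validation("stimulation pattern must contain at least one pulse")
  alpha <- resolve_alpha(mu, cfg)
  ft <- mu$first_twitch
  contractions <- vector("list", n)
  f_tetmin <- numeric(n)
  contractions[[1]] <- ft
  if (n > 1) {
    for (k in 2:n) {
      if (is.null(observed_f_tetmin)) {
        t_eval <- pattern$pulse_times[k] +
          if (cfg$lead_offset_in_sampling) ft$t_lead else 0
        f <- 0
        for (i in 1:(k - 1))
          f <- f + twitch_force(contractions[[i]],
                                t_eval - pattern$pulse_times[i])
        f_tetmin[k] <- max(f, 0)
      } else {
        f_tetmin[k] <- observed_f_tetmin[k]
      }
      contractions[[k]] <- predict_contraction(mu, f_tetmin[k], alpha, cfg)
    }
  }
  train <- contraction_train(pattern$pulse_times, contractions, f_tetmin)
  trace <- reconstruct(train, prediction_grid(mu, pattern, train, cfg))
  list(trace = trace, train = train, alpha = alpha)
}

#' Full prediction of an unfused tetanic contraction
#'
#' The core forward algorithm: from the six parameters of the single twitch,
#' the maximal fused-tetanus force and a stimulation pattern alone, predicts
#' the whole tetanic force curve. The angle alpha is computed from the force
#' ratio; the first contraction is the single twitch (starting force 0); for
#' each later pulse the starting force level is read off the sum of all
#' previously predicted contractions at the pulse time, and the contraction's
#' parameters follow from [predict_contraction()]. The returned trace is the
#' sum of all modeled twitches on a uniform grid.
#'
#' @inheritParams predict_contraction
#' @param pattern A [stim_pattern()].
#' @return A list with elements `trace` ([force_trace()]), `train`
#'   ([contraction_train()]) and `alpha` (degrees).
#' @examples
#' mu <- motor_unit("S1", "S", twitch_params(20, 2, 25, 45, 100, 350), 150)
#' pat <- stim_pattern(rep(77, 10))
#' pred <- full_predict(mu, pat, prediction_config(step = 0.5))
#' max(pred$trace$force)
#' @export
full_predict <- function(mu, pattern, cfg = prediction_config()) {
  predict_engine(mu, pattern, cfg)
}

#' Prediction with observed starting force levels
#'
#' Same algorithm as [full_predict()] but the force level at which each
#' contraction starts is taken from a supplied list (e.g. local minima
#' measured on a recorded tetanic curve) instead of from the running model
#' sum.
#'
#' @inheritParams full_predict
#' @param observed_f_tetmin Numeric vector, one value per pulse; the first
#'   must be 0.
#' @return As [full_predict()].
#' @export
predict_with_observed_minima <- function(mu, pattern, observed_f_tetmin,
                                         cfg = prediction_config()) {
  n <- length(pattern$pulse_times)
  if (length(observed_f_tetmin) != n)
    stop_validation("observed_f_tetmin has length %d but the pattern has %d pulses",
                    length(observed_f_tetmin), n)
  if (any(!is.finite(observed_f_tetmin)) || any(observed_f_tetmin < 0))
    stop_validation("observed starting force levels must be non-negative")
  if (observed_f_tetmin[1] != 0)
    stop_validation("the first contraction starts from rest: observed_f_tetmin[1] must be 0")
  predict_engine(mu, pattern, cfg, observed_f_tetmin = observed_f_tetmin)
}

#' Summation of equal twitches
#'
#' The naive baseline: superposition of identical copies of the first twitch
#' at each stimulus time, ignoring any dependence of the successive
#' contractions on the force level.
#'
#' @inheritParams full_predict
#' @return A list with elements `trace` and `train`.
#' @export
sum_equal_twitches <- function(mu, pattern, cfg = prediction_config()) {
  stopifnot(inherits(mu, "motor_unit"), inherits(pattern, "stim_pattern"))
  n <- length(pattern$pulse_times)
  if (n < 1) stop_validation("stimulation pattern must contain at least one pulse")
  train <- contraction_train(pattern$pulse_times,
                             rep(list(mu$first_twitch), n),
                             numeric(n))
  trace <- reconstruct(train, prediction_grid(mu, pattern, train, cfg))
  list(trace = trace, train = train)
}
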