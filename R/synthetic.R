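#' Generate a synthetic motor unit
#'
#' Draws a motor unit of a given physiological type with first-twitch
#' parameters and twitch-to-tetanus ratio from type-specific ranges. The
#' ratio is drawn from the type's reported mean and standard deviation
#' (0.13 +/- 0.05 for S, 0.19 +/- 0.06 for FR, 0.28 +/- 0.08 for FF units in
#' rat medial gastrocnemius), truncated to (0.05, 1). Contraction times are
#' uniform on 30-70 ms for slow units and 12-25 ms for fast ones; the other
#' time parameters follow fixed physiological proportions
#' (`t_hc = 0.55 t_c`, `t_hr = 2.2 t_c`, `t_tw = 8 t_c`), which are synthetic
#' conventions — only their ordering matters to the algorithms.
#'
#' @param mu_type `"S"`, `"FR"` or `"FF"`.
#' @param seed Integer seed; the same seed reproduces the same unit.
#' @param mu_id Label (defaults to the type plus the seed).
#' @return A [motor_unit()].
#' @export
generate_motor_unit <- function(mu_type = c("S", "FR", "FF"), seed,
                                mu_id = NULL) {
  mu_type <- match.arg(mu_type)
  mu_id <- mu_id %||% sprintf("%s_seed%d", mu_type, seed)
  withr::with_seed(seed, {
    ratio_pars <- switch(mu_type,
                         S = c(0.13, 0.05),
                         FR = c(0.19, 0.06),
                         FF = c(0.28, 0.08))
    p <- Inf
    while (p <= 0.05 || p >= 1)
      p <- stats::rnorm(1, ratio_pars[1], ratio_pars[2])
    t_c <- if (mu_type == "S") stats::runif(1, 30, 70)
           else stats::runif(1, 12, 25)
    t_lead <- stats::runif(1, 1, 3)
    f_max <- switch(mu_type,
                    S = stats::runif(1, 5, 30),
                    FR = stats::runif(1, 20, 100),
                    FF = stats::runif(1, 50, 200))
    ft <- twitch_params(f_max, t_lead, 0.55 * t_c, t_c, 2.2 * t_c, 8 * t_c)
    motor_unit(mu_id, mu_type, ft, f_max / p)
  })
}

#' Generate a jittered stimulation pattern
#'
#' Interpulse intervals are drawn i.i.d. uniformly within a jitter band
#' around the mean interval `1000 / mean_freq` ms (by default 50-150\% of the
#' mean, the band used experimentally for random stimulation patterns).
#'
#' @param mean_freq Mean stimulation frequency (Hz).
#' @param jitter Lower and upper jitter bounds as fractions of the mean IPI.
#' @param n Number of pulses (41 in the experimental patterns).
#' @param seed Integer seed.
#' @return A [stim_pattern()] with `n` pulses.
#' @export
generate_pattern <- function(mean_freq, jitter = c(0.5, 1.5), n = 41, seed) {
  if (!is.finite(mean_freq) || mean_freq <= 0)
    stop_validation("mean_freq must be positive")
  if (length(jitter) != 2 || any(jitter <= 0) || any(jitter >= 2) ||
      jitter[1] > jitter[2])
    stop_validation("jitter bounds must satisfy 0 < lower <= upper < 2")
  if (n < 1) stop_validation("need at least one pulse")
  mean_ipi <- 1000 / mean_freq
  withr::with_seed(seed, {
    ipis <- stats::runif(n - 1, jitter[1] * mean_ipi, jitter[2] * mean_ipi)
    stim_pattern(ipis)
  })
}

#' Simulate a noisy "recorded" tetanic force trace
#'
#' Forward-simulates the unfused tetanus of a unit via [full_predict()] and
#' adds Gaussian measurement noise (clipped at zero force). With
#' `noise_sd = 0` the output is exactly the prediction.
#'
#' @param mu A [motor_unit()].
#' @param pattern A [stim_pattern()].
#' @param noise_sd Noise standard deviation as a fraction of the unit's
#'   maximal fused-tetanus force.
#' @param seed Integer seed for the noise.
#' @param cfg A [prediction_config()].
#' @return A list with `trace` (the noisy [force_trace()]), `clean` (the
#'   noiseless trace) and `train` (the generating [contraction_train()]).
#' @export
synth_recording <- function(mu, pattern, noise_sd = 0.01, seed,
                            cfg = prediction_config()) {
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_validation("noise_sd must be non-negative")
  pred <- full_predict(mu, pattern, cfg)
  noisy <- pred$trace
  if (noise_sd > 0) {
    noisy$force <- withr::with_seed(seed,
      pmax(0, noisy$force + stats::rnorm(length(noisy$force),
                                         sd = noise_sd * mu$f_mftf)))
  }
  list(trace = noisy, clean = pred$trace, train = pred$train)
}

#' Choose a stimulation frequency evoking a moderately fused tetanus
#'
#' Emulates the experimental protocol in which, for each motor unit, the
#' stimulation rate was chosen so that the unfused tetanus reached a moderate
#' force level (30-70\% of the maximal fused-tetanus force). The predicted
#' peak force of a 41-pulse tetanus grows monotonically with the rate; a
#' bisection on the rate returns the frequency whose predicted peak is
#' closest to the middle of the target band.
#'
#' When `seed` (and `jitter`) are given, the bisection is run on the exact
#' jittered pattern that [generate_pattern()] produces for that seed — the
#' jitter factors are fixed, so the interpulse intervals scale as the inverse
#' rate and `generate_pattern(freq, jitter, n, seed)` afterwards reproduces
#' the probed pattern.
#'
#' @param mu A [motor_unit()].
#' @param target Target band for peak force as a fraction of `f_mftf`; the
#'   bisection aims at its midpoint.
#' @param n Number of pulses used for the probe tetanus.
#' @param jitter,seed Jitter band and seed as in [generate_pattern()];
#'   `seed = NULL` probes a constant-rate train.
#' @param freq_range Search interval (Hz).
#' @param cfg A [prediction_config()] (a coarse step is enough here).
#' @return A frequency in Hz.
#' @export
choose_mean_frequency <- function(mu, target = c(0.3, 0.7), n = 41,
                                  jitter = c(0.5, 1.5), seed = NULL,
                                  freq_range = c(1, 80),
                                  cfg = prediction_config(step = 1)) {
  stopifnot(inherits(mu, "motor_unit"))
  goal <- mean(target) * mu$f_mftf
  factors <- if (is.null(seed)) rep(1, n - 1)
             else withr::with_seed(seed,
               stats::runif(n - 1, jitter[1], jitter[2]))
  peak_at <- function(freq) {
    pat <- stim_pattern(factors * 1000 / freq)
    max(full_predict(mu, pat, cfg)$trace$force)
  }
  lo <- freq_range[1]; hi <- freq_range[2]
  if (peak_at(lo) >= goal) return(lo)
  # peaks explode once fusion sets in; shrink hi until finite and bracketing
  while (hi / lo > 1.01) {
    mid <- sqrt(lo * hi)
    pk <- tryCatch(peak_at(mid), error = function(e) Inf)
    if (is.finite(pk) && pk < goal) lo <- mid else hi <- mid
  }
  lo
}
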