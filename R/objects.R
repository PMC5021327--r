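#' Motor unit descriptor
#'
#' A motor unit is described by its physiological type, the parameters of its
#' first (single) twitch, and the maximal force it develops in a fused tetanus
#' (150 Hz stimulation), `f_mftf`. The twitch-to-tetanus ratio
#' `p = f_max(1) / f_mftf` must lie in (0, 1]: a single twitch cannot exceed
#' the fused-tetanus force.
#'
#' @param mu_id Character label.
#' @param mu_type One of `"S"` (slow), `"FR"` (fast fatigue-resistant),
#'   `"FF"` (fast fatigable).
#' @param first_twitch A [twitch_params()] object for the first contraction.
#' @param f_mftf Maximal fused-tetanus force (mN).
#' @return An object of class `"motor_unit"`.
#' @export
motor_unit <- function(mu_id, mu_type = c("S", "FR", "FF"), first_twitch, f_mftf) {
  mu_type <- match.arg(mu_type)
  stopifnot(inherits(first_twitch, "twitch_params"))
  if (!is.finite(f_mftf) || f_mftf <= 0)
    stop_validation("f_mftf must be a positive force (got %g)", f_mftf)
  p <- first_twitch$f_max / f_mftf
  if (p > 1)
    stop_validation("twitch-to-tetanus ratio out of range: f_max(1) = %g exceeds f_mftf = %g",
                    first_twitch$f_max, f_mftf)
  mu <- list(mu_id = as.character(mu_id), mu_type = mu_type,
             first_twitch = first_twitch, f_mftf = f_mftf)
  class(mu) <- "motor_unit"
  mu
}

#' @export
print.motor_unit <- function(x, ...) {
  cat(sprintf("Motor unit %s (type %s): F_mftf = %.4f mN, twitch-to-tetanus ratio p = %.4f\n",
              x$mu_id, x$mu_type, x$f_mftf, x$first_twitch$f_max / x$f_mftf))
  print(x$first_twitch)
  invisible(x)
}

#' Stimulation pattern
#'
#' An ordered train of stimulus pulses, stored as pulse times (ms). By
#' convention the first pulse is at time 0 and the pattern is defined by its
#' list of interpulse intervals (IPIs).
#'
#' @param ipis Numeric vector of interpulse intervals (ms), all positive;
#'   `n` pulses have `n - 1` IPIs. May be empty for a single-pulse pattern.
#' @return An object of class `"stim_pattern"` with fields `pulse_times`
#'   and `ipis`.
#' @export
stim_pattern <- function(ipis = numeric(0)) {
  ipis <- as.numeric(ipis)
  if (any(!is.finite(ipis)) || any(ipis <= 0))
    stop_validation("all interpulse intervals must be positive and finite")
  pat <- list(pulse_times = c(0, cumsum(ipis)), ipis = ipis)
  class(pat) <- "stim_pattern"
  pat
}

#' @export
print.stim_pattern <- function(x, ...) {
  n <- length(x$pulse_times)
  cat(sprintf("Stimulation pattern: %d pulses over %.1f ms", n,
              x$pulse_times[n]))
  if (n > 1)
    cat(sprintf(" (mean IPI %.2f ms, %.2f Hz)", mean(x$ipis), 1000 / mean(x$ipis)))
  cat("\n")
  invisible(x)
}

#' Uniformly sampled force trace
#'
#' A force-versus-time curve (recorded, reconstructed or predicted) sampled on
#' a uniform time grid.
#'
#' @param time Numeric vector of sample times (ms), uniform and increasing,
#'   or `NULL` to build the grid from `start` and `step`.
#' @param force Numeric vector of forces (mN).
#' @param start Start time (ms), used when `time` is `NULL`.
#' @param step Sampling step (ms), used when `time` is `NULL`.
#' @return An object of class `"force_trace"` with fields `start`, `step`,
#'   `force`.
#' @export
force_trace <- function(force, time = NULL, start = 0, step = 0.1) {
  force <- as.numeric(force)
  if (length(force) < 2)
    stop_validation("a force trace needs at least 2 samples")
  if (any(!is.finite(force)))
    stop_validation("force samples must be finite")
  if (!is.null(time)) {
    if (length(time) != length(force))
      stop_validation("time and force lengths differ (%d vs %d)",
                      length(time), length(force))
    d <- diff(time)
    if (any(d <= 0))
      stop_validation("trace time grid must be strictly increasing")
    step <- mean(d)
    if (diff(range(d)) > 1e-6 * step)
      stop_validation("trace time grid must be uniform")
    start <- time[1]
  }
  if (!is.finite(step) || step <= 0)
    stop_validation("sampling step must be positive")
  tr <- list(start = start, step = step, force = force)
  class(tr) <- "force_trace"
  tr
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples, %.4g ms step, t in [%.4g, %.4g] ms, peak %.4f mN\n",
              length(x$force), x$step, x$start,
              x$start + (length(x$force) - 1) * x$step, max(x$force)))
  invisible(x)
}

#' Sample times of a force trace
#' @param trace A [force_trace()] object.
#' @return Numeric vector of sample times (ms).
#' @export
trace_times <- function(trace) {
  trace$start + trace$step * (seq_along(trace$force) - 1)
}

#' @export
as.data.frame.force_trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), force_mN = x$force)
}

# Index of the grid point at or immediately before time t (1-based).
trace_index <- function(trace, t) {
  i <- floor((t - trace$start) / trace$step + 1e-9) + 1
  pmin(pmax(i, 1L), length(trace$force))
}

#' Train of successive contractions within a tetanus
#'
#' The output of prediction or decomposition: per-stimulus twitch parameters
#' together with the force level at which each contraction starts
#' (`f_tetmin`).
#'
#' @param stimulus_times Numeric vector of pulse times (ms).
#' @param contractions List of [twitch_params()], one per stimulus.
#' @param f_tetmin Numeric vector of starting force levels (mN); for a full
#'   prediction `f_tetmin[1] = 0`.
#' @return An object of class `"contraction_train"`.
#' @export
contraction_train <- function(stimulus_times, contractions, f_tetmin) {
  n <- length(stimulus_times)
  if (length(contractions) != n || length(f_tetmin) != n)
    stop_validation("train length mismatch: %d stimuli, %d contractions, %d f_tetmin",
                    n, length(contractions), length(f_tetmin))
  ok <- vapply(contractions, inherits, logical(1), what = "twitch_params")
  if (!all(ok)) stop_validation("contractions must all be twitch_params objects")
  tr <- list(stimulus_times = as.numeric(stimulus_times),
             contractions = contractions, f_tetmin = as.numeric(f_tetmin))
  class(tr) <- "contraction_train"
  tr
}

#' @export
length.contraction_train <- function(x) length(x$stimulus_times)

#' @export
print.contraction_train <- function(x, ...) {
  cat(sprintf("Contraction train: %d contractions\n", length(x)))
  print(utils::head(as.data.frame(x), 5))
  if (length(x) > 5) cat(sprintf("  ... and %d more\n", length(x) - 5))
  invisible(x)
}

#' @export
as.data.frame.contraction_train <- function(x, ...) {
  data.frame(
    stimulus_time = x$stimulus_times,
    f_tetmin = x$f_tetmin,
    f_max = vapply(x$contractions, `[[`, numeric(1), "f_max"),
    t_lead = vapply(x$contractions, `[[`, numeric(1), "t_lead"),
    t_hc = vapply(x$contractions, `[[`, numeric(1), "t_hc"),
    t_c = vapply(x$contractions, `[[`, numeric(1), "t_c"),
    t_hr = vapply(x$contractions, `[[`, numeric(1), "t_hr"),
    t_tw = vapply(x$contractions, `[[`, numeric(1), "t_tw"))
}

#' Reconstruct a force trace from a contraction train
#'
#' Sums the analytical curves of all contractions in a train, each shifted to
#' its stimulus time, on a uniform grid. The sum is linear in the train and
#' independent of contraction order.
#'
#' @param train A [contraction_train()] object (may be empty).
#' @param grid Numeric vector: uniform, increasing sample times (ms).
#' @return A [force_trace()] on `grid`.
#' @export
reconstruct <- function(train, grid) {
  if (length(grid) < 2)
    stop_validation("reconstruction grid needs at least 2 points")
  step <- (grid[length(grid)] - grid[1]) / (length(grid) - 1)
  total <- numeric(length(grid))
  for (i in seq_along(train$stimulus_times)) {
    p <- train$contractions[[i]]
    if (p$f_max == 0) next
    t0 <- train$stimulus_times[i]
    lo <- t0 + p$t_lead
    hi <- t0 + p$t_lead + p$t_tw
    j0 <- max(1L, ceiling((lo - grid[1]) / step) + 1L)
    j1 <- min(length(grid), floor((hi - grid[1]) / step) + 1L)
    if (j0 > j1) next
    idx <- j0:j1
    total[idx] <- total[idx] + twitch_force(p, grid[idx] - t0)
  }
  force_trace(total, start = grid[1], step = step)
}
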