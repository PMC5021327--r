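#' Fit a twitch model to a residual force segment
#'
#' Least-squares fit of the six twitch parameters to a residual force trace
#' over a window following one stimulus. The time parameters are fitted as
#' positive increments (`t_hc`, `t_c - t_hc`, `t_hr - t_c`, `t_tw - t_hr`) so
#' the parameter ordering holds throughout the optimization, which is a
#' box-bounded Levenberg-Marquardt run.
#'
#' @param residual A [force_trace()]: the recording minus all previously
#'   fitted contraction models.
#' @param stimulus_time Time of the stimulus (ms).
#' @param init A [twitch_params()] initial guess (typically the previous
#'   contraction's fit, or the single twitch).
#' @param window End of the fit window (ms, absolute); defaults to
#'   `stimulus_time + 3 * (init$t_lead + init$t_tw)`.
#' @param bounds Either a length-2 numeric vector of multiplicative box
#'   bounds applied to `init` (decomposed contractions of slow units can be
#'   several-fold higher and longer than the single twitch), or a list with
#'   numeric `lower` and `upper` vectors of length 6 bounding the increment
#'   parameterization `(f_max, t_lead, t_hc, t_c - t_hc, t_hr - t_c,
#'   t_tw - t_hr)` directly.
#' @param on_empty What to do when the window carries no signal: return a
#'   zero-amplitude sentinel (`"zero"`) or raise an error (`"error"`).
#' @param fix_lead Hold the lead time fixed at `init$t_lead` instead of
#'   fitting it (the lead time has low physiological variability and trades
#'   off against the shape parameters when fitted freely).
#' @return A fitted [twitch_params()]; the residual sum of squares is
#'   attached as attribute `"rss"`.
#' @export
fit_twitch_segment <- function(residual, stimulus_time, init,
                               window = NULL, bounds = c(0.2, 8),
                               on_empty = c("zero", "error"),
                               fix_lead = FALSE) {
  stopifnot(inherits(residual, "force_trace"), inherits(init, "twitch_params"))
  on_empty <- match.arg(on_empty)
  if (is.null(window))
    window <- stimulus_time + 3 * (init$t_lead + init$t_tw)
  tt <- trace_times(residual)
  sel <- which(tt >= stimulus_time & tt <= window)
  if (length(sel) < 8)
    stop_validation("empty or too-short fit window after stimulus at %g ms", stimulus_time)
  t_loc <- tt[sel] - stimulus_time
  y <- residual$force[sel]
  if (max(abs(y)) < 1e-9 * max(init$f_max, 1e-12)) {
    if (on_empty == "error")
      stop_numeric("no signal in fit window after stimulus at %g ms", stimulus_time)
    return(twitch_params(0, init$t_lead, init$t_hc, init$t_c, init$t_hr,
                         init$t_tw, allow_zero = TRUE))
  }

  # increments: f_max, t_lead, t_hc, dc, dr, dw (all positive)
  to_inc <- function(p) c(p$f_max, p$t_lead, p$t_hc, p$t_c - p$t_hc,
                          p$t_hr - p$t_c, p$t_tw - p$t_hr)
  from_inc <- function(th) {
    twitch_params(th[1], th[2], th[3], th[3] + th[4],
                  th[3] + th[4] + th[5], th[3] + th[4] + th[5] + th[6])
  }
  th0 <- to_inc(init)
  if (is.list(bounds)) {
    lower <- bounds$lower
    upper <- bounds$upper
    th0 <- pmin(pmax(th0, lower), upper)
  } else {
    lower <- bounds[1] * th0
    upper <- bounds[2] * th0
    lower[2] <- 0                    # lead time may shrink to zero
  }
  lower <- pmax(lower, 1e-6)
  free <- if (fix_lead) c(1L, 3L, 4L, 5L, 6L) else 1:6

  fill <- function(th) { full <- th0; full[free] <- th; full }
  fn <- function(th) twitch_force(from_inc(fill(th)), t_loc) - y
  fit <- tryCatch(
    minpack.lm::nls.lm(par = th0[free], lower = lower[free],
                       upper = upper[free], fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 300,
                                                            maxfev = 3000)),
    error = function(e) e)
  if (inherits(fit, "error") || !(fit$info %in% 1:4))
    stop_numeric("twitch fit did not converge for stimulus at %g ms%s",
                 stimulus_time,
                 if (inherits(fit, "error")) paste0(": ", conditionMessage(fit))
                 else paste0(" (nls.lm info ", fit$info, ": ", fit$message, ")"))
  out <- from_inc(fill(fit$par))
  attr(out, "rss") <- sum(fit$fvec^2)
  out
}

#' Decompose an unfused tetanus into twitch-like contractions
#'
#' Sequentially decomposes a recorded (or simulated) tetanic force curve into
#' one twitch-like contraction per stimulus. For contraction `i` the models of
#' all previous contractions are subtracted from the recording and a twitch
#' model is fitted to the residual. A first pass fits each contraction on the
#' uncontaminated segment up to the onset of the next contraction; subsequent
#' refinement sweeps refit each contraction over its full support against the
#' recording minus all other current models, which untangles the overlap of
#' neighbouring contractions.
#'
#' @param trace A [force_trace()] covering all pulses and the relaxation tail.
#' @param pattern The [stim_pattern()] that evoked the tetanus.
#' @param seed_twitch Optional [twitch_params()] used as the initial guess for
#'   the first contraction (e.g. the recorded single twitch). When `NULL` a
#'   rough guess is derived from the first inter-pulse segment.
#' @param refine Number of refinement sweeps (non-negative integer).
#' @param bounds Box bounds relative to the first-contraction fit, passed to
#'   [fit_twitch_segment()].
#' @param pair_refine Number of additional sweeps in which adjacent
#'   contractions are refitted jointly (10 shared parameters); this resolves
#'   the amplitude/duration trade-offs between strongly overlapping
#'   neighbours that single-contraction refits cannot untangle.
#' @param fix_lead Fit the lead time only for the first contraction and hold
#'   it at that value for all later ones (the lead time has low physiological
#'   variability; fitting it freely lets it trade off against the shape
#'   parameters of overlapping contractions).
#' @return A [contraction_train()]; the reconstruction similarity against
#'   `trace` is attached as attribute `"similarity"` (list with `fit_co`,
#'   `area_co`).
#' @export
decompose_tetanus <- function(trace, pattern, seed_twitch = NULL,
                              refine = 2L, pair_refine = 3L,
                              bounds = c(0.2, 8), fix_lead = TRUE) {
  stopifnot(inherits(trace, "force_trace"), inherits(pattern, "stim_pattern"))
  tt <- trace_times(trace)
  n <- length(pattern$pulse_times)
  if (tt[1] > pattern$pulse_times[1] ||
      tt[length(tt)] < pattern$pulse_times[n])
    stop_validation("trace does not cover the stimulation pattern")
  if (is.null(seed_twitch))
    seed_twitch <- seed_twitch_guess(trace, pattern)
  ref <- seed_twitch

  grid <- tt
  contractions <- vector("list", n)
  running <- numeric(length(grid))    # sum of fitted models so far

  fit_one <- function(i, init, resid_force, w_end, b, fix) {
    res_tr <- force_trace(resid_force, start = trace$start, step = trace$step)
    tryCatch(
      fit_twitch_segment(res_tr, pattern$pulse_times[i], init,
                         window = w_end, bounds = b, fix_lead = fix),
      mutet_numeric_error = function(e)
        stop_numeric("decomposition failed at contraction %d: %s", i,
                     conditionMessage(e)))
  }

  inc <- function(p) c(p$f_max, p$t_lead, p$t_hc, p$t_c - p$t_hc,
                       p$t_hr - p$t_c, p$t_tw - p$t_hr)
  glob_lo <- pmax(bounds[1] * inc(ref), 1e-6)
  glob_hi <- bounds[2] * inc(ref)
  glob_lo[2] <- 0

  # pass 1: only the segment before the next contraction's onset is clean,
  # and it may cover little more than the rising phase, so each fit is kept
  # within a trust region around the previous contraction (successive
  # contractions change gradually); the amplitude is allowed more room.
  step_up <- c(2.5, 1, 1.6, 1.6, 1.6, 1.6)
  for (i in seq_len(n)) {
    init <- if (i == 1) seed_twitch else contractions[[i - 1]]
    if (init$f_max == 0) init <- ref
    w_full <- pattern$pulse_times[i] + 3 * (ref$t_lead + ref$t_tw)
    w_end <- if (i < n)
      min(w_full, pattern$pulse_times[i + 1] + ref$t_lead)
    else w_full
    if (i > 1 && fix_lead)
      init$t_lead <- contractions[[1]]$t_lead
    b <- if (i == 1) bounds
         else list(lower = pmax(glob_lo, inc(init) / step_up),
                   upper = pmin(glob_hi, inc(init) * step_up))
    fit <- fit_one(i, init, trace$force - running, w_end, b,
                   fix = fix_lead && i > 1)
    contractions[[i]] <- fit
    running <- add_twitch(running, grid, fit, pattern$pulse_times[i])
  }

  # refinement: full-support refits against the recording minus all others,
  # now within the global bounds
  glob_bounds <- list(lower = glob_lo, upper = glob_hi)
  for (s in seq_len(max(0L, as.integer(refine)))) {
    for (i in seq_len(n)) {
      running <- add_twitch(running, grid, contractions[[i]],
                            pattern$pulse_times[i], sign = -1)
      init <- if (contractions[[i]]$f_max > 0) contractions[[i]] else ref
      w_end <- pattern$pulse_times[i] + 3 * (ref$t_lead + ref$t_tw)
      fit <- fit_one(i, init, trace$force - running, w_end, glob_bounds,
                     fix = fix_lead)
      contractions[[i]] <- fit
      running <- add_twitch(running, grid, fit, pattern$pulse_times[i])
    }
  }

  # pair refinement: joint refits of adjacent contractions
  lead1 <- contractions[[1]]$t_lead
  inc5 <- function(p) c(p$f_max, p$t_hc, p$t_c - p$t_hc, p$t_hr - p$t_c,
                        p$t_tw - p$t_hr)
  mk5 <- function(th) twitch_params(th[1], lead1, th[2], th[2] + th[3],
                                    th[2] + th[3] + th[4],
                                    th[2] + th[3] + th[4] + th[5])
  glo5 <- pmax(glob_lo[-2], 1e-6)
  ghi5 <- glob_hi[-2]
  if (n > 1) for (s in seq_len(max(0L, as.integer(pair_refine)))) {
    for (i in seq_len(n - 1)) {
      running <- add_twitch(running, grid, contractions[[i]],
                            pattern$pulse_times[i], sign = -1)
      running <- add_twitch(running, grid, contractions[[i + 1]],
                            pattern$pulse_times[i + 1], sign = -1)
      resid <- trace$force - running
      w1 <- min(pattern$pulse_times[i + 1] + 3 * (ref$t_lead + ref$t_tw),
                grid[length(grid)])
      sel <- which(grid >= pattern$pulse_times[i] & grid <= w1)
      pa <- contractions[[i]]; pb <- contractions[[i + 1]]
      if (pa$f_max > 0 && pb$f_max > 0 && length(sel) >= 12) {
        th0 <- pmin(pmax(c(inc5(pa), inc5(pb)), c(glo5, glo5)), c(ghi5, ghi5))
        fn <- function(th)
          twitch_force(mk5(th[1:5]), grid[sel] - pattern$pulse_times[i]) +
          twitch_force(mk5(th[6:10]), grid[sel] - pattern$pulse_times[i + 1]) -
          resid[sel]
        f <- tryCatch(
          minpack.lm::nls.lm(th0, lower = c(glo5, glo5),
                             upper = c(ghi5, ghi5), fn = fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 150, maxfev = 5000)),
          error = function(e) NULL)
        if (!is.null(f) && f$info %in% 1:4 &&
            sum(f$fvec^2) < sum(fn(th0)^2)) {
          contractions[[i]] <- mk5(f$par[1:5])
          contractions[[i + 1]] <- mk5(f$par[6:10])
        }
      }
      running <- add_twitch(running, grid, contractions[[i]],
                            pattern$pulse_times[i])
      running <- add_twitch(running, grid, contractions[[i + 1]],
                            pattern$pulse_times[i + 1])
    }
  }

  f_tetmin <- local_minima(trace, pattern,
                           t_lead = contractions[[1]]$t_lead)
  train <- contraction_train(pattern$pulse_times, contractions, f_tetmin)
  model <- reconstruct(train, grid)
  attr(train, "similarity") <- similarity_report(trace, model)
  train
}

# Add (or subtract) one twitch curve into a running sum on the trace grid.
add_twitch <- function(total, grid, p, t0, sign = 1) {
  if (p$f_max == 0) return(total)
  step <- grid[2] - grid[1]
  lo <- t0 + p$t_lead
  hi <- t0 + p$t_lead + p$t_tw
  j0 <- max(1L, ceiling((lo - grid[1]) / step) + 1L)
  j1 <- min(length(grid), floor((hi - grid[1]) / step) + 1L)
  if (j0 > j1) return(total)
  idx <- j0:j1
  total[idx] <- total[idx] + sign * twitch_force(p, grid[idx] - t0)
  total
}

# Rough first-twitch guess from the segment up to the second pulse: peak,
# time-to-peak and crossing times of the observed rising phase, tail times by
# typical proportions when not observable.
seed_twitch_guess <- function(trace, pattern) {
  tt <- trace_times(trace)
  end1 <- if (length(pattern$pulse_times) > 1) pattern$pulse_times[2]
          else tt[length(tt)]
  sel <- which(tt >= pattern$pulse_times[1] & tt <= end1)
  y <- trace$force[sel]
  t_loc <- tt[sel] - pattern$pulse_times[1]
  pk <- which.max(y)
  f_max <- max(y[pk], 1e-6)
  t_lead <- t_loc[match(TRUE, y > 0.01 * f_max)] %||% 0
  if (is.na(t_lead)) t_lead <- 0
  t_c <- max(t_loc[pk] - t_lead, 2 * trace$step)
  t_hc <- t_loc[match(TRUE, y > 0.5 * f_max)] - t_lead
  if (is.na(t_hc) || t_hc <= 0 || t_hc >= t_c) t_hc <- 0.55 * t_c
  twitch_params(f_max, t_lead, t_hc, t_c, 2.2 * t_c, 8 * t_c)
}

#' Starting force levels of successive contractions
#'
#' Reads, for each pulse, the local minimum of the force in the short window
#' between the pulse and the onset of the contraction it evokes (the true
#' minimum lies within the lead time). The first contraction starts from
#' rest, so its level is 0 by definition.
#'
#' @param trace A [force_trace()].
#' @param pattern The [stim_pattern()] that evoked the tetanus.
#' @param t_lead Lead time of the unit's first contraction (ms), defining the
#'   search window `[t_pulse, t_pulse + t_lead + 2 step]`.
#' @return Numeric vector of starting force levels (mN), one per pulse.
#' @export
local_minima <- function(trace, pattern, t_lead) {
  stopifnot(inherits(trace, "force_trace"), inherits(pattern, "stim_pattern"))
  tt <- trace_times(trace)
  n <- length(pattern$pulse_times)
  out <- numeric(n)
  if (n == 1) return(out)
  for (k in 2:n) {
    tp <- pattern$pulse_times[k]
    sel <- which(tt >= tp & tt <= tp + t_lead + 2 * trace$step)
    if (!length(sel))
      stop_validation("empty local-minimum search window at pulse %d", k)
    out[k] <- min(trace$force[sel])
  }
  out
}
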