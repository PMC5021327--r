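#' Sensitivity scan of the angle alpha
#'
#' Reruns the full prediction over a grid of angles centred on the integer
#' part of a starting angle and returns the angle whose predicted curve best
#' matches a reference recording. The best angle maximizes FitCo; ties within
#' 0.01 FitCo are broken by the smallest deviation of AreaCo from 1.
#'
#' @param mu A [motor_unit()].
#' @param pattern The [stim_pattern()] used for the reference.
#' @param reference A [force_trace()] to match (recorded or simulated).
#' @param alpha1 Starting angle in degrees (e.g. from [compute_alpha()]).
#' @param half_width Half-width of the scanned interval (degrees). A width of
#'   0 returns `alpha1` unchanged.
#' @param step Scan step (degrees).
#' @param cfg A [prediction_config()]; its `alpha_model` is overridden by each
#'   grid angle in turn.
#' @return A list with `alpha2` (best angle), `similarity` (list with
#'   `fit_co`, `area_co` at the optimum), and the scanned `grid` with its
#'   per-angle `fit_co` and `area_co` vectors.
#' @export
sensitivity_scan <- function(mu, pattern, reference, alpha1,
                             half_width = 20, step = 0.1,
                             cfg = prediction_config()) {
  stopifnot(inherits(reference, "force_trace"))
  if (half_width < 0 || step <= 0)
    stop_validation("half_width must be >= 0 and step > 0")
  grid <- if (half_width == 0) alpha1
          else seq(trunc(alpha1) - half_width, trunc(alpha1) + half_width,
                   by = step)
  grid <- grid[grid > 0 & grid < 180]
  if (!length(grid)) stop_validation("empty angle grid")
  ref_t <- trace_times(reference)
  fitv <- numeric(length(grid))
  areav <- numeric(length(grid))
  for (g in seq_along(grid)) {
    cfg_g <- cfg
    cfg_g$alpha_model <- grid[g]
    cfg_g$step <- reference$step
    pred <- full_predict(mu, pattern, cfg_g)
    model <- match_grid(pred$trace, reference)
    fitv[g] <- fit_co(reference, model)
    areav[g] <- area_co(reference, model)
  }
  best_fit <- max(fitv)
  cand <- which(fitv >= best_fit - 0.01)
  best <- cand[which.min(abs(areav[cand] - 1))]
  list(alpha2 = grid[best],
       similarity = list(fit_co = fitv[best], area_co = areav[best]),
       grid = grid, fit_co = fitv, area_co = areav)
}

# Resample/pad a predicted trace onto the grid of a reference trace
# (zero force outside the predicted support; same step required).
match_grid <- function(trace, reference) {
  if (abs(trace$step - reference$step) > 1e-9 * reference$step)
    stop_validation("traces have different sampling steps (%g vs %g ms)",
                    trace$step, reference$step)
  nref <- length(reference$force)
  off <- round((reference$start - trace$start) / trace$step)
  idx <- seq_len(nref) + off - 1
  f <- numeric(nref)
  ok <- idx >= 0 & idx < length(trace$force)
  f[ok] <- trace$force[idx[ok] + 1]
  force_trace(f, start = reference$start, step = reference$step)
}

#' Fit a power model y = a x^b
#'
#' Nonlinear least squares in linear space (minimizing the RMSE in `y`, the
#' criterion by which the power model was originally selected among candidate
#' fits), started from the log-log ordinary least squares solution. Two
#' distinct points are interpolated exactly.
#'
#' @param points A data frame (or list) with numeric columns `x` and `y`
#'   (e.g. force ratios and angles); `x` must be positive.
#' @return A list with coefficients `a`, `b` and the residual `rmse`.
#' @export
fit_power_model <- function(points) {
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (length(x) < 2 || length(x) != length(y))
    stop_validation("need at least 2 (x, y) points")
  if (any(x <= 0) || any(y <= 0))
    stop_validation("power-model fit requires positive x and y")
  if (diff(range(x)) == 0)
    stop_validation("degenerate fit: all x values are equal")
  # log-log OLS start (exact for noiseless power-law data)
  ll <- stats::lm(log(y) ~ log(x))
  b0 <- unname(stats::coef(ll)[2])
  a0 <- exp(unname(stats::coef(ll)[1]))
  if (length(x) == 2)
    return(list(a = a0, b = b0, rmse = 0))
  df <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(y ~ a * x^b, data = df,
                           start = list(a = a0, b = b0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(a = unname(co["a"]), b = unname(co["b"]),
       rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Fit the linear time-parameter laws
#'
#' Ordinary least-squares lines `y = p1 + p2 x` for the normalized
#' contraction time (`t_c(i)/t_c(1)`) and half-relaxation time
#' (`t_hr(i)/t_c(1)`) against the normalized starting force
#' `x = f_tetmin/f_max(1)`, with Pearson correlations.
#'
#' @param data A data frame with numeric columns `x`, `tc_ratio`,
#'   `thr_ratio`.
#' @return A list with elements `tc` and `thr`, each a list with `p1`, `p2`
#'   and `correlation` (`NA` with a warning when the response is constant).
#' @export
fit_time_param_lines <- function(data) {
  x <- as.numeric(data$x)
  if (length(x) < 3)
    stop_validation("need at least 3 points to fit the time-parameter lines")
  if (diff(range(x)) == 0)
    stop_validation("degenerate fit: all x values are equal")
  fit_line <- function(y, label) {
    co <- stats::coef(stats::lm(y ~ x))
    r <- if (stats::sd(y) == 0) {
      warning(sprintf("constant %s response: correlation undefined", label))
      NA_real_
    } else stats::cor(x, y)
    list(p1 = unname(co[1]), p2 = unname(co[2]), correlation = r)
  }
  list(tc = fit_line(as.numeric(data$tc_ratio), "tc_ratio"),
       thr = fit_line(as.numeric(data$thr_ratio), "thr_ratio"))
}

#' Calibrate the angle power law on a corpus of motor units
#'
#' For each motor unit, runs a [sensitivity_scan()] of the angle against its
#' reference tetanic curve and then refits the power law relating the best
#' angles to the units' fused-tetanus to twitch force ratios — the procedure
#' by which the ameliorated angle model was derived from the original one.
#'
#' @param mus List of [motor_unit()] objects.
#' @param patterns List of [stim_pattern()], one per unit.
#' @param references List of reference [force_trace()] objects, one per unit.
#' @param cfg A [prediction_config()].
#' @param half_width,step Scan parameters, see [sensitivity_scan()].
#' @return A list with `per_mu` (data frame: id, ratio, alpha1, alpha2,
#'   fit_co, area_co) and `power` (list `a`, `b`, `rmse`).
#' @export
calibrate_corpus <- function(mus, patterns, references,
                             cfg = prediction_config(),
                             half_width = 20, step = 0.1) {
  stopifnot(length(mus) == length(patterns),
            length(mus) == length(references))
  rows <- lapply(seq_along(mus), function(i) {
    mu <- mus[[i]]
    ratio <- mu$f_mftf / mu$first_twitch$f_max
    a1 <- resolve_alpha(mu, cfg)
    scan <- sensitivity_scan(mu, patterns[[i]], references[[i]], a1,
                             half_width = half_width, step = step, cfg = cfg)
    data.frame(mu_id = mu$mu_id, mu_type = mu$mu_type, ratio = ratio,
               alpha1 = a1, alpha2 = scan$alpha2,
               fit_co = scan$similarity$fit_co,
               area_co = scan$similarity$area_co)
  })
  per_mu <- do.call(rbind, rows)
  power <- fit_power_model(data.frame(x = per_mu$ratio, y = per_mu$alpha2))
  list(per_mu = per_mu, power = power)
}
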