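#' Six-parameter description of a twitch-like contraction
#'
#' Bundles the six parameters that describe one bell-shaped twitch-like
#' contraction of a motor unit: the peak force and five characteristic times.
#' All times are measured from the start of the contraction (i.e. after the
#' lead time), in milliseconds; force is in millinewtons.
#'
#' @param f_max Peak force of the contraction (mN). Must be positive unless
#'   `allow_zero = TRUE`, in which case `f_max = 0` denotes a degenerate
#'   "no response" contraction whose curve is identically zero.
#' @param t_lead Lead time between the stimulus and the start of the
#'   contraction (ms); non-negative.
#' @param t_hc Half-contraction time: time from contraction onset until force
#'   first reaches `f_max / 2` (ms).
#' @param t_c Contraction time: time from onset until the force peak (ms).
#' @param t_hr Half-relaxation time: time from onset until force falls back
#'   to `f_max / 2` (ms).
#' @param t_tw Total twitch duration: time from onset until force decays to
#'   0.01\% of `f_max` (ms).
#' @param allow_zero Permit `f_max = 0` (used internally when a predicted
#'   amplitude is clamped at zero).
#'
#' @return An object of class `"twitch_params"`: a named list with the six
#'   fields above plus precomputed shape exponents.
#' @seealso [build_twitch()], [twitch_force()]
#' @export
twitch_params <- function(f_max, t_lead, t_hc, t_c, t_hr, t_tw,
                          allow_zero = FALSE) {
  vals <- c(f_max = f_max, t_lead = t_lead, t_hc = t_hc, t_c = t_c,
            t_hr = t_hr, t_tw = t_tw)
  if (any(!is.finite(vals)))
    stop_validation("twitch parameters must be finite numbers")
  if (allow_zero && f_max == 0) {
    p <- list(f_max = 0, t_lead = t_lead, t_hc = t_hc, t_c = t_c,
              t_hr = t_hr, t_tw = t_tw, k = c(NA_real_, NA_real_, NA_real_))
    class(p) <- "twitch_params"
    return(p)
  }
  if (f_max <= 0)
    stop_validation("twitch parameter ordering violated: f_max > 0 required (got %g)", f_max)
  if (t_lead < 0)
    stop_validation("twitch parameter ordering violated: t_lead >= 0 required (got %g)", t_lead)
  if (!(0 < t_hc && t_hc < t_c && t_c < t_hr && t_hr < t_tw))
    stop_validation(paste0(
      "twitch parameter ordering violated: need 0 < t_hc < t_c < t_hr < t_tw, got ",
      sprintf("t_hc = %g, t_c = %g, t_hr = %g, t_tw = %g", t_hc, t_c, t_hr, t_tw)))
  p <- list(f_max = f_max, t_lead = t_lead, t_hc = t_hc, t_c = t_c,
            t_hr = t_hr, t_tw = t_tw)
  p$k <- twitch_exponents(p)
  class(p) <- "twitch_params"
  p
}

# Bell kernel on normalized time u = (t - t_lead)/t_c: rises from 0 at u = 0
# to 1 at u = 1, then decays. Raising it to a positive power moves the
# half-amplitude and end anchors without moving the peak.
bell_g <- function(u) u * exp(1 - u)

# Closed-form shape exponents pinning the three anchor constraints:
#   g(u_hc)^k1 = 1/2            (rising phase through the half-contraction time)
#   g(u_hr)^k2 = 1/2            (falling phase through the half-relaxation time)
#   (g(u_tw)/g(u_hr))^k3 = 2e-4 (tail from f_max/2 down to 1e-4 * f_max)
twitch_exponents <- function(p) {
  u_hc <- p$t_hc / p$t_c
  u_hr <- p$t_hr / p$t_c
  u_tw <- p$t_tw / p$t_c
  k1 <- log(0.5) / log(bell_g(u_hc))
  k2 <- log(0.5) / log(bell_g(u_hr))
  k3 <- log(2e-4) / log(bell_g(u_tw) / bell_g(u_hr))
  c(k1 = k1, k2 = k2, k3 = k3)
}

#' Evaluate a twitch curve at given times
#'
#' Evaluates the bell-shaped analytical twitch curve of a contraction at times
#' measured from its stimulus. The curve is zero before the contraction onset
#' (`t_lead`) and is truncated to zero beyond `t_lead + t_tw`; in between it is
#' continuous, non-negative and unimodal, passing exactly through the anchors
#' `f(t_lead + t_hc) = f_max/2` (rising), `f(t_lead + t_c) = f_max` (peak),
#' `f(t_lead + t_hr) = f_max/2` (falling) and `f(t_lead + t_tw) = 1e-4 f_max`.
#'
#' @param params A [twitch_params()] object.
#' @param t Numeric vector of times since the stimulus (ms).
#' @return Numeric vector of forces (mN), same length as `t`.
#' @export
twitch_force <- function(params, t) {
  stopifnot(inherits(params, "twitch_params"))
  f <- numeric(length(t))
  if (params$f_max == 0) return(f)
  tau <- t - params$t_lead
  u <- tau / params$t_c
  k <- params$k
  i1 <- which(tau > 0 & u <= 1)
  i2 <- which(u > 1 & tau <= params$t_hr)
  i3 <- which(tau > params$t_hr & tau <= params$t_tw)
  if (length(i1)) f[i1] <- params$f_max * bell_g(u[i1])^k[[1]]
  if (length(i2)) f[i2] <- params$f_max * bell_g(u[i2])^k[[2]]
  if (length(i3)) {
    g_hr <- bell_g(params$t_hr / params$t_c)
    f[i3] <- (params$f_max / 2) * (bell_g(u[i3]) / g_hr)^k[[3]]
  }
  f
}

#' Build a twitch curve as a function of time since the stimulus
#'
#' Returns the analytical twitch curve of a contraction as a vectorized
#' function mapping time since the stimulus (ms) to force (mN).
#'
#' @inheritParams twitch_force
#' @return A function `f(t)`; the generating parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' tw <- twitch_params(20, 2, 12, 22, 48, 180)
#' f <- build_twitch(tw)
#' f(2 + 22)  # peak force: 20
#' @export
build_twitch <- function(params) {
  stopifnot(inherits(params, "twitch_params"))
  f <- function(t) twitch_force(params, t)
  attr(f, "params") <- params
  f
}

#' Sample a twitch curve on a uniform time grid
#'
#' @param curve A function returned by [build_twitch()] (or a
#'   [twitch_params()] object).
#' @param times Strictly increasing uniform grid of times since the
#'   stimulus (ms).
#' @return Numeric vector of forces on the grid.
#' @export
evaluate_on_grid <- function(curve, times) {
  if (inherits(curve, "twitch_params")) curve <- build_twitch(curve)
  if (length(times) == 0)
    stop_validation("empty time grid")
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0))
      stop_validation("time grid must be strictly increasing")
    if (diff(range(d)) > 1e-6 * mean(d))
      stop_validation("time grid must be uniform")
  }
  curve(times)
}

#' @export
print.twitch_params <- function(x, ...) {
  cat("Twitch-like contraction parameters:\n")
  cat(sprintf("  F_max  %8.4f mN\n", x$f_max))
  cat(sprintf("  T_lead %8.4f ms   T_hc %8.4f ms   T_c %8.4f ms\n",
              x$t_lead, x$t_hc, x$t_c))
  cat(sprintf("  T_hr   %8.4f ms   T_tw %8.4f ms\n", x$t_hr, x$t_tw))
  invisible(x)
}

#' @export
format.twitch_params <- function(x, ...) {
  sprintf("twitch(F_max=%.3f, T_lead=%.2f, T_hc=%.2f, T_c=%.2f, T_hr=%.2f, T_tw=%.2f)",
          x$f_max, x$t_lead, x$t_hc, x$t_c, x$t_hr, x$t_tw)
}
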