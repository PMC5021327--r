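#' Fit coefficient between two force curves
#'
#' Point-wise similarity between a reference (e.g. recorded) and a model
#' curve, on their shared grid:
#' \deqn{FitCo = 100\,(1 - \sqrt{ \tfrac{1}{N} \sum_i \Delta_i^2 })}
#' where \eqn{\Delta_i} is the per-sample difference normalized to the common
#' maximal value of the two curves. Identical curves give 100; lower values
#' mean a bigger difference.
#'
#' @param reference,model [force_trace()] objects on the same grid.
#' @return FitCo in percent (at most 100).
#' @export
fit_co <- function(reference, model) {
  check_same_grid(reference, model)
  cmax <- max(max(reference$force), max(model$force))
  if (cmax <= 0)
    stop_validation("FitCo undefined: both traces are non-positive everywhere")
  delta <- (reference$force - model$force) / cmax
  100 * (1 - sqrt(mean(delta^2)))
}

#' Area coefficient between two force curves
#'
#' Ratio of the areas under the reference and the model curves (trapezoidal
#' rule on the shared grid). A value of 1 means equal areas; above 1 the
#' reference force output is bigger, below 1 the model overpredicts.
#'
#' @inheritParams fit_co
#' @return The dimensionless area ratio `area_ref / area_model`.
#' @export
area_co <- function(reference, model) {
  check_same_grid(reference, model)
  t <- trace_times(reference)
  a_ref <- pracma::trapz(t, reference$force)
  a_mod <- pracma::trapz(t, model$force)
  if (a_mod <= 0)
    stop_validation("AreaCo undefined: model curve has non-positive area")
  a_ref / a_mod
}

#' Similarity report for two force curves
#'
#' @inheritParams fit_co
#' @return A list with elements `fit_co` (percent) and `area_co` (ratio).
#' @export
similarity_report <- function(reference, model) {
  list(fit_co = fit_co(reference, model), area_co = area_co(reference, model))
}

check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "force_trace"), inherits(b, "force_trace"))
  if (length(a$force) != length(b$force) ||
      abs(a$start - b$start) > 1e-9 * max(1, abs(a$start)) ||
      abs(a$step - b$step) > 1e-9 * a$step)
    stop_validation("the two traces must share the same time grid")
  invisible(TRUE)
}
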