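#' Read and write force traces as CSV
#'
#' Traces are exchanged as two-column CSV files with header
#' `time_ms, force_mN` on a uniform time grid.
#'
#' @param path File path.
#' @return `read_trace()` returns a [force_trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop_validation("cannot read trace file '%s': %s", path, conditionMessage(e)))
  if (!all(c("time_ms", "force_mN") %in% names(df)))
    stop_validation("trace file '%s' must have columns time_ms, force_mN", path)
  if (nrow(df) < 2)
    stop_validation("trace file '%s' has fewer than 2 samples", path)
  bad <- which(!is.finite(df$time_ms) | !is.finite(df$force_mN))
  if (length(bad))
    stop_validation("trace file '%s': non-numeric or missing value at row %d",
                    path, bad[1])
  d <- diff(df$time_ms)
  if (any(d <= 0))
    stop_validation("trace file '%s': time not strictly increasing at row %d",
                    path, which(d <= 0)[1] + 1)
  if (diff(range(d)) > 1e-6 * mean(d))
    stop_validation("trace file '%s': non-uniform time grid", path)
  force_trace(df$force_mN, time = df$time_ms)
}

#' @rdname read_trace
#' @param trace A [force_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a stimulation pattern from an IPI file
#'
#' One interpulse interval (ms) per line; `n - 1` intervals define an
#' `n`-pulse pattern starting at time 0.
#'
#' @param path File path.
#' @return A [stim_pattern()].
#' @export
read_ipis <- function(path) {
  x <- tryCatch(scan(path, what = numeric(), quiet = TRUE,
                     comment.char = "#"),
                error = function(e)
                  stop_validation("cannot read IPI file '%s': %s", path,
                                  conditionMessage(e)))
  if (!length(x))
    stop_validation("IPI file '%s' is empty", path)
  if (any(!is.finite(x)) || any(x <= 0))
    stop_validation("IPI file '%s': all interpulse intervals must be positive", path)
  stim_pattern(x)
}

#' @rdname read_ipis
#' @param pattern A [stim_pattern()].
#' @export
write_ipis <- function(pattern, path) {
  stopifnot(inherits(pattern, "stim_pattern"))
  writeLines(format(pattern$ipis, trim = TRUE, digits = 10), path)
  invisible(path)
}

#' Read and write motor-unit parameter tables
#'
#' CSV with one row per motor unit and columns `id, type, f_max1, t_lead1,
#' t_hc1, t_c1, t_hr1, t_tw1, f_mftf` (forces in mN, times in ms).
#'
#' @param path File path.
#' @return `read_mus()` returns a list of [motor_unit()] objects.
#' @export
read_mus <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_validation("cannot read MU file '%s': %s", path,
                                   conditionMessage(e)))
  need <- c("id", "type", "f_max1", "t_lead1", "t_hc1", "t_c1", "t_hr1",
            "t_tw1", "f_mftf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("MU file '%s' is missing column(s): %s", path,
                    paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    ft <- twitch_params(row$f_max1, row$t_lead1, row$t_hc1, row$t_c1,
                        row$t_hr1, row$t_tw1)
    motor_unit(row$id, row$type, ft, row$f_mftf)
  })
}

#' @rdname read_mus
#' @param mus A list of [motor_unit()] objects.
#' @export
write_mus <- function(mus, path) {
  df <- do.call(rbind, lapply(mus, function(mu) {
    ft <- mu$first_twitch
    data.frame(id = mu$mu_id, type = mu$mu_type, f_max1 = ft$f_max,
               t_lead1 = ft$t_lead, t_hc1 = ft$t_hc, t_c1 = ft$t_c,
               t_hr1 = ft$t_hr, t_tw1 = ft$t_tw, f_mftf = mu$f_mftf)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a contraction train as CSV
#'
#' Columns: `stimulus_time, f_tetmin` and the six twitch parameters.
#'
#' @param train A [contraction_train()].
#' @param path File path.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "contraction_train"))
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}
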