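# Fixed-rate continuous traces (pupil radius, whisker angle, intensity
# functions). A trace is a numeric vector plus a sample rate and start time.

#' Construct a fixed-rate trace
#'
#' Container for regularly sampled continuous signals such as pupil radius
#' (60 Hz) or whisker mean angle (125 Hz).
#'
#' @param values Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param start_s Time of the first sample, in seconds.
#' @return An object of class `fr_trace`.
#' @examples
#' tr <- fr_trace(sin(seq(0, 2 * pi, length.out = 125)), rate_hz = 125)
#' range(trace_times(tr))
#' @export
fr_trace <- function(values, rate_hz, start_s = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  stopifnot(is.numeric(start_s), length(start_s) == 1L, is.finite(start_s))
  structure(
    list(values = as.numeric(values), rate_hz = rate_hz, start_s = start_s),
    class = "fr_trace"
  )
}

#' Sample times of a fixed-rate trace
#'
#' @param x An `fr_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "fr_trace"))
  x$start_s + (seq_along(x$values) - 1L) / x$rate_hz
}

#' Duration of a fixed-rate trace in seconds
#' @param x An `fr_trace`.
#' @return Duration in seconds (n samples / rate).
#' @export
trace_duration <- function(x) {
  length(x$values) / x$rate_hz
}

#' @export
print.fr_trace <- function(x, ...) {
  cat(sprintf(
    "<fr_trace> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    length(x$values), x$rate_hz, x$start_s,
    x$start_s + (length(x$values) - 1L) / x$rate_hz
  ))
  invisible(x)
}

#' Linearly interpolate a trace onto an arbitrary time grid
#'
#' Values outside the trace support are held at the nearest sample.
#' @noRd
trace_at <- function(x, times) {
  stats::approx(trace_times(x), x$values, xout = times, rule = 2)$y
}

#' Write a trace to CSV (header rows `rate_hz`, `start_s`, then values)
#'
#' @param x An `fr_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "fr_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("rate_hz,%.10g", x$rate_hz), con)
  writeLines(sprintf("start_s,%.10g", x$start_s), con)
  writeLines(sprintf("%.10g", x$values), con)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path File path.
#' @return An `fr_trace`.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  stopifnot(length(lines) >= 3L)
  rate <- as.numeric(sub("^rate_hz,", "", lines[1L]))
  start <- as.numeric(sub("^start_s,", "", lines[2L]))
  fr_trace(as.numeric(lines[-(1:2)]), rate_hz = rate, start_s = start)
}
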