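# Conditioning of the continuous physiology/arousal signals: pupil-radius
# cleaning (blink removal), Hilbert-envelope whisking amplitude, and
# resampling of all streams onto a common 1-kHz timeline.

#' Pupil radius from a fitted ellipse
#'
#' Geometric mean of the semi-major and semi-minor axes.
#'
#' @param semi_major,semi_minor Axis lengths (> 0), any common length unit.
#' @return Radius in the same unit. Vectorized.
#' @examples
#' pupil_radius_from_ellipse(9, 1) # 3
#' @export
pupil_radius_from_ellipse <- function(semi_major, semi_minor) {
  if (any(!is.finite(semi_major)) || any(!is.finite(semi_minor)) ||
      any(semi_major <= 0) || any(semi_minor <= 0)) {
    stop("ellipse axes must be positive and finite", call. = FALSE)
  }
  sqrt(semi_major * semi_minor)
}

#' Clean a pupil-radius trace
#'
#' Blink artifacts are detected as samples deviating from a 3-s running
#' median by more than a fraction of that median, removed, and linearly
#' interpolated; the result is then smoothed with a 5-frame moving average.
#' Intended for ~60 Hz pupillometry traces.
#'
#' @param trace An [fr_trace()] (pupil radius).
#' @param smooth_frames Moving-average span in frames (default 5).
#' @param median_span_s Running-median span in seconds (default 3).
#' @param deviation_frac Exclusion threshold as a fraction of the local
#'   median (default 0.25).
#' @param max_excluded_frac Reject the trace if more than this fraction of
#'   samples is excluded (default 0.5).
#' @return A cleaned `fr_trace` with attribute `n_excluded`.
#' @export
clean_pupil_trace <- function(trace, smooth_frames = 5, median_span_s = 3,
                              deviation_frac = 0.25,
                              max_excluded_frac = 0.5) {
  stopifnot(inherits(trace, "fr_trace"))
  v <- trace$values
  n <- length(v)
  k <- max(3L, round(median_span_s * trace$rate_hz))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  med <- stats::runmed(v, k, endrule = "median")
  bad <- abs(v - med) > deviation_frac * abs(med)
  if (mean(bad) > max_excluded_frac) {
    stop(sprintf(
      "pupil trace rejected: %.0f%% of samples flagged as artifacts",
      100 * mean(bad)
    ), call. = FALSE)
  }
  if (any(bad)) {
    good <- which(!bad)
    v[bad] <- stats::approx(good, v[good], xout = which(bad), rule = 2)$y
  }
  if (smooth_frames > 1L) {
    w <- rep(1 / smooth_frames, smooth_frames)
    sm <- stats::filter(v, w, sides = 2)
    # centered moving average is NA at the edges; hold raw values there
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  out <- fr_trace(v, trace$rate_hz, trace$start_s)
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Whisking amplitude via band-pass filter and Hilbert transform
#'
#' The mean whisker angle is band-pass filtered in the whisk band
#' (default 4-30 Hz) with a zero-phase 4th-order Butterworth filter
#' (forward-backward). The instantaneous phase of the analytic signal
#' defines the whisk cycle: samples where phase crosses 0 are the most
#' protracted points, samples where phase wraps at +/-pi the most
#' retracted. Envelopes are anchored at those samples on the *unfiltered*
#' angle, linearly interpolated between anchors (held constant beyond the
#' first/last anchor), and whisking amplitude is their difference,
#' floored at zero.
#'
#' @param angle An [fr_trace()] of whisker mean angle, degrees (~125 Hz).
#' @param band_hz Pass band in Hz (default c(4, 30)).
#' @return An object of class `whisk_decomp`: `filtered_angle`, `phase`,
#'   `protracted_envelope`, `retracted_envelope`, `amplitude` (all
#'   `fr_trace`s on the input grid).
#' @examples
#' t <- seq(0, 4, by = 1 / 125)
#' wd <- whisk_amplitude(fr_trace(60 + 10 * sin(2 * pi * 8 * t), 125))
#' mean(wd$amplitude$values[200:300]) # ~ 20 degrees peak-to-trough
#' @export
whisk_amplitude <- function(angle, band_hz = c(4, 30)) {
  stopifnot(inherits(angle, "fr_trace"))
  fs <- angle$rate_hz
  x <- angle$values
  n <- length(x)
  if (n / fs <= 1) {
    stop("whisker-angle trace must be longer than 1 s", call. = FALSE)
  }
  stopifnot(band_hz[2L] < fs / 2)
  # signal::butter doubles the order for band-pass designs: n = 2 -> 4th order
  bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, x - mean(x))
  an <- analytic_signal(filt)
  phase <- Arg(an)
  dphase <- diff(phase)
  # phase 0 crossing (negative -> positive, no wrap): most protracted
  prot <- which(phase[-n] < 0 & phase[-1L] >= 0 & abs(dphase) < pi) + 1L
  # wrap from +pi to -pi: most retracted
  retr <- which(dphase < -pi) + 1L
  envelope <- function(anchors) {
    if (length(anchors) == 0L) {
      return(rep(stats::median(x), n))
    }
    if (length(anchors) == 1L) {
      return(rep(x[anchors], n))
    }
    stats::approx(anchors, x[anchors], xout = seq_len(n), rule = 2)$y
  }
  upper <- envelope(prot)
  lower <- envelope(retr)
  amp <- pmax(upper - lower, 0)
  structure(
    list(
      filtered_angle = fr_trace(filt, fs, angle$start_s),
      phase = fr_trace(phase, fs, angle$start_s),
      protracted_envelope = fr_trace(upper, fs, angle$start_s),
      retracted_envelope = fr_trace(lower, fs, angle$start_s),
      amplitude = fr_trace(amp, fs, angle$start_s)
    ),
    class = "whisk_decomp"
  )
}

#' @export
print.whisk_decomp <- function(x, ...) {
  cat(sprintf(
    "<whisk_decomp> %d samples @ %g Hz, median amplitude %.2f deg\n",
    length(x$amplitude$values), x$amplitude$rate_hz,
    stats::median(x$amplitude$values)
  ))
  invisible(x)
}

#' Resample traces and events onto a common 1-kHz timeline
#'
#' Continuous traces are linearly interpolated onto a shared grid spanning
#' the intersection of their supports; event times are rounded to the
#' nearest millisecond (grid step).
#'
#' @param traces Named list of [fr_trace()]s.
#' @param events Named list of numeric event-time vectors (may be empty).
#' @param rate_hz Target rate (default 1000).
#' @return List with `rate_hz`, `start_s`, `traces` (named list of
#'   `fr_trace`s on the common grid), `events` (rounded).
#' @export
resample_to_common_rate <- function(traces, events = list(), rate_hz = 1000) {
  stopifnot(length(traces) >= 1L, all(vapply(traces, inherits, TRUE, "fr_trace")))
  t0 <- max(vapply(traces, function(x) x$start_s, numeric(1)))
  t1 <- min(vapply(
    traces,
    function(x) x$start_s + (length(x$values) - 1L) / x$rate_hz, numeric(1)
  ))
  if (t1 <= t0) {
    stop("trace time supports do not overlap", call. = FALSE)
  }
  grid <- seq(t0, t1, by = 1 / rate_hz)
  out_traces <- lapply(traces, function(x) {
    fr_trace(trace_at(x, grid), rate_hz, t0)
  })
  out_events <- lapply(events, function(e) round(e * rate_hz) / rate_hz)
  list(rate_hz = rate_hz, start_s = t0, traces = out_traces, events = out_events)
}
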