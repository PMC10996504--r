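# Movement/arousal regression: firing rates, lick rate, whisking amplitude
# and pupil radius are binned on one 250-ms grid; each unit's rate is fit
# by ordinary least squares on the three movement predictors; the model
# residuals are a baseline-subtracted, movement-corrected firing rate used
# for residual PSTHs and the coupling/gain dissociation. Cross-correlations
# between firing and each movement variable complete the module.

#' Bin a session onto a common grid
#'
#' Spike counts become per-bin firing rates (Hz), lick events a per-bin
#' lick rate, and continuous traces per-bin means. A final partial bin is
#' dropped (with a message).
#'
#' @param session A `synth_session` (or loaded bundle) — see
#'   [simulate_population()], [read_session()]. Whisking amplitude is
#'   computed from the whisker-angle trace via [whisk_amplitude()].
#' @param bin_s Bin width in seconds (default 0.25).
#' @return Object of class `binned_session`: `bin_start` (vector),
#'   `bin_s`, `rates` (units x bins matrix, Hz), `lick_rate`, `pupil`,
#'   `whisk_amp`.
#' @export
bin_session <- function(session, bin_s = 0.25) {
  L <- session$schedule$session_length_s
  n_bins <- floor(L / bin_s)
  if (n_bins * bin_s < L) {
    message(sprintf(
      "final partial bin (%.3f s) dropped", L - n_bins * bin_s
    ))
  }
  starts <- (seq_len(n_bins) - 1L) * bin_s
  ends <- starts + bin_s
  rates <- t(vapply(
    session$spikes,
    function(st) count_in_windows(st, starts, ends) / bin_s,
    numeric(n_bins)
  ))
  bin_trace <- function(tr) {
    idx <- floor((trace_times(tr) - 0) / bin_s) + 1L
    ok <- idx >= 1L & idx <= n_bins
    means <- rep(NA_real_, n_bins)
    agg <- tapply(tr$values[ok], idx[ok], mean)
    means[as.integer(names(agg))] <- agg
    # bins not covered by the trace (edges) hold the nearest value
    if (anyNA(means)) {
      means <- stats::approx(which(!is.na(means)), means[!is.na(means)],
        xout = seq_len(n_bins), rule = 2
      )$y
    }
    means
  }
  amp <- whisk_amplitude(session$whisker)$amplitude
  structure(
    list(
      bin_start = starts, bin_s = bin_s,
      rates = rates,
      lick_rate = count_in_windows(sort(session$lick_times), starts, ends) / bin_s,
      pupil = bin_trace(session$pupil),
      whisk_amp = bin_trace(amp)
    ),
    class = "binned_session"
  )
}

#' @export
print.binned_session <- function(x, ...) {
  cat(sprintf(
    "<binned_session> %d units x %d bins @ %.3g s\n",
    nrow(x$rates), length(x$bin_start), x$bin_s
  ))
  invisible(x)
}

#' Fit the movement model for one unit
#'
#' Ordinary least squares of the unit's binned firing rate on whisking
#' amplitude, pupil radius and lick rate, with an intercept (the baseline
#' term). Predictors are standardized internally for numerical stability;
#' coefficients are reported on the original scale. Constant predictors
#' are dropped from the design (with a message). Residuals are the
#' baseline-subtracted, movement-corrected firing rate.
#'
#' @param binned A [bin_session()] result.
#' @param unit_id Unit to fit.
#' @param min_bins Minimum number of bins (default 100).
#' @return Object of class `movement_fit`: `unit_id`, `coefficients`
#'   (named: intercept, whisk, pupil, lick; `NA` for dropped predictors),
#'   `residuals`, `fitted`, `r2`, `bin_start`, `bin_s`.
#' @export
fit_movement_model <- function(binned, unit_id, min_bins = 100) {
  stopifnot(inherits(binned, "binned_session"))
  i <- match(unit_id, rownames(binned$rates))
  if (is.na(i)) stop("unknown unit_id: ", unit_id, call. = FALSE)
  y <- binned$rates[i, ]
  if (length(y) < min_bins) {
    stop(sprintf("need >= %d bins (got %d)", min_bins, length(y)),
      call. = FALSE
    )
  }
  preds <- list(
    whisk = binned$whisk_amp, pupil = binned$pupil, lick = binned$lick_rate
  )
  sds <- vapply(preds, stats::sd, numeric(1))
  keep <- sds > 0
  if (!all(keep)) {
    message(
      "constant predictor(s) dropped: ",
      paste(names(preds)[!keep], collapse = ", ")
    )
  }
  coefs <- c(intercept = NA_real_, whisk = NA_real_, pupil = NA_real_,
             lick = NA_real_)
  if (!any(keep)) {
    res <- y - mean(y)
    coefs["intercept"] <- mean(y)
    fit_r2 <- 0
    fitted <- rep(mean(y), length(y))
  } else {
    Xs <- vapply(preds[keep], function(v) (v - mean(v)) / stats::sd(v),
      numeric(length(y))
    )
    fit <- stats::lm.fit(cbind(1, Xs), y)
    b_std <- fit$coefficients
    # back-transform standardized slopes to original predictor units
    slopes <- b_std[-1L] / sds[keep]
    coefs[names(preds)[keep]] <- slopes
    coefs["intercept"] <- b_std[1L] -
      sum(slopes * vapply(preds[keep], mean, numeric(1)))
    res <- fit$residuals
    fitted <- fit$fitted.values
    tss <- sum((y - mean(y))^2)
    fit_r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  }
  structure(
    list(
      unit_id = unit_id, coefficients = coefs, residuals = as.numeric(res),
      fitted = as.numeric(fitted), r2 = fit_r2,
      bin_start = binned$bin_start, bin_s = binned$bin_s
    ),
    class = "movement_fit"
  )
}

#' @export
print.movement_fit <- function(x, ...) {
  cat(sprintf(
    "<movement_fit> %s: R^2 = %.3f; b = [%s]\n",
    x$unit_id, x$r2,
    paste(sprintf("%s %.3g", names(x$coefficients), x$coefficients),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Event-aligned PSTH of movement-model residuals
#'
#' The residual series is cut into peri-stimulus windows around retained
#' presentations of one modality and averaged across presentations.
#'
#' @param fit A [fit_movement_model()] result.
#' @param schedule The session's [stim_schedule()].
#' @param modality `"tactile"` or `"visual"`.
#' @param window_s Peri-stimulus window (default c(-2, 4) s).
#' @param overlap_window_s Cross-modal exclusion distance (default 6 s).
#' @return Data frame: `time_s` (bin start relative to onset), `mean`,
#'   `sem`, `n`. Empty (with a message) when nothing is retained.
#' @export
residual_psth <- function(fit, schedule, modality, window_s = c(-2, 4),
                          overlap_window_s = 6) {
  modality <- match.arg(modality, c("tactile", "visual"))
  ev <- schedule$events
  keep <- retained_presentations(schedule, overlap_window_s)
  onsets <- ev$onset_s[keep & ev$modality == modality]
  rel <- seq(window_s[1L], window_s[2L] - fit$bin_s, by = fit$bin_s)
  if (length(onsets) == 0L) {
    message("no retained presentations for residual PSTH")
    return(data.frame(
      time_s = rel, mean = NA_real_, sem = NA_real_, n = 0L
    ))
  }
  n_bins <- length(fit$residuals)
  mat <- vapply(onsets, function(o) {
    idx <- floor((o + rel) / fit$bin_s) + 1L
    out <- rep(NA_real_, length(rel))
    ok <- idx >= 1L & idx <= n_bins
    out[ok] <- fit$residuals[idx[ok]]
    out
  }, numeric(length(rel)))
  m <- rowMeans(mat, na.rm = TRUE)
  n_ok <- rowSums(!is.na(mat))
  s <- apply(mat, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L))
  data.frame(time_s = rel, mean = m, sem = s, n = n_ok)
}

#' Cross-correlation between a unit's firing rate and a movement variable
#'
#' Pearson correlation at integer-bin lags. The sign convention follows
#' the physiology reading: a *negative* lag means the firing rate precedes
#' the movement variable, a positive lag that it follows it (a rate equal
#' to the predictor delayed by 1 s peaks at lag +1 s).
#'
#' @param binned A [bin_session()] result.
#' @param unit_id Unit to correlate.
#' @param predictor `"pupil"`, `"whisk"` or `"lick"`.
#' @param max_lag_s Maximum absolute lag (default 3 s).
#' @return Data frame: `lag_s`, `r` (`NA` where a series is degenerate).
#' @export
firing_behavior_xcorr <- function(binned, unit_id,
                                  predictor = c("pupil", "whisk", "lick"),
                                  max_lag_s = 3) {
  stopifnot(inherits(binned, "binned_session"))
  predictor <- match.arg(predictor)
  i <- match(unit_id, rownames(binned$rates))
  if (is.na(i)) stop("unknown unit_id: ", unit_id, call. = FALSE)
  y <- binned$rates[i, ]
  x <- switch(predictor,
    pupil = binned$pupil, whisk = binned$whisk_amp, lick = binned$lick_rate
  )
  n <- length(y)
  max_lag <- floor(max_lag_s / binned$bin_s)
  stopifnot(n > 3L * max_lag)
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(l) {
    # value at lag l: cor(rate(t), predictor(t - l))
    if (l >= 0L) {
      yy <- y[(1L + l):n]
      xx <- x[1L:(n - l)]
    } else {
      yy <- y[1L:(n + l)]
      xx <- x[(1L - l):n]
    }
    if (stats::sd(yy) == 0 || stats::sd(xx) == 0) {
      return(NA_real_)
    }
    stats::cor(yy, xx)
  }, numeric(1))
  data.frame(lag_s = lags * binned$bin_s, r = r)
}
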