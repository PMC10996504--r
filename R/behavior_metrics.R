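# Lick detection and the lick index (LI), the behavioral readout of
# learning: LI = (licks during stimulus - licks in the 2 s before onset) /
# (sum of both counts), in [-1, 1]. Positive LI means the animal licks in
# response to the stimulus (anticipation), negative means it withholds
# licking, zero means it ignores the stimulus.

#' Detect licks from an analog lick-port signal
#'
#' One lick per upward threshold crossing; crossings closer than the
#' debounce interval are merged into the first crossing of the group.
#'
#' @param signal An [fr_trace()] of the analog lick sensor.
#' @param threshold Threshold in signal units.
#' @param debounce_s Minimum separation between detected licks (default 0.05 s).
#' @return Numeric vector of lick times in seconds (possibly empty).
#' @examples
#' tr <- fr_trace(rep(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0), 3), rate_hz = 100)
#' detect_licks(tr, threshold = 0.5)
#' @export
detect_licks <- function(signal, threshold, debounce_s = 0.05) {
  stopifnot(inherits(signal, "fr_trace"))
  v <- signal$values
  above <- v >= threshold
  idx <- which(above[-1L] & !above[-length(above)]) + 1L
  if (above[1L]) idx <- c(1L, idx)
  if (length(idx) == 0L) {
    return(numeric(0))
  }
  times <- signal$start_s + (idx - 1L) / signal$rate_hz
  kept <- times[1L]
  if (length(times) > 1L) {
    for (t in times[-1L]) {
      if (t - kept[length(kept)] > debounce_s) kept <- c(kept, t)
    }
  }
  kept
}

#' Lick index for one stimulus presentation
#'
#' Baseline window is the 2 s before onset, stimulus window is the stimulus
#' itself; licks within +/-50 ms of onset are ambiguous and excluded from
#' both windows. If the stimulus duration differs from the 2-s baseline,
#' counts are rate-normalized before the formula (an extension beyond the
#' standard 2-s design, flagged by the `rate_normalized` field).
#'
#' @param lick_times Numeric vector of lick times, seconds.
#' @param onset_s Stimulus onset, seconds.
#' @param duration_s Stimulus duration, seconds (default 2).
#' @param baseline_s Baseline window length, seconds (default 2).
#' @param exclusion_s Half-width of the onset ambiguity band (default 0.05).
#' @return A one-row data frame: `licks_baseline`, `licks_stimulus`, `li`
#'   (`NA` when both counts are zero), `rate_normalized`.
#' @examples
#' lick_index(c(0.5, 1.0, 10.2, 10.6, 11.1), onset_s = 10)
#' @export
lick_index <- function(lick_times, onset_s, duration_s = 2,
                       baseline_s = 2, exclusion_s = 0.05) {
  stopifnot(onset_s >= baseline_s)
  ambiguous <- abs(lick_times - onset_s) <= exclusion_s
  lt <- lick_times[!ambiguous]
  n_base <- sum(lt >= onset_s - baseline_s & lt < onset_s)
  n_stim <- sum(lt > onset_s & lt <= onset_s + duration_s)
  rate_normalized <- !isTRUE(all.equal(duration_s, baseline_s))
  b <- n_base / baseline_s
  s <- n_stim / duration_s
  if (!rate_normalized) {
    b <- n_base
    s <- n_stim
  }
  li <- if (b + s > 0) (s - b) / (s + b) else NA_real_
  data.frame(
    licks_baseline = n_base, licks_stimulus = n_stim,
    li = li, rate_normalized = rate_normalized
  )
}

#' Lick index for every presentation in a schedule
#'
#' @param lick_times Numeric vector of lick times, seconds.
#' @param schedule A [stim_schedule()].
#' @param ... Passed to [lick_index()].
#' @return Data frame with one row per presentation: `stim_id`, `modality`,
#'   `rewarded`, `onset_s`, the [lick_index()] columns.
#' @export
lick_index_table <- function(lick_times, schedule, ...) {
  ev <- schedule$events
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    li <- lick_index(lick_times, ev$onset_s[i], ev$duration_s[i], ...)
    cbind(
      data.frame(
        stim_id = i, modality = ev$modality[i],
        rewarded = ev$rewarded[i], onset_s = ev$onset_s[i]
      ),
      li
    )
  })
  do.call(rbind, rows)
}

#' Session-level learning-criterion tests
#'
#' Advance-to-full criterion: the session's CS+ lick indices are
#' significantly greater than zero (one-sided Wilcoxon signed-rank test)
#' with a minimum number of shaping sessions. Training-complete criterion:
#' the CS- lick indices are not significantly different from zero
#' (two-sided) with a minimum number of full-task sessions. Presentations
#' with undefined LI (no licks in either window) are excluded.
#'
#' @param li_table Output of [lick_index_table()].
#' @param cs_plus Rewarded modality.
#' @param n_shaping_sessions Number of shaping sessions completed so far.
#' @param n_full_sessions Number of full-task sessions completed so far.
#' @param alpha Significance level (default 0.05).
#' @param min_shaping_days Minimum shaping sessions before advancing (3).
#' @param min_full_days Minimum full-task sessions before completion (4).
#' @return List with per-modality mean LI, test p-values, evaluability
#'   flags, and the `advance_to_full` / `training_complete` flags.
#' @export
session_learning_tests <- function(li_table, cs_plus,
                                   n_shaping_sessions = 1,
                                   n_full_sessions = 0,
                                   alpha = 0.05,
                                   min_shaping_days = 3,
                                   min_full_days = 4) {
  cs_plus <- match.arg(cs_plus, c("tactile", "visual"))
  cs_minus <- setdiff(c("tactile", "visual"), cs_plus)
  li_plus <- li_table$li[li_table$modality == cs_plus & is.finite(li_table$li)]
  li_minus <- li_table$li[li_table$modality == cs_minus & is.finite(li_table$li)]
  plus_eval <- length(li_plus) >= 1L
  minus_eval <- length(li_minus) >= 1L
  p_plus <- if (plus_eval) signrank_p(li_plus, "greater") else NA_real_
  p_minus <- if (minus_eval) signrank_p(li_minus, "two.sided") else NA_real_
  list(
    cs_plus = cs_plus,
    mean_li_cs_plus = if (plus_eval) mean(li_plus) else NA_real_,
    mean_li_cs_minus = if (minus_eval) mean(li_minus) else NA_real_,
    n_defined_cs_plus = length(li_plus),
    n_defined_cs_minus = length(li_minus),
    p_cs_plus_gt0 = p_plus,
    p_cs_minus_ne0 = p_minus,
    evaluable_cs_plus = plus_eval,
    evaluable_cs_minus = minus_eval,
    advance_to_full = plus_eval && p_plus < alpha &&
      n_shaping_sessions >= min_shaping_days,
    training_complete = minus_eval && p_minus >= alpha &&
      n_full_sessions >= min_full_days
  )
}
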