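# Stimulus-schedule generation for the shaping and full versions of the
# cross-modal conditioning task, plus the hazard-rate diagnostic used to
# verify that full-task stimulus timing is unpredictable.
#
# Shaping task: a single interleaved stream of tactile (air puff) and visual
# (drifting grating) stimuli, balanced 50:50, with onset-to-onset gaps drawn
# Uniform(8, 12) s. Full task: per-modality inter-stimulus intervals drawn
# Exponential(mean 10 s) + Uniform(8, 12) s, clipped at 55 s and rounded to
# whole seconds; the two modality streams are drawn independently, so
# stimuli may overlap and neither stream predicts the other.

STIM_DURATION_S <- 2

#' Construct a stimulus schedule object
#'
#' Normally produced by [draw_shaping_schedule()] or [draw_full_schedule()].
#'
#' @param events Data frame with columns `onset_s`, `duration_s`, `modality`
#'   (`"tactile"` or `"visual"`), `rewarded` (logical), `reward_time_s`
#'   (`NA` for unrewarded events).
#' @param task_phase `"shaping"` or `"full"`.
#' @param cs_plus The rewarded modality.
#' @param seed Seed recorded in metadata (may be `NULL`).
#' @param session_length_s Session length; default last offset + 5 s.
#' @return An object of class `stim_schedule`.
#' @export
stim_schedule <- function(events, task_phase, cs_plus, seed = NULL,
                          session_length_s = NULL) {
  stopifnot(is.data.frame(events))
  stopifnot(all(c("onset_s", "duration_s", "modality", "rewarded",
                  "reward_time_s") %in% names(events)))
  task_phase <- match.arg(task_phase, c("shaping", "full"))
  cs_plus <- match.arg(cs_plus, c("tactile", "visual"))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  stopifnot(all(events$onset_s >= 0), all(events$duration_s > 0))
  stopifnot(all(events$modality %in% c("tactile", "visual")))
  # within one modality events must be sorted and non-overlapping
  for (m in unique(events$modality)) {
    ev <- events[events$modality == m, , drop = FALSE]
    if (nrow(ev) > 1L) {
      gaps <- diff(ev$onset_s)
      stopifnot(all(gaps >= ev$duration_s[-nrow(ev)]))
    }
  }
  rew <- events$rewarded
  stopifnot(all(abs(events$reward_time_s[rew] -
                    (events$onset_s[rew] + events$duration_s[rew])) < 1e-9))
  if (is.null(session_length_s)) {
    session_length_s <- max(events$onset_s + events$duration_s) + 5
  }
  structure(
    list(
      events = events, task_phase = task_phase, cs_plus = cs_plus,
      seed = seed, session_length_s = session_length_s
    ),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %s task, CS+ = %s: %d tactile + %d visual events over %.0f s\n",
    x$task_phase, x$cs_plus,
    sum(x$events$modality == "tactile"), sum(x$events$modality == "visual"),
    x$session_length_s
  ))
  invisible(x)
}

#' Reward delivery times of a schedule
#' @param schedule A `stim_schedule`.
#' @return Numeric vector of reward times (CS+ offsets), in seconds.
#' @export
reward_times <- function(schedule) {
  ev <- schedule$events
  sort(ev$reward_time_s[ev$rewarded])
}

make_events <- function(onsets, modality, cs_plus,
                        duration = STIM_DURATION_S) {
  rewarded <- modality == cs_plus
  data.frame(
    onset_s = onsets,
    duration_s = duration,
    modality = modality,
    rewarded = rewarded,
    reward_time_s = ifelse(rewarded, onsets + duration, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Draw a shaping-task schedule
#'
#' Trial-based schedule: one stimulus per trial, modality labels a random
#' permutation of an exactly balanced vector (so counts are equal), and
#' onset-to-onset gaps drawn Uniform(8, 12) s. The CS+ modality is rewarded
#' at stimulus offset. Because gaps exceed the 2-s stimulus duration, the
#' two modalities never overlap.
#'
#' @param n_per_modality Number of presentations per modality (>= 1).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param cs_plus Rewarded modality, `"tactile"` (default) or `"visual"`.
#' @return A `stim_schedule` with `task_phase = "shaping"`.
#' @examples
#' sched <- draw_shaping_schedule(10, seed = 1)
#' table(sched$events$modality)
#' @export
draw_shaping_schedule <- function(n_per_modality, seed = NULL,
                                  cs_plus = c("tactile", "visual")) {
  if (!is.numeric(n_per_modality) || length(n_per_modality) != 1L ||
      !is.finite(n_per_modality) || n_per_modality < 1) {
    stop("`n_per_modality` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n_per_modality)
  cs_plus <- match.arg(cs_plus)
  with_seed(seed, {
    labels <- sample(rep(c("tactile", "visual"), n))
    gaps <- stats::runif(2L * n, min = 8, max = 12)
    onsets <- cumsum(gaps)
    stim_schedule(make_events(onsets, labels, cs_plus),
      task_phase = "shaping", cs_plus = cs_plus, seed = seed
    )
  })
}

#' Draw full-task inter-stimulus intervals
#'
#' ISIs are Exponential(mean 10 s) plus an independent Uniform(8, 12) s
#' offset, clipped at 55 s, then rounded to the nearest whole second.
#' Past the offset support the hazard of this distribution is flat at
#' 1 - exp(-1/10) per 1-s bin, so stimulus timing carries no information.
#'
#' @param n Number of intervals.
#' @param exp_mean_s Mean of the exponential component (default 10 s).
#' @param offset_range_s Range of the uniform offset (default c(8, 12)).
#' @param cap_s Clipping bound (default 55 s).
#' @param round_isi Round ISIs to whole seconds (default TRUE).
#' @return Numeric vector of ISIs in seconds.
#' @export
draw_full_isis <- function(n, exp_mean_s = 10, offset_range_s = c(8, 12),
                           cap_s = 55, round_isi = TRUE) {
  stopifnot(n >= 1)
  isi <- stats::rexp(n, rate = 1 / exp_mean_s) +
    stats::runif(n, offset_range_s[1L], offset_range_s[2L])
  isi <- pmin(isi, cap_s)
  if (round_isi) isi <- round(isi)
  isi
}

#' Draw a full-task schedule
#'
#' The tactile and visual streams are drawn independently from the same
#' ISI distribution (see [draw_full_isis()]); stimuli of different
#' modalities may overlap, and only the CS+ predicts reward timing.
#'
#' @inheritParams draw_shaping_schedule
#' @return A `stim_schedule` with `task_phase = "full"`.
#' @examples
#' sched <- draw_full_schedule(100, seed = 7)
#' summary(diff(sched$events$onset_s[sched$events$modality == "tactile"]))
#' @export
draw_full_schedule <- function(n_per_modality, seed = NULL,
                               cs_plus = c("tactile", "visual")) {
  if (!is.numeric(n_per_modality) || length(n_per_modality) != 1L ||
      !is.finite(n_per_modality) || n_per_modality < 1) {
    stop("`n_per_modality` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n_per_modality)
  cs_plus <- match.arg(cs_plus)
  with_seed(seed, {
    onsets_t <- cumsum(draw_full_isis(n))
    onsets_v <- cumsum(draw_full_isis(n))
    ev <- rbind(
      make_events(onsets_t, rep("tactile", n), cs_plus),
      make_events(onsets_v, rep("visual", n), cs_plus)
    )
    stim_schedule(ev, task_phase = "full", cs_plus = cs_plus, seed = seed)
  })
}

#' Per-modality inter-stimulus intervals of a schedule
#' @param schedule A `stim_schedule`.
#' @return Named list with numeric ISI vectors `tactile` and `visual`.
#' @export
schedule_isis <- function(schedule) {
  ev <- schedule$events
  lapply(
    stats::setNames(nm = c("tactile", "visual")),
    function(m) diff(ev$onset_s[ev$modality == m])
  )
}

#' Empirical hazard rate of inter-stimulus intervals
#'
#' For each bin, the hazard is the probability that the next stimulus occurs
#' in that bin given that it has not occurred yet:
#' `hazard = (# ISIs ending in bin) / (# ISIs >= bin start)`.
#' Bins with no surviving intervals are reported as `NA` (undefined), never
#' zero-filled.
#'
#' @param isis Numeric vector of inter-stimulus intervals, in seconds.
#' @param bin_width_s Bin width, in seconds (default 1).
#' @return A data frame of class `hazard_curve` with columns `bin_start`,
#'   `bin_end`, `n_end`, `n_risk`, `hazard`.
#' @examples
#' hz <- hazard_rate(draw_full_isis(10000), 1)
#' @export
hazard_rate <- function(isis, bin_width_s = 1) {
  if (length(isis) == 0L) {
    stop("`isis` must be non-empty", call. = FALSE)
  }
  stopifnot(bin_width_s > 0, all(is.finite(isis)), all(isis >= 0))
  edges <- seq(0, (floor(max(isis) / bin_width_s) + 1L) * bin_width_s,
    by = bin_width_s
  )
  starts <- edges[-length(edges)]
  # ISI "ends in bin" [start, start + w); survivors are ISIs >= bin start
  n_end <- vapply(
    starts,
    function(s) sum(isis >= s & isis < s + bin_width_s), numeric(1)
  )
  n_risk <- vapply(starts, function(s) sum(isis >= s), numeric(1))
  hz <- ifelse(n_risk > 0, n_end / n_risk, NA_real_)
  out <- data.frame(
    bin_start = starts, bin_end = starts + bin_width_s,
    n_end = n_end, n_risk = n_risk, hazard = hz
  )
  class(out) <- c("hazard_curve", class(out))
  out
}

#' Write a schedule to TSV
#'
#' Columns: `onset_s`, `duration_s`, `modality`, `rewarded`,
#' `reward_time_s`; metadata (`task_phase`, `cs_plus`, `session_length_s`,
#' `seed`) carried as comment header lines.
#'
#' @param schedule A `stim_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stim_schedule"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# task_phase: %s", schedule$task_phase), con)
  writeLines(sprintf("# cs_plus: %s", schedule$cs_plus), con)
  writeLines(sprintf("# session_length_s: %.10g", schedule$session_length_s), con)
  writeLines(sprintf("# seed: %s",
                     if (is.null(schedule$seed)) "NA" else schedule$seed), con)
  utils::write.table(schedule$events, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a schedule written by [write_schedule_tsv()]
#' @param path File path.
#' @return A `stim_schedule`.
#' @export
read_schedule_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  meta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    sub(paste0("# ", key, ": "), "", ln[1L])
  }
  ev <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  seed <- meta("seed")
  stim_schedule(
    ev,
    task_phase = meta("task_phase"),
    cs_plus = meta("cs_plus"),
    seed = if (identical(seed, "NA")) NULL else as.numeric(seed),
    session_length_s = as.numeric(meta("session_length_s"))
  )
}
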