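# Single-unit quality control and anatomical assignment: refractory-period
# violation screening (multi-unit contamination), region assignment in a
# synthetic box atlas with 50-um border exclusion, and spontaneous-rate
# estimation over quiet epochs (no licks, stimuli, or rewards).

#' Refractory-period violation fraction
#'
#' Fraction of inter-spike intervals shorter than the refractory bound
#' (3 ms). Units with more than 10% violations are treated as multi-unit
#' contamination and fail QC; exactly 10% passes.
#'
#' @param spike_times Sorted numeric vector of spike times, seconds.
#' @param refractory_s Refractory bound (default 0.003 s).
#' @param max_fraction QC threshold (default 0.10; fail when strictly above).
#' @return List: `fraction` (`NA` with < 2 spikes), `n_isi`, `qc_pass`.
#' @examples
#' refractory_violation_fraction(c(0, 0.001, 0.002, 0.003))
#' @export
refractory_violation_fraction <- function(spike_times, refractory_s = 0.003,
                                          max_fraction = 0.10) {
  if (length(spike_times) < 2L) {
    return(list(fraction = NA_real_, n_isi = 0L, qc_pass = FALSE))
  }
  stopifnot(!is.unsorted(spike_times))
  isis <- diff(spike_times)
  frac <- mean(isis < refractory_s)
  list(
    fraction = frac, n_isi = length(isis),
    qc_pass = frac <= max_fraction
  )
}

#' Synthetic box atlas for POm, LP and VPM
#'
#' Axis-aligned bounding boxes in stereotaxic-style coordinates
#' (AP mm from bregma, DV mm below the surface, ML mm from the midline),
#' sized to the secondary somatosensory (POm) and visual (LP) thalamic
#' nuclei and the neighbouring primary nucleus VPM. These boxes stand in
#' for atlas meshes; real-atlas registration is out of scope.
#'
#' @return Named list of regions, each `list(ap = c(lo, hi), dv = ..., ml = ...)`.
#' @export
default_region_geometry <- function() {
  list(
    POm = list(ap = c(-2.5, -1.5), dv = c(2.8, 3.6), ml = c(1.0, 1.8)),
    LP = list(ap = c(-2.5, -1.5), dv = c(2.0, 2.8), ml = c(1.2, 2.0)),
    VPM = list(ap = c(-2.3, -1.5), dv = c(3.0, 4.0), ml = c(1.8, 2.6))
  )
}

#' Assign a recording position to a region with border exclusion
#'
#' The region is the first geometry box containing the position; the border
#' distance is the distance to the nearest face of that box. Units closer
#' than the border threshold (50 um) are labeled `"border"` and excluded
#' from region analyses; positions outside all boxes are `"other"`.
#'
#' @param position Numeric length-3 vector `(AP, DV, ML)` in mm.
#' @param geometry Region geometry, default [default_region_geometry()].
#' @param border_mm Exclusion distance from any region face (default 0.05).
#' @return List: `region` (containing box or `"other"`), `border_distance_mm`
#'   (`NA` outside all boxes), `included`, `assigned` (`region` or
#'   `"border"` when excluded).
#' @export
assign_region <- function(position, geometry = default_region_geometry(),
                          border_mm = 0.05) {
  stopifnot(is.numeric(position), length(position) == 3L)
  ap <- position[1L]; dv <- position[2L]; ml <- position[3L]
  for (nm in names(geometry)) {
    g <- geometry[[nm]]
    if (ap >= g$ap[1L] && ap <= g$ap[2L] &&
        dv >= g$dv[1L] && dv <= g$dv[2L] &&
        ml >= g$ml[1L] && ml <= g$ml[2L]) {
      d <- min(
        ap - g$ap[1L], g$ap[2L] - ap,
        dv - g$dv[1L], g$dv[2L] - dv,
        ml - g$ml[1L], g$ml[2L] - ml
      )
      inc <- d >= border_mm
      return(list(
        region = nm, border_distance_mm = d, included = inc,
        assigned = if (inc) nm else "border"
      ))
    }
  }
  list(
    region = "other", border_distance_mm = NA_real_,
    included = FALSE, assigned = "other"
  )
}

#' Quiet epochs of a session
#'
#' Maximal intervals that contain no licks, stimuli (for their full
#' duration), or rewards, start at least `pre_gap_s` after the end of any
#' such event, and last at least `min_length_s`.
#'
#' @param lick_times,reward_times Numeric event-time vectors, seconds.
#' @param stim_intervals 2-column matrix of stimulus (onset, offset) pairs.
#' @param session_length_s Session length, seconds.
#' @param pre_gap_s Required gap after any event (default 2 s).
#' @param min_length_s Minimum epoch length (default 6 s).
#' @return 2-column matrix of qualifying (start, end) epochs (may be empty).
#' @export
quiet_epochs <- function(lick_times, reward_times, stim_intervals,
                         session_length_s, pre_gap_s = 2, min_length_s = 6) {
  pts <- c(lick_times, reward_times)
  ivals <- rbind(
    if (length(pts)) cbind(pts, pts) else NULL,
    stim_intervals
  )
  if (is.null(ivals) || nrow(ivals) == 0L) {
    excl <- matrix(numeric(0), ncol = 2L)
  } else {
    # exclusion zone: the event itself plus the following pre_gap_s
    excl <- merge_intervals(cbind(ivals[, 1L], ivals[, 2L] + pre_gap_s))
  }
  free <- complement_intervals(excl, 0, session_length_s)
  free[free[, 2L] - free[, 1L] >= min_length_s, , drop = FALSE]
}

#' Spontaneous firing rate over quiet epochs
#'
#' Total spike count within qualifying quiet epochs (see [quiet_epochs()])
#' divided by their total duration; `NA` when no epoch qualifies.
#'
#' @param spike_times Sorted spike times, seconds.
#' @inheritParams quiet_epochs
#' @return List: `rate_hz` (`NA` if undefined), `n_epochs`,
#'   `total_quiet_s`, `epochs` (matrix).
#' @export
spontaneous_rate <- function(spike_times, lick_times, reward_times,
                             stim_intervals, session_length_s,
                             pre_gap_s = 2, min_length_s = 6) {
  ep <- quiet_epochs(
    lick_times, reward_times, stim_intervals,
    session_length_s, pre_gap_s, min_length_s
  )
  if (nrow(ep) == 0L) {
    return(list(
      rate_hz = NA_real_, n_epochs = 0L, total_quiet_s = 0,
      epochs = ep
    ))
  }
  n <- sum(count_in_windows(spike_times, ep[, 1L], ep[, 2L]))
  tot <- sum(ep[, 2L] - ep[, 1L])
  list(rate_hz = n / tot, n_epochs = nrow(ep), total_quiet_s = tot, epochs = ep)
}

#' Run quality control on all units of a session
#'
#' @param session A synthetic or loaded session (see [simulate_population()]).
#' @param geometry Region geometry (default [default_region_geometry()]).
#' @param border_mm Border exclusion threshold in mm (default 0.05).
#' @return Data frame with one row per unit: `unit_id`, `n_spikes`,
#'   `violation_fraction`, `qc_pass`, `region`, `border_distance_mm`,
#'   `included`, `spontaneous_rate_hz`.
#' @export
unit_qc_table <- function(session, geometry = default_region_geometry(),
                          border_mm = 0.05) {
  ev <- session$schedule$events
  stim_iv <- cbind(ev$onset_s, ev$onset_s + ev$duration_s)
  rew <- reward_times(session$schedule)
  rows <- lapply(seq_len(nrow(session$units)), function(i) {
    u <- session$units[i, ]
    st <- session$spikes[[u$unit_id]]
    rv <- refractory_violation_fraction(st)
    reg <- assign_region(c(u$ap_mm, u$dv_mm, u$ml_mm), geometry, border_mm)
    sp <- spontaneous_rate(
      st, session$lick_times, rew, stim_iv,
      session$schedule$session_length_s
    )
    data.frame(
      unit_id = u$unit_id, n_spikes = length(st),
      violation_fraction = rv$fraction, qc_pass = rv$qc_pass,
      region = reg$assigned, border_distance_mm = reg$border_distance_mm,
      included = reg$included && rv$qc_pass,
      spontaneous_rate_hz = sp$rate_hz
    )
  })
  do.call(rbind, rows)
}
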