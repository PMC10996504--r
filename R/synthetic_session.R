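# Synthetic conditioning sessions with recorded ground truth. Spikes are an
# inhomogeneous Poisson process generated by thinning (Lewis-Shedler) on a
# 1-ms grid: rate = baseline x stimulus gain, plus linear coupling to
# z-scored arousal/movement signals (pupil radius lagged 1 s, whisking
# amplitude, lick intensity), floored at zero. Licking, pupil and whisking
# dynamics emulate the structure the analyses assume: anticipatory licking
# to the CS+, consumption bursts after reward, pupil dilation to the air
# puff (and to the grating in trained visual-cohort animals), transient
# constriction at grating onset, and air-puff-evoked whisking.

#' Behavior-generator parameters
#'
#' Defaults are chosen as plausible head-fixed mouse values; lick-rate
#' magnitudes are free parameters of the simulator, not literature values.
#'
#' @param lick_base_hz Baseline lick rate (Hz).
#' @param lick_antic_hz Anticipatory lick rate during the CS+ (Hz).
#' @param lick_consum_hz Consumption lick rate for 2 s after reward (Hz).
#' @param lick_suppress Multiplicative suppression of licking during the
#'   CS- for non-naive animals on correlated (shaping) schedules.
#' @param pupil_base Baseline pupil radius (arbitrary units).
#' @param pupil_drift_sd Stationary SD of the slow AR(1) pupil drift.
#' @param pupil_drift_tau_s Time constant of the drift (s).
#' @param puff_dilation,reward_dilation,grating_dilation Kernel amplitudes.
#' @param grating_constrict Amplitude of the onset constriction (negative).
#' @param whisk_mean_deg Mean whisker angle (degrees).
#' @param whisk_base_amp_deg Baseline peak-to-trough whisk amplitude.
#' @param whisk_puff_amp_deg Added amplitude at air-puff onset.
#' @param whisk_spont_sd_deg SD of spontaneous (stimulus-independent)
#'   amplitude fluctuations; this variance is what identifies movement
#'   coefficients in the regression stage.
#' @param whisk_spont_tau_s Time constant of those fluctuations (s).
#' @param whisk_freq_hz Whisk carrier frequency.
#' @param whisk_noise_sd Additive angle noise SD (degrees).
#' @return Named list of parameters.
#' @export
behavior_params <- function(lick_base_hz = 0.2, lick_antic_hz = 4,
                            lick_consum_hz = 7, lick_suppress = 0.15,
                            pupil_base = 1, pupil_drift_sd = 0.05,
                            pupil_drift_tau_s = 20,
                            puff_dilation = 0.25, reward_dilation = 0.2,
                            grating_dilation = 0.2,
                            grating_constrict = -0.08,
                            whisk_mean_deg = 60, whisk_base_amp_deg = 6,
                            whisk_puff_amp_deg = 14,
                            whisk_spont_sd_deg = 3, whisk_spont_tau_s = 1,
                            whisk_freq_hz = 8, whisk_noise_sd = 0.5) {
  as.list(environment())
}

# alpha-function kernel peaking at 1 after tau seconds
alpha_kernel <- function(tau_s, dur_s, rate_hz) {
  t <- seq(0, dur_s, by = 1 / rate_hz)
  (t / tau_s) * exp(1 - t / tau_s)
}

# add `kernel * amp` to `values` starting at each time in `t0s`
add_kernels <- function(values, rate_hz, t0s, kernel, amp) {
  n <- length(values)
  for (t0 in t0s) {
    i0 <- floor(t0 * rate_hz) + 1L
    idx <- i0:min(n, i0 + length(kernel) - 1L)
    if (idx[1L] > n) next
    values[idx] <- values[idx] + amp * kernel[seq_along(idx)]
  }
  values
}

ar1_drift <- function(n, sd, tau_s, rate_hz) {
  phi <- exp(-1 / (tau_s * rate_hz))
  as.numeric(stats::filter(
    stats::rnorm(n, sd = sd * sqrt(1 - phi^2)),
    phi,
    method = "recursive"
  ))
}

# thinning sampler for a piecewise-constant rate on a dt grid over [0, L)
thin_poisson <- function(rate, dt, session_length_s) {
  rmax <- max(rate)
  if (rmax <= 0) {
    return(numeric(0))
  }
  n_cand <- stats::rpois(1L, rmax * session_length_s)
  if (n_cand == 0L) {
    return(numeric(0))
  }
  tc <- sort(stats::runif(n_cand, 0, session_length_s))
  idx <- pmin(floor(tc / dt) + 1L, length(rate))
  tc[stats::runif(n_cand) < rate[idx] / rmax]
}

#' Simulate licking, pupil and whisking for a session
#'
#' @param schedule A [stim_schedule()].
#' @param cohort Conditioning cohort (which modality is rewarded); defaults
#'   to the schedule's CS+.
#' @param learning_state `"naive"` (licking independent of stimuli),
#'   `"shaped"` or `"trained"` (anticipatory licking to the CS+; on
#'   correlated shaping schedules non-naive visual-cohort animals also
#'   suppress licking during the air puff).
#' @param seed Integer seed (optional).
#' @param params [behavior_params()].
#' @return An object of class `synth_behavior`: `lick_times`, `pupil`
#'   (60 Hz [fr_trace()]), `whisker` (125 Hz angle trace), plus generator
#'   ground truth `amp_true` (whisk amplitude) and `lick_intensity`.
#' @export
simulate_behavior <- function(schedule, cohort = schedule$cs_plus,
                              learning_state = c("trained", "shaped", "naive"),
                              seed = NULL, params = behavior_params()) {
  stopifnot(inherits(schedule, "stim_schedule"))
  cohort <- match.arg(cohort, c("tactile", "visual"))
  learning_state <- match.arg(learning_state)
  p <- params
  L <- schedule$session_length_s
  ev <- schedule$events
  rew <- reward_times(schedule)
  cs_on <- ev$onset_s[ev$modality == cohort]
  cs_dur <- ev$duration_s[ev$modality == cohort]
  puff_on <- ev$onset_s[ev$modality == "tactile"]
  grat_on <- ev$onset_s[ev$modality == "visual"]

  with_seed(seed, {
    # --- lick intensity (100 Hz grid) and lick times ---
    lr <- 100
    nl <- ceiling(L * lr)
    tl <- (seq_len(nl) - 1L) / lr
    lam <- rep(p$lick_base_hz, nl)
    if (learning_state != "naive") {
      for (i in seq_along(cs_on)) {
        lam[tl > cs_on[i] & tl <= cs_on[i] + cs_dur[i]] <- p$lick_antic_hz
      }
    }
    for (r in rew) {
      lam[tl > r & tl <= r + 2] <- p$lick_consum_hz
    }
    if (learning_state != "naive" && cohort == "visual" &&
        schedule$task_phase == "shaping") {
      for (t0 in puff_on) {
        sel <- tl > t0 & tl <= t0 + 2
        lam[sel] <- lam[sel] * p$lick_suppress
      }
    }
    lick_times <- thin_poisson(lam, 1 / lr, L)

    # --- pupil radius (60 Hz) ---
    pr <- 60
    np <- ceiling(L * pr)
    pupil <- p$pupil_base +
      ar1_drift(np, p$pupil_drift_sd, p$pupil_drift_tau_s, pr)
    pupil <- add_kernels(pupil, pr, puff_on, alpha_kernel(1, 5, pr),
                         p$puff_dilation)
    pupil <- add_kernels(pupil, pr, grat_on, alpha_kernel(0.4, 2, pr),
                         p$grating_constrict)
    pupil <- add_kernels(pupil, pr, rew, alpha_kernel(1.2, 5, pr),
                         p$reward_dilation)
    if (learning_state == "trained" && cohort == "visual") {
      pupil <- add_kernels(pupil, pr, grat_on, alpha_kernel(1, 5, pr),
                           p$grating_dilation)
    }
    pupil <- pmax(pupil, 0.05)

    # --- whisker angle (125 Hz): amplitude-modulated whisk-band carrier ---
    wr <- 125
    nw <- ceiling(L * wr)
    amp <- p$whisk_base_amp_deg +
      ar1_drift(nw, p$whisk_spont_sd_deg, p$whisk_spont_tau_s, wr)
    amp <- add_kernels(amp, wr, puff_on, alpha_kernel(0.5, 3, wr),
                       p$whisk_puff_amp_deg)
    amp <- pmax(amp, 0.5)
    freq <- p$whisk_freq_hz + ar1_drift(nw, 1, 2, wr)
    phase <- cumsum(2 * pi * freq / wr)
    angle <- p$whisk_mean_deg + (amp / 2) * sin(phase) +
      stats::rnorm(nw, sd = p$whisk_noise_sd)

    structure(
      list(
        lick_times = lick_times,
        pupil = fr_trace(pupil, pr, 0),
        whisker = fr_trace(angle, wr, 0),
        amp_true = fr_trace(amp, wr, 0),
        lick_intensity = fr_trace(lam, lr, 0),
        cohort = cohort, learning_state = learning_state, params = p
      ),
      class = "synth_behavior"
    )
  })
}

#' Ground-truth parameters of one simulated unit
#'
#' @param unit_id Unit identifier.
#' @param baseline_hz Baseline firing rate (> 0).
#' @param region Region label (`"POm"`, `"LP"`, `"VPM"`, `"other"`).
#' @param ap_mm,dv_mm,ml_mm Anatomical position, mm.
#' @param gain_tactile,gain_visual Multiplicative rate gains during the
#'   stimulus-response window of each modality (>= 0; 1 = no response).
#' @param latency_s Response latency after stimulus onset (>= 0).
#' @param response_dur_s Duration of the gain window.
#' @param offset_gain Multiplicative gain for 2 s after CS+ offset.
#' @param c_pupil,c_whisk,c_lick Coupling weights, Hz per SD of the signal.
#' @param pupil_lag_s Lag applied to pupil before coupling (default 1 s).
#' @param dead_time_s Optional absolute refractory period injected after
#'   each spike (default 0; used to exercise the QC filter).
#' @return Named list of validated parameters.
#' @export
unit_truth <- function(unit_id, baseline_hz = 10, region = "POm",
                       ap_mm = -2, dv_mm = 3.2, ml_mm = 1.4,
                       gain_tactile = 1, gain_visual = 1,
                       latency_s = 0.05, response_dur_s = 1.5,
                       offset_gain = 1, c_pupil = 0, c_whisk = 0,
                       c_lick = 0, pupil_lag_s = 1, dead_time_s = 0) {
  stopifnot(
    baseline_hz > 0, gain_tactile >= 0, gain_visual >= 0,
    latency_s >= 0, response_dur_s > 0, offset_gain >= 0
  )
  as.list(environment())
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson by thinning at 1-ms resolution. The rate is
#' `baseline * gain(t) + c_pupil * z(pupil(t - lag)) + c_whisk * z(amp(t))
#' + c_lick * z(lick_intensity(t))`, floored at zero (with a warning when
#' flooring occurs). `gain(t)` multiplies in the modality gain from
#' stimulus onset + latency for `response_dur_s`, and `offset_gain` for
#' 2 s after CS+ offset.
#'
#' @param schedule A [stim_schedule()].
#' @param truth A [unit_truth()].
#' @param behavior A [simulate_behavior()] result (may be `NULL` when all
#'   coupling weights are zero).
#' @param seed Integer seed (optional).
#' @param dt Rate-grid resolution, seconds (default 0.001).
#' @param return_rate Attach the rate function as attribute `"rate"`.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
simulate_spikes <- function(schedule, truth, behavior = NULL, seed = NULL,
                            dt = 0.001, return_rate = FALSE) {
  stopifnot(inherits(schedule, "stim_schedule"))
  L <- schedule$session_length_s
  coupled <- any(c(truth$c_pupil, truth$c_whisk, truth$c_lick) != 0)
  if (coupled && is.null(behavior)) {
    stop("`behavior` is required when coupling weights are non-zero",
      call. = FALSE
    )
  }
  ev <- schedule$events
  modulated <- truth$gain_tactile != 1 || truth$gain_visual != 1 ||
    truth$offset_gain != 1

  with_seed(seed, {
    if (!coupled && !modulated) {
      # homogeneous special case: no need to materialize the rate grid
      n <- stats::rpois(1L, truth$baseline_hz * L)
      spikes <- sort(stats::runif(n, 0, L))
      rate <- NULL
      if (return_rate) {
        rate <- fr_trace(rep(truth$baseline_hz, ceiling(L / dt)), 1 / dt, 0)
      }
    } else {
      nb <- ceiling(L / dt)
      tg <- (seq_len(nb) - 1L) * dt
      g <- rep(1, nb)
      for (i in seq_len(nrow(ev))) {
        gm <- if (ev$modality[i] == "tactile") truth$gain_tactile else truth$gain_visual
        if (gm != 1) {
          a <- ev$onset_s[i] + truth$latency_s
          sel <- tg > a & tg <= a + truth$response_dur_s
          g[sel] <- g[sel] * gm
        }
        if (ev$rewarded[i] && truth$offset_gain != 1) {
          off <- ev$onset_s[i] + ev$duration_s[i]
          sel <- tg > off & tg <= off + 2
          g[sel] <- g[sel] * truth$offset_gain
        }
      }
      r <- truth$baseline_hz * g
      if (coupled) {
        zscore <- function(v) {
          s <- stats::sd(v)
          if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
        }
        if (truth$c_pupil != 0) {
          pz <- zscore(trace_at(behavior$pupil, tg - truth$pupil_lag_s))
          r <- r + truth$c_pupil * pz
        }
        if (truth$c_whisk != 0) {
          wz <- zscore(trace_at(behavior$amp_true, tg))
          r <- r + truth$c_whisk * wz
        }
        if (truth$c_lick != 0) {
          lz <- zscore(trace_at(behavior$lick_intensity, tg))
          r <- r + truth$c_lick * lz
        }
      }
      if (any(r < 0)) {
        warning(sprintf(
          "unit %s: rate floored at 0 in %.2f%% of bins",
          truth$unit_id, 100 * mean(r < 0)
        ), call. = FALSE)
        r <- pmax(r, 0)
      }
      spikes <- sort(thin_poisson(r, dt, L))
      rate <- if (return_rate) fr_trace(r, 1 / dt, 0) else NULL
    }
    if (truth$dead_time_s > 0 && length(spikes) > 1L) {
      keep <- logical(length(spikes))
      keep[1L] <- TRUE
      last <- spikes[1L]
      for (i in 2L:length(spikes)) {
        if (spikes[i] - last >= truth$dead_time_s) {
          keep[i] <- TRUE
          last <- spikes[i]
        }
      }
      spikes <- spikes[keep]
    }
    if (return_rate) attr(spikes, "rate") <- rate
    spikes
  })
}

#' Population-generator parameters
#'
#' Baseline rates span 2-20 Hz with POm skewed higher than LP; gains span
#' 1.5-4; latencies 20-150 ms. In the visual cohort the tactile gain
#' increases with medial-lateral position at `ml_selectivity_slope`
#' (gain units per mm), emulating a laterally clustered touch-selective
#' subregion.
#'
#' @param p_pom Probability a unit is in POm (rest in LP).
#' @param baseline_range_pom,baseline_range_lp Baseline-rate ranges (Hz).
#' @param gain_range Range of the driven modality gain.
#' @param latency_range Response-latency range (s).
#' @param response_dur_range Response-duration range (s).
#' @param offset_gain_range Offset-period gain range for CS+-modulated units.
#' @param p_offset_modulated Fraction of units with offset-period gain.
#' @param coupling_frac_range Movement-coupling weights as a fraction of
#'   the unit's baseline rate (Hz per SD of the signal = fraction x
#'   baseline); proportional modulation keeps rates positive.
#' @param ml_selectivity_slope Visual-cohort tactile-gain slope per ML mm.
#' @param ml_gain_noise_sd SD of unit-level noise around the ML gradient.
#' @param p_cross_modal Tactile-cohort fraction with a (weak) visual gain.
#' @param dead_time_s Injected absolute refractory period (default 0).
#' @return Named list of parameters.
#' @export
population_params <- function(p_pom = 0.7,
                              baseline_range_pom = c(2, 20),
                              baseline_range_lp = c(2, 12),
                              gain_range = c(1.5, 4),
                              latency_range = c(0.02, 0.15),
                              response_dur_range = c(0.8, 1.8),
                              offset_gain_range = c(1.5, 3),
                              p_offset_modulated = 0.6,
                              coupling_frac_range = c(0, 0.08),
                              ml_selectivity_slope = 2,
                              ml_gain_noise_sd = 0.2,
                              p_cross_modal = 0.1,
                              dead_time_s = 0) {
  as.list(environment())
}

#' Simulate a full synthetic session (schedule, behavior, population)
#'
#' @param n_units Number of units (>= 1).
#' @param cohort Conditioning cohort, `"tactile"` or `"visual"`.
#' @param n_per_modality Stimulus presentations per modality (default 60).
#' @param learning_state Behavioral state (default `"trained"`).
#' @param seed Integer seed.
#' @param params [population_params()].
#' @param behavior_par [behavior_params()].
#' @return An object of class `synth_session`: `schedule`, `behavior`,
#'   `lick_times`, `pupil`, `whisker`, `spikes` (named list of spike-time
#'   vectors), `units` (ground-truth data frame), `params`, `seed`.
#' @export
simulate_population <- function(n_units, cohort = c("tactile", "visual"),
                                n_per_modality = 60,
                                learning_state = "trained", seed = NULL,
                                params = population_params(),
                                behavior_par = behavior_params()) {
  if (!is.numeric(n_units) || length(n_units) != 1L || n_units < 1) {
    stop("`n_units` must be a positive count", call. = FALSE)
  }
  n_units <- as.integer(n_units)
  cohort <- match.arg(cohort)
  p <- params
  geom <- default_region_geometry()

  with_seed(seed, {
    schedule <- draw_full_schedule(n_per_modality, seed = NULL, cs_plus = cohort)
    behavior <- simulate_behavior(schedule,
      cohort = cohort,
      learning_state = learning_state, params = behavior_par
    )
    units <- lapply(seq_len(n_units), function(i) {
      region <- if (stats::runif(1) < p$p_pom) "POm" else "LP"
      g <- geom[[region]]
      pos <- c(
        stats::runif(1, g$ap[1L], g$ap[2L]),
        stats::runif(1, g$dv[1L], g$dv[2L]),
        stats::runif(1, g$ml[1L], g$ml[2L])
      )
      br <- if (region == "POm") p$baseline_range_pom else p$baseline_range_lp
      if (cohort == "tactile") {
        gain_t <- stats::runif(1, p$gain_range[1L], p$gain_range[2L])
        gain_v <- if (stats::runif(1) < p$p_cross_modal) {
          stats::runif(1, 1, 1.5)
        } else {
          1
        }
      } else {
        gain_v <- stats::runif(1, p$gain_range[1L], min(3, p$gain_range[2L]))
        ml_mid <- mean(g$ml)
        gain_t <- max(1, 1 + p$ml_selectivity_slope * (pos[3L] - ml_mid) +
          stats::rnorm(1, sd = p$ml_gain_noise_sd))
      }
      off_g <- if (stats::runif(1) < p$p_offset_modulated) {
        stats::runif(1, p$offset_gain_range[1L], p$offset_gain_range[2L])
      } else {
        1
      }
      base_hz <- stats::runif(1, br[1L], br[2L])
      cfr <- function() {
        base_hz *
          stats::runif(1, p$coupling_frac_range[1L], p$coupling_frac_range[2L])
      }
      unit_truth(
        unit_id = sprintf("u%03d", i),
        baseline_hz = base_hz,
        region = region, ap_mm = pos[1L], dv_mm = pos[2L], ml_mm = pos[3L],
        gain_tactile = gain_t, gain_visual = gain_v,
        latency_s = stats::runif(1, p$latency_range[1L], p$latency_range[2L]),
        response_dur_s = stats::runif(1, p$response_dur_range[1L],
                                      p$response_dur_range[2L]),
        offset_gain = off_g,
        c_pupil = cfr(), c_whisk = cfr(), c_lick = cfr(),
        dead_time_s = p$dead_time_s
      )
    })
    spikes <- lapply(units, function(u) {
      simulate_spikes(schedule, u, behavior)
    })
    names(spikes) <- vapply(units, `[[`, character(1), "unit_id")
    units_df <- do.call(rbind, lapply(units, function(u) {
      as.data.frame(u, stringsAsFactors = FALSE)
    }))
    structure(
      list(
        schedule = schedule, behavior = behavior,
        lick_times = behavior$lick_times, pupil = behavior$pupil,
        whisker = behavior$whisker, spikes = spikes, units = units_df,
        cohort = cohort, learning_state = learning_state,
        params = p, seed = seed
      ),
      class = "synth_session"
    )
  })
}

#' @export
print.synth_session <- function(x, ...) {
  cat(sprintf(
    "<synth_session> %s cohort (%s): %d units, %d stimuli, %.0f s, %d licks\n",
    x$cohort, x$learning_state, nrow(x$units), nrow(x$schedule$events),
    x$schedule$session_length_s, length(x$lick_times)
  ))
  invisible(x)
}

#' Write a session bundle to a directory
#'
#' Plain-text bundle: `schedule.tsv`, `spikes.tsv`, `units.tsv`,
#' `licks.tsv`, `pupil.csv`, `whisker.csv`, `truth.json`, `config.yaml`.
#'
#' @param session A `synth_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "synth_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_schedule_tsv(session$schedule, file.path(dir, "schedule.tsv"))
  spk <- data.frame(
    unit_id = rep(names(session$spikes), lengths(session$spikes)),
    time_s = sprintf("%.6f", unlist(session$spikes, use.names = FALSE))
  )
  utils::write.table(spk, file.path(dir, "spikes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(session$units, file.path(dir, "units.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    data.frame(time_s = sprintf("%.6f", session$lick_times)),
    file.path(dir, "licks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_trace_csv(session$pupil, file.path(dir, "pupil.csv"))
  write_trace_csv(session$whisker, file.path(dir, "whisker.csv"))
  jsonlite::write_json(
    list(
      cohort = session$cohort, learning_state = session$learning_state,
      seed = session$seed, units = session$units,
      behavior_params = session$behavior$params
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  yaml::write_yaml(
    list(
      cohort = session$cohort, learning_state = session$learning_state,
      seed = session$seed, population_params = session$params
    ),
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' Generator-internal signals (`amp_true`, `lick_intensity`) are not part
#' of the bundle; analyses recompute whisking amplitude from the angle
#' trace.
#'
#' @param dir Bundle directory.
#' @return A `synth_session` (without generator internals).
#' @export
read_session <- function(dir) {
  needed <- c(
    "schedule.tsv", "spikes.tsv", "units.tsv", "licks.tsv",
    "pupil.csv", "whisker.csv", "truth.json", "config.yaml"
  )
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing)) {
    stop(
      "session bundle incomplete; missing: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  schedule <- read_schedule_tsv(file.path(dir, "schedule.tsv"))
  spk <- utils::read.delim(file.path(dir, "spikes.tsv"),
    stringsAsFactors = FALSE
  )
  units <- utils::read.delim(file.path(dir, "units.tsv"),
    stringsAsFactors = FALSE
  )
  spikes <- lapply(
    stats::setNames(nm = units$unit_id),
    function(u) sort(spk$time_s[spk$unit_id == u])
  )
  licks <- utils::read.delim(file.path(dir, "licks.tsv"))$time_s
  if (is.null(licks)) licks <- numeric(0)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
    simplifyVector = TRUE
  )
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  structure(
    list(
      schedule = schedule,
      behavior = list(params = truth$behavior_params),
      lick_times = as.numeric(licks),
      pupil = read_trace_csv(file.path(dir, "pupil.csv")),
      whisker = read_trace_csv(file.path(dir, "whisker.csv")),
      spikes = spikes, units = units,
      cohort = truth$cohort, learning_state = truth$learning_state,
      params = cfg$population_params, seed = truth$seed
    ),
    class = "synth_session"
  )
}
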