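make_small_session <- function(seed = 81, n_units = 3, n_stim = 25,
                               units = NULL) {
  sched <- draw_full_schedule(n_stim, seed = seed)
  beh <- simulate_behavior(sched, seed = seed + 1)
  if (is.null(units)) {
    units <- lapply(seq_len(n_units), function(i) {
      unit_truth(sprintf("u%02d", i), baseline_hz = 8, c_whisk = 2,
                 c_pupil = 0.5)
    })
  }
  spikes <- lapply(units, function(u) {
    simulate_spikes(sched, u, beh, seed = seed + 10 + match(u$unit_id,
      vapply(units, `[[`, character(1), "unit_id")))
  })
  names(spikes) <- vapply(units, `[[`, character(1), "unit_id")
  structure(
    list(
      schedule = sched, behavior = beh, lick_times = beh$lick_times,
      pupil = beh$pupil, whisker = beh$whisker, spikes = spikes,
      units = data.frame(unit_id = names(spikes)), cohort = "tactile",
      learning_state = "trained"
    ),
    class = "synth_session"
  )
}

test_that("session binning converts counts and events to rates", {
  ses <- make_small_session()
  b <- bin_session(ses, bin_s = 0.25)
  L <- ses$schedule$session_length_s
  expect_equal(length(b$bin_start), floor(L / 0.25))
  # mean binned rate equals overall rate
  u <- names(ses$spikes)[1]
  n_in <- sum(ses$spikes[[u]] <= max(b$bin_start) + 0.25)
  expect_equal(mean(b$rates[u, ]), n_in / (length(b$bin_start) * 0.25),
    tolerance = 1e-6
  )
  # one lick alone in a bin contributes 4 licks/s at 0.25-s bins
  ses2 <- ses
  ses2$lick_times <- c(10.1)
  b2 <- bin_session(ses2, bin_s = 0.25)
  expect_equal(sort(unique(b2$lick_rate)), c(0, 4))
  # constant pupil stays constant
  ses2$pupil <- fr_trace(rep(2, 60 * ceiling(L)), 60)
  b3 <- bin_session(ses2, bin_s = 0.25)
  expect_true(all(abs(b3$pupil - 2) < 1e-9))
})

test_that("movement model recovers constructed coefficients", {
  ses <- make_small_session(seed = 82)
  b <- bin_session(ses)
  # construct a rate exactly linear in the predictors plus noise
  y <- 3 + 2 * b$whisk_amp + 0.5 * b$pupil +
    withr::with_seed(83, rnorm(length(b$bin_start), 0, 0.3))
  b$rates <- rbind(b$rates, synth = y)
  f <- fit_movement_model(b, "synth")
  expect_equal(unname(f$coefficients["whisk"]), 2, tolerance = 0.1)
  expect_equal(unname(f$coefficients["pupil"]), 0.5, tolerance = 0.3)
  expect_gt(f$r2, 0.9)
  # noiseless linear rate: residuals ~ 0 everywhere
  b$rates <- rbind(b$rates, exact = 3 + 2 * b$whisk_amp + 0.5 * b$pupil)
  fe <- fit_movement_model(b, "exact")
  expect_lt(max(abs(fe$residuals)), 1e-9)
  # residuals sum to ~0 and are orthogonal to every fitted predictor
  expect_lt(abs(sum(f$residuals)), 1e-6)
  for (p in list(b$whisk_amp, b$pupil, b$lick_rate)) {
    expect_lt(abs(sum(f$residuals * p)) / length(p), 1e-6)
  }
})

test_that("coupling-free units fit with near-zero slopes and R2", {
  units <- list(unit_truth("free", baseline_hz = 10))
  ses <- make_small_session(seed = 84, units = units)
  b <- bin_session(ses)
  f <- fit_movement_model(b, "free")
  expect_lt(f$r2, 0.05)
  # nesting: adding predictors never lowers R2 relative to a single one
  y <- b$rates["free", ]
  r2_single <- summary(lm(y ~ b$whisk_amp))$r.squared
  expect_gte(f$r2 + 1e-12, r2_single)
})

test_that("constant predictors are dropped, not fatal", {
  ses <- make_small_session(seed = 85)
  ses$lick_times <- numeric(0)
  b <- bin_session(ses)
  expect_message(
    f <- fit_movement_model(b, names(ses$spikes)[1]),
    "constant predictor"
  )
  expect_true(is.na(f$coefficients["lick"]))
})

test_that("residual PSTH distinguishes coupling from true gain", {
  units <- list(
    unit_truth("coup", baseline_hz = 8, c_whisk = 3),
    unit_truth("gain", baseline_hz = 8, gain_tactile = 2.5,
               response_dur_s = 1.5)
  )
  ses <- make_small_session(seed = 86, n_stim = 40, units = units)
  b <- bin_session(ses)
  effect <- function(unit) {
    f <- fit_movement_model(b, unit)
    ps <- residual_psth(f, ses$schedule, "tactile")
    stim <- ps$mean[ps$time_s >= 0 & ps$time_s < 1]
    base <- ps$mean[ps$time_s >= -1 & ps$time_s < 0]
    mean(stim) - mean(base)
  }
  raw_effect <- function(unit) {
    i <- match(unit, rownames(b$rates))
    onsets <- ses$schedule$events$onset_s[
      retained_presentations(ses$schedule) &
        ses$schedule$events$modality == "tactile"
    ]
    thalattn:::stim_effect(
      b$rates[i, ] - mean(b$rates[i, ]), b$bin_start, b$bin_s, onsets
    )
  }
  # the whisk-coupled unit responds to the puff in raw rates but its
  # residual response collapses; the gain unit keeps its response
  expect_gt(raw_effect("coup"), 2)
  expect_lt(abs(effect("coup")), 1)
  expect_gt(effect("gain"), 2)
  # zero-residual series yields a flat zero PSTH
  f <- fit_movement_model(b, "coup")
  f$residuals <- rep(0, length(f$residuals))
  ps0 <- residual_psth(f, ses$schedule, "tactile")
  expect_true(all(ps0$mean == 0))
})

test_that("cross-correlation sign convention and self-correlation", {
  ses <- make_small_session(seed = 87, n_stim = 40)
  b <- bin_session(ses, bin_s = 0.25)
  n <- length(b$bin_start)
  # rate = pupil delayed by 1 s: activity follows pupil, peak at +1 s
  shift <- 4 # bins
  y <- c(rep(b$pupil[1], shift), b$pupil[1:(n - shift)])
  b$rates <- rbind(b$rates, lagged = y)
  xc <- firing_behavior_xcorr(b, "lagged", "pupil", max_lag_s = 3)
  expect_equal(xc$lag_s[which.max(xc$r)], 1)
  # rate = -whisk: correlation -1 at lag 0
  b$rates <- rbind(b$rates, anti = -b$whisk_amp)
  xc2 <- firing_behavior_xcorr(b, "anti", "whisk", max_lag_s = 2)
  expect_equal(xc2$r[xc2$lag_s == 0], -1)
  # self-correlation structure: a series against itself peaks at lag 0 at 1
  b$rates <- rbind(b$rates, self = b$whisk_amp)
  xc3 <- firing_behavior_xcorr(b, "self", "whisk", max_lag_s = 2)
  expect_equal(xc3$r[xc3$lag_s == 0], 1)
  expect_equal(xc3$lag_s[which.max(xc3$r)], 0)
  # independent white series: correlations small
  b$rates <- rbind(b$rates, noise = withr::with_seed(88, rnorm(n)))
  xc4 <- firing_behavior_xcorr(b, "noise", "lick", max_lag_s = 2)
  expect_lt(max(abs(xc4$r)), 5 / sqrt(n))
})
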