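test_that("cross-modal overlap exclusion drops both members of close pairs", {
  ev <- data.frame(
    onset_s = c(100, 200, 103, 210),
    duration_s = 2,
    modality = c("tactile", "tactile", "visual", "visual"),
    rewarded = c(TRUE, TRUE, FALSE, FALSE),
    reward_time_s = c(102, 202, NA, NA)
  )
  s <- stim_schedule(ev, "full", "tactile")
  keep <- retained_presentations(s)
  kept <- s$events$onset_s[keep]
  # the 100/103 pair is excluded, the 200/210 pair retained
  expect_setequal(kept, c(200, 210))
})

test_that("a toy schedule with 4 collisions retains 12 presentations", {
  iso_t <- seq(500, 1000, by = 100) # 6 isolated tactile
  iso_v <- iso_t + 50 # 6 isolated visual
  col_t <- seq(1100, 1400, by = 100) # 4 colliding pairs
  col_v <- col_t + 3
  ev <- data.frame(
    onset_s = c(iso_t, col_t, iso_v, col_v),
    duration_s = 2,
    modality = rep(c("tactile", "visual"), each = 10),
    rewarded = FALSE, reward_time_s = NA_real_
  )
  s <- stim_schedule(ev, "full", "tactile")
  w <- build_trial_windows(numeric(0), s)
  expect_equal(nrow(w), 12)
  expect_equal(sum(w$modality == "tactile"), 6)
})

test_that("retention matches a brute-force double loop over pairs", {
  for (seed in 41:45) {
    s <- draw_full_schedule(15, seed = seed)
    ev <- s$events
    brute <- vapply(seq_len(nrow(ev)), function(i) {
      others <- ev$onset_s[ev$modality != ev$modality[i]]
      all(abs(others - ev$onset_s[i]) > 6)
    }, logical(1))
    expect_identical(retained_presentations(s), brute)
  }
})

test_that("trial windows count spikes in the stated windows", {
  s <- toy_schedule(n = 3)
  on <- s$events$onset_s[1] # tactile at 100
  spikes <- sort(c(
    on - 0.5, on - 0.03, # baseline window + ambiguous band
    on + 0.02, on + 0.5, on + 0.9, # ambiguous + stimulus window
    on + 2.5, on + 3.9 # offset window
  ))
  w <- build_trial_windows(spikes, s)
  r <- w[w$stim_id == 1, ]
  expect_equal(r$baseline_count, 1) # ambiguous spike excluded
  expect_equal(r$stimulus_count, 2)
  expect_equal(r$offset_count, 2)
  expect_equal(r$baseline_rate, 1 / 0.95)
})

test_that("selectivity index reproduces the worked examples and properties", {
  expect_equal(selectivity_index(2, 10, 2), 1)
  expect_equal(selectivity_index(2, 6, 6), 0)
  expect_equal(selectivity_index(2, 2, 10), -1)
  # undefined when both deviations vanish: explicit NA, never 0
  expect_true(is.na(selectivity_index(5, 5, 5)))
  withr::with_seed(42, {
    for (i in 1:25) {
      fr <- runif(3, 0, 30)
      si <- selectivity_index(fr[1], fr[2], fr[3])
      # antisymmetric under exchanging the two stimulus rates
      expect_equal(si, -selectivity_index(fr[1], fr[3], fr[2]))
      # invariant to common positive rescaling
      k <- runif(1, 0.1, 10)
      expect_equal(si, selectivity_index(k * fr[1], k * fr[2], k * fr[3]))
    }
  })
})

test_that("classification labels match injected gains", {
  sched <- draw_full_schedule(100, seed = 43)
  mk <- function(id, gt, gv) {
    tr <- unit_truth(id, baseline_hz = 8, gain_tactile = gt, gain_visual = gv,
                     latency_s = 0.05, response_dur_s = 1.5)
    build_trial_windows(simulate_spikes(sched, tr, seed = 44 + gt + gv), sched)
  }
  windows <- list(
    puff = mk("puff", 3, 1),
    both = mk("both", 3, 3),
    flat = mk("flat", 1, 1)
  )
  res <- classify_responses(windows)
  expect_equal(res$label[res$unit_id == "puff"], "puff")
  expect_gt(res$si[res$unit_id == "puff"], 0.8)
  expect_equal(res$label[res$unit_id == "both"], "both")
  expect_lt(abs(res$si[res$unit_id == "both"]), 0.35)
  expect_false(res$corrected_significant[res$unit_id == "flat"])
  expect_true(is.na(res$si[res$unit_id == "flat"]))
})

test_that("degenerate units are marked untestable", {
  s <- toy_schedule(n = 5)
  res <- classify_responses(list(dead = build_trial_windows(numeric(0), s)))
  expect_true(res$untestable)
  expect_true(is.na(res$label))
})

test_that("latency detection needs two consecutive out-of-band bins", {
  # trial-averaged rate vector: 100 baseline bins then post-onset bins
  base <- rep(10, 100)
  post <- rep(10, 60)
  noise <- withr::with_seed(45, rnorm(100, 0, 0.5))
  lat <- thalattn:::latency_from_binned(c(base + noise, post), 0.01, 100)
  expect_true(is.na(lat))
  # a step at 120 ms crossing the band in bins 13, 14, ...
  post2 <- post
  post2[13:20] <- 30
  lat <- thalattn:::latency_from_binned(c(base + noise, post2), 0.01, 100)
  expect_equal(lat, 0.12)
  # a single 10-ms transient is rejected (run length 1 < 2)
  post3 <- post
  post3[13] <- 30
  lat <- thalattn:::latency_from_binned(c(base + noise, post3), 0.01, 100)
  expect_true(is.na(lat))
  # invariance to adding a constant rate: baseline and threshold co-shift
  lat0 <- thalattn:::latency_from_binned(c(base + noise, post2), 0.01, 100)
  lat7 <- thalattn:::latency_from_binned(c(base + noise, post2) + 7, 0.01, 100)
  expect_equal(lat0, lat7)
  # decreases count too (two-sided criterion)
  post4 <- post
  post4[6:12] <- 0
  noise_lo <- withr::with_seed(46, rnorm(100, 0, 0.3))
  lat <- thalattn:::latency_from_binned(c(base + noise_lo, post4), 0.01, 100)
  expect_equal(lat, 0.05)
})

test_that("latency recovery on simulated spike trains", {
  sched <- draw_full_schedule(100, seed = 47)
  tr <- unit_truth("u", baseline_hz = 10, gain_tactile = 4,
                   latency_s = 0.12, response_dur_s = 0.6)
  st <- simulate_spikes(sched, tr, seed = 48)
  lat <- response_latency(st, sched, "tactile")
  expect_equal(lat, 0.12, tolerance = 0.1) # within one 10-ms bin
  # flat unit returns NA
  flat <- simulate_spikes(sched, unit_truth("f", baseline_hz = 10), seed = 49)
  expect_true(is.na(response_latency(flat, sched, "tactile")))
})

test_that("offset-period analysis separates CS+ offset activity", {
  sched <- draw_full_schedule(60, seed = 50, cs_plus = "tactile")
  mk <- function(id, off_gain, seed) {
    tr <- unit_truth(id, baseline_hz = 10, offset_gain = off_gain)
    build_trial_windows(simulate_spikes(sched, tr, seed = seed), sched)
  }
  windows <- lapply(
    stats::setNames(nm = sprintf("u%02d", 1:12)),
    function(u) mk(u, 2.5, 50 + as.integer(substr(u, 2, 3)))
  )
  meta <- data.frame(unit_id = names(windows), cohort = "tactile")
  res <- offset_period_analysis(windows, meta)
  w <- res$wilcoxon
  p_off <- w$p[w$period == "offset"]
  expect_lt(p_off, 0.05)
  expect_gt(w$median_diff[w$period == "offset"], 0)
  # single-cohort input: within-cohort results only
  expect_null(res$anova)

  # two identical populations under different factor labels: interaction ns
  windows2 <- windows
  names(windows2) <- sprintf("v%02d", 1:12)
  meta2 <- rbind(meta, data.frame(unit_id = names(windows2), cohort = "visual"))
  res2 <- offset_period_analysis(c(windows, windows2), meta2)
  inter_p <- res2$anova$d_offset$p[res2$anova$d_offset$term == "interaction"]
  expect_gt(inter_p, 0.05)
})

test_that("position model recovers an injected ML x cohort interaction", {
  d <- withr::with_seed(51, thalattn:::simulate_si_population(300, ml_slope = 2))
  fit <- position_selectivity_model(d)
  inter <- fit$coefficients[grepl("ml_mm:", fit$coefficients$term), ]
  expect_gt(inter$estimate, 0)
  expect_lt(inter$p, 0.05)
  expect_gt(fit$adjusted_r2, 0.2)

  # degenerate positions are rejected
  d2 <- d
  d2$ml_mm <- 1.4
  d2$ap_mm <- -2
  d2$dv_mm <- 3.2
  expect_error(position_selectivity_model(d2), "rank deficient")
  # both cohorts required
  expect_error(
    position_selectivity_model(d[d$cohort == "visual", ]), "cohort"
  )
  expect_error(position_selectivity_model(d[1:5, ]), ">= 20")
})
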