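test_that("licks are detected at upward crossings with debounce", {
  # square pulses at 1, 2, 3 s
  v <- numeric(400)
  for (t0 in c(1, 2, 3)) v[(t0 * 100):(t0 * 100 + 5)] <- 1
  licks <- detect_licks(fr_trace(v, 100), threshold = 0.5)
  expect_equal(length(licks), 3)
  expect_equal(licks, c(1, 2, 3), tolerance = 0.02)

  expect_equal(detect_licks(fr_trace(rep(0.1, 100), 100), 0.5), numeric(0))

  # 8 Hz pulse train: 125-ms period exceeds the 50-ms debounce
  t <- seq(0, 2, by = 1 / 1000)
  v <- as.numeric((t %% 0.125) < 0.02)
  licks <- detect_licks(fr_trace(v, 1000), 0.5)
  expect_equal(length(licks), sum((t %% 0.125) < 1e-9))
})

test_that("lick index follows the count formula with onset exclusion", {
  # 4 stimulus licks, 0 baseline -> +1
  li <- lick_index(licks_for_counts(0, 4), onset_s = 10)
  expect_equal(li$li, 1)
  # 3 licks each window -> 0 (stimulus ignored)
  li <- lick_index(licks_for_counts(3, 3), onset_s = 10)
  expect_equal(li$li, 0)
  # 1 stimulus, 3 baseline -> -0.5
  li <- lick_index(licks_for_counts(3, 1), onset_s = 10)
  expect_equal(li$li, -0.5)
  # licks within +/-50 ms of onset excluded from both windows
  li <- lick_index(c(9.99, 10.01, 10.04, 11), onset_s = 10)
  expect_equal(li$licks_baseline, 0)
  expect_equal(li$licks_stimulus, 1)
  # no licks at all -> undefined, not zero
  li <- lick_index(numeric(0), onset_s = 10)
  expect_true(is.na(li$li))
})

test_that("lick index is antisymmetric and shift invariant", {
  withr::with_seed(21, {
    for (i in 1:50) {
      a <- sample(0:6, 1)
      b <- sample(0:6, 1)
      if (a + b == 0) next
      li_ab <- lick_index(licks_for_counts(a, b), onset_s = 10)$li
      li_ba <- lick_index(licks_for_counts(b, a), onset_s = 10)$li
      expect_equal(li_ab, -li_ba)
    }
  })
  # uniform time shift of session leaves LI unchanged
  lt <- licks_for_counts(2, 5, onset = 50)
  li0 <- lick_index(lt, onset_s = 50)$li
  li1 <- lick_index(lt + 123.4, onset_s = 50 + 123.4)$li
  expect_equal(li0, li1)
})

test_that("equal-rate Poisson licking gives mean LI near zero", {
  sched <- toy_schedule(n = 150)
  lt <- withr::with_seed(22, sort(runif(3000, 0, sched$session_length_s)))
  tab <- lick_index_table(lt, sched)
  m <- mean(tab$li, na.rm = TRUE)
  expect_lt(abs(m), 0.05)
})

test_that("session learning criteria follow the signed-rank rules", {
  # uniformly positive CS+ indices: advance criterion met after 3 days
  tab <- data.frame(modality = rep(c("tactile", "visual"), each = 40),
                    li = c(rep(0.8, 40), rnorm(40, 0, 0.05)))
  res <- session_learning_tests(tab, "tactile",
    n_shaping_sessions = 3, n_full_sessions = 4
  )
  expect_true(res$advance_to_full)
  expect_lt(res$p_cs_plus_gt0, 0.05)
  # symmetric CS- indices: complete criterion met
  expect_true(res$training_complete)
  expect_gt(res$p_cs_minus_ne0, 0.05)
  # day minimums gate the flags
  res2 <- session_learning_tests(tab, "tactile",
    n_shaping_sessions = 2, n_full_sessions = 2
  )
  expect_false(res2$advance_to_full)
  expect_false(res2$training_complete)
  # all-undefined LI: not evaluable, reported as such
  und <- data.frame(modality = c("tactile", "visual"), li = NA_real_)
  res3 <- session_learning_tests(und, "tactile")
  expect_false(res3$evaluable_cs_plus)
  expect_false(res3$advance_to_full)
})

test_that("simulated trained animals show CS+ anticipation, naive do not", {
  sched <- draw_full_schedule(60, seed = 23, cs_plus = "tactile")
  trained <- simulate_behavior(sched, learning_state = "trained", seed = 24)
  tab <- lick_index_table(trained$lick_times, sched)
  res <- session_learning_tests(tab, "tactile", n_shaping_sessions = 5)
  expect_gt(res$mean_li_cs_plus, 0.3)
  expect_true(res$advance_to_full)

  naive <- simulate_behavior(sched, learning_state = "naive", seed = 25)
  tabn <- lick_index_table(naive$lick_times, sched)
  mean_t <- mean(tabn$li[tabn$modality == "tactile"], na.rm = TRUE)
  expect_lt(abs(mean_t), 0.25)

  # visual cohort on a correlated shaping schedule withholds licks to the puff
  shap <- draw_shaping_schedule(80, seed = 26, cs_plus = "visual")
  vb <- simulate_behavior(shap, learning_state = "shaped", seed = 27)
  vt <- lick_index_table(vb$lick_times, shap)
  li_puff <- mean(vt$li[vt$modality == "tactile"], na.rm = TRUE)
  li_grat <- mean(vt$li[vt$modality == "visual"], na.rm = TRUE)
  expect_gt(li_grat, 0.3)
  expect_lt(li_puff, 0)
})
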