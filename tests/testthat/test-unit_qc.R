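test_that("refractory violation fraction and the 10% boundary", {
  # spikes at 0, 1, 2, 3 ms: every ISI violates
  r <- refractory_violation_fraction(c(0, 0.001, 0.002, 0.003))
  expect_equal(r$fraction, 1)
  expect_false(r$qc_pass)

  # regular 100-ms train: clean
  r <- refractory_violation_fraction(seq(0, 10, by = 0.1))
  expect_equal(r$fraction, 0)
  expect_true(r$qc_pass)

  # exactly 11/100 short ISIs: > 10%, excluded; 10/100 retained
  t11 <- c(0, cumsum(c(rep(0.002, 11), rep(0.1, 89))))
  t10 <- c(0, cumsum(c(rep(0.002, 10), rep(0.1, 90))))
  r11 <- refractory_violation_fraction(t11)
  r10 <- refractory_violation_fraction(t10)
  expect_equal(r11$fraction, 0.11)
  expect_false(r11$qc_pass)
  expect_equal(r10$fraction, 0.10)
  expect_true(r10$qc_pass)

  # < 2 spikes: undefined, fails QC
  r <- refractory_violation_fraction(1.5)
  expect_true(is.na(r$fraction))
  expect_false(r$qc_pass)
})

test_that("region assignment applies the 50-um border exclusion", {
  geom <- default_region_geometry()
  centroid <- c(mean(geom$POm$ap), mean(geom$POm$dv), mean(geom$POm$ml))
  a <- assign_region(centroid)
  expect_equal(a$region, "POm")
  expect_true(a$included)

  # 0.04 mm from the POm medial face: labeled border, excluded
  near <- c(centroid[1], centroid[2], geom$POm$ml[1] + 0.04)
  a <- assign_region(near)
  expect_equal(a$region, "POm")
  expect_equal(a$assigned, "border")
  expect_false(a$included)
  expect_equal(a$border_distance_mm, 0.04)

  # 0.06 mm inside LP: kept
  inside <- c(mean(geom$LP$ap), geom$LP$dv[1] + 0.06, mean(geom$LP$ml))
  a <- assign_region(inside)
  expect_equal(a$assigned, "LP")
  expect_true(a$included)

  # outside every box
  a <- assign_region(c(0, 0, 0))
  expect_equal(a$region, "other")
  expect_false(a$included)

  # shrinking the border threshold monotonically grows the included set
  pts <- withr::with_seed(31, {
    t(replicate(200, c(
      runif(1, geom$POm$ap[1], geom$POm$ap[2]),
      runif(1, geom$POm$dv[1], geom$POm$dv[2]),
      runif(1, geom$POm$ml[1], geom$POm$ml[2])
    )))
  })
  n_inc <- vapply(c(0.08, 0.05, 0.02, 0.005), function(b) {
    sum(apply(pts, 1, function(p) assign_region(p, border_mm = b)$included))
  }, numeric(1))
  expect_true(all(diff(n_inc) >= 0))
})

test_that("quiet epochs avoid events and their 2-s shadows", {
  licks <- c(10, 11, 40)
  rew <- 60
  stim <- rbind(c(20, 22), c(70, 72))
  ep <- quiet_epochs(licks, rew, stim, session_length_s = 100)
  expect_true(nrow(ep) >= 1)
  # no epoch intersects any event interval or the 2 s after it
  all_ev <- rbind(cbind(c(licks, rew), c(licks, rew)), stim)
  for (i in seq_len(nrow(ep))) {
    for (j in seq_len(nrow(all_ev))) {
      expect_true(ep[i, 2] <= all_ev[j, 1] || ep[i, 1] >= all_ev[j, 2] + 2)
    }
  }
  expect_true(all(ep[, 2] - ep[, 1] >= 6))

  # events covering the whole session: undefined rate
  sp <- spontaneous_rate(
    c(1, 2, 3), seq(0, 100, by = 1), numeric(0),
    matrix(numeric(0), ncol = 2), 100
  )
  expect_true(is.na(sp$rate_hz))

  # zero spikes but one qualifying epoch: rate 0, not NA
  sp <- spontaneous_rate(
    numeric(0), 5, numeric(0), matrix(numeric(0), ncol = 2), 100
  )
  expect_equal(sp$rate_hz, 0)
})

test_that("spontaneous rate is unbiased for homogeneous Poisson units", {
  # sparse events leave most of the session quiet
  licks <- seq(50, 500, by = 50)
  stim <- cbind(seq(100, 400, by = 100), seq(100, 400, by = 100) + 2)
  est <- withr::with_seed(32, {
    vapply(1:20, function(i) {
      st <- sort(runif(rpois(1, 5 * 500), 0, 500))
      spontaneous_rate(st, licks, numeric(0), stim, 500)$rate_hz
    }, numeric(1))
  })
  expect_equal(mean(est), 5, tolerance = 0.02)
})

test_that("unit_qc_table flags injected refractory-free units", {
  ses <- simulate_population(4, seed = 33, n_per_modality = 20)
  qc <- unit_qc_table(ses)
  expect_equal(nrow(qc), 4)
  # thinned Poisson trains have no refractory period: violations scale with
  # rate and stay near baseline_hz * 0.003 * 2
  expect_true(all(qc$violation_fraction < 0.2))
  expect_true(all(qc$region %in% c("POm", "LP", "border")))
})
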