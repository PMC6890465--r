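test_that("eduction of flat or identical flies has the expected mean and SEM", {
  act <- tibble::tibble(fly_id = "f1", genotype = "g",
                        time = seq(0, 47.9, by = 0.1),
                        counts = 7L, light = "OFF", temperature = 25,
                        protocol = "DD",
                        day = as.integer(floor(seq(0, 47.9, by = 0.1) / 24) + 1))
  prof <- educe_profile(act)
  expect_equal(nrow(prof), 240)
  expect_true(all(prof$mean_activity == 7))
  expect_true(all(prof$sem == 0))
  two <- dplyr::bind_rows(act, dplyr::mutate(act, fly_id = "f2"))
  prof2 <- educe_profile(two)
  expect_true(all(prof2$sem == 0))
  expect_equal(unique(prof2$n_flies), 2)
})

test_that("eduction recovers programmed bimodal peak positions", {
  sim <- simulate_locomotor_cohort(n_flies = 12, days_ld = 4, days_dd = 0,
                                   morning_phase = 0, evening_phase = 12,
                                   seed = 31)
  prof <- educe_profile(sim$activity, protocol = "LD")
  sm <- circafly:::circular_ma(prof$mean_activity, 2 / 0.1)
  evening <- prof$phase[which.max(ifelse(prof$phase >= 6 & prof$phase < 18,
                                         sm, -Inf))]
  expect_lt(abs(evening - 12), 1.01)
})

test_that("peak phase reads a symmetric bump exactly and resists spikes", {
  tri <- pmax(0, 3 - abs(circular_diff(seq(0, 23.9, by = 0.1), 11, 24)))
  prof <- as_eduction_profile(tri)
  expect_equal(peak_phase(prof)$peak_time, 11.0)
  spiked <- tri
  spiked[31] <- spiked[31] + 2.5   # one-bin spike at phase 3
  pk <- peak_phase(as_eduction_profile(spiked))
  expect_equal(pk$peak_time, 11.0, tolerance = 0.05)
})

test_that("peak ties return the earliest time and flat profiles are undefined", {
  x <- rep(1, 240)
  x[c(60, 180)] <- 5   # equal maxima at 5.9 and 17.9
  pk <- peak_phase(as_eduction_profile(x), smoothing_hours = 0.1)
  expect_true(pk$tie)
  expect_equal(pk$peak_time, 5.9)
  flat <- peak_phase(as_eduction_profile(rep(2, 240)))
  expect_true(flat$undefined)
  expect_true(is.na(flat$peak_time))
})

test_that("phase shifts of identical groups are exactly zero", {
  sim <- simulate_locomotor_cohort(n_flies = 6, tau = 24, days_ld = 3,
                                   days_dd = 3, seed = 41)
  ps <- phase_shift(sim$activity, sim$activity, days = 4:6)
  expect_identical(ps$shift, 0)
})

test_that("a simulated light-pulse advance is recovered with its sign", {
  unp <- simulate_locomotor_cohort(n_flies = 16, tau = 24, days_ld = 3,
                                   days_dd = 6, seed = 51)
  pul <- simulate_locomotor_cohort(n_flies = 16, tau = 24, days_ld = 3,
                                   days_dd = 6, dd_phase_shift = 2, seed = 52)
  ps <- phase_shift(pul$activity, unp$activity, days = 5:9)
  expect_equal(ps$shift, 2, tolerance = 0.25)
  del <- simulate_locomotor_cohort(n_flies = 16, tau = 24, days_ld = 3,
                                   days_dd = 6, dd_phase_shift = -1.5,
                                   seed = 53)
  ps2 <- phase_shift(del$activity, unp$activity, days = 5:9)
  expect_equal(ps2$shift, -1.5, tolerance = 0.25)
})

test_that("relative evening phase is zero for identical profiles and maps the half-cycle boundary", {
  tri <- pmax(0, 3 - abs(circular_diff(seq(0, 23.9, by = 0.1), 9, 24)))
  prof <- as_eduction_profile(tri)
  expect_equal(relative_evening_phase(prof, prof,
                                      search_window = NULL)$relative_phase, 0)
  # exactly half a cycle apart: reported as +12, never -12
  shifted <- as_eduction_profile(c(tail(tri, 120), head(tri, 120)))
  rp <- relative_evening_phase(shifted, prof, search_window = NULL)
  expect_equal(abs(rp$relative_phase), 12)
  expect_equal(circular_diff(12, 0), 12)
  expect_equal(circular_diff(12.1, 0), -11.9)
})

test_that("anticipation scores match closed forms", {
  cfg <- rhythm_config()
  # uniform activity: 3 h of 6 h = 50% for both scores
  u <- anticipation_scores(as_eduction_profile(rep(4, 240)), cfg)
  expect_equal(u$morning_score, 50)
  expect_equal(u$evening_score, 50)
  # all activity inside ZT 20.5-23.5: morning = 100
  x <- rep(0, 240)
  x[206:235] <- 5
  a <- anticipation_scores(as_eduction_profile(x), cfg)
  expect_equal(a$morning_score, 100)
  # linear ramp from 0 across ZT 17.5-23.5: last-half integral = 75%
  ph <- seq(0.05, 23.95, by = 0.1)   # bin centers for midpoint-exact sums
  ramp <- ifelse(ph > 17.5 & ph < 23.5, ph - 17.5, 0)
  r <- anticipation_scores(as_eduction_profile(ramp), cfg)
  expect_equal(r$morning_score, 75)
  # zero denominator flags undefined
  z <- anticipation_scores(as_eduction_profile(c(rep(1, 50), rep(0, 190))),
                           cfg)
  expect_true(z$morning_undefined)
  expect_true(is.na(z$morning_score))
})

test_that("circular consistency: rotating a profile rotates its peak", {
  tri <- pmax(0, 3 - abs(circular_diff(seq(0, 23.9, by = 0.1), 8, 24)))
  base <- peak_phase(as_eduction_profile(tri))$peak_time
  for (k in c(30, 75, 151)) {
    rot <- as_eduction_profile(c(tail(tri, -k), head(tri, k)))
    pk <- peak_phase(rot)$peak_time
    expect_equal(circular_diff(pk, base), circular_diff(-k * 0.1, 0),
                 tolerance = 1e-8)
  }
})

test_that("smoothing preserves total mass and fixes constants", {
  x <- rpois(240, 5)
  sm <- circafly:::circular_ma(x, 40)
  expect_equal(sum(sm), sum(x), tolerance = 1e-9)
  expect_equal(circafly:::circular_ma(rep(3, 240), 40), rep(3, 240))
})

test_that("entrainment stability drift check warns on unstable phase", {
  stable <- simulate_locomotor_cohort(n_flies = 10, tau = 24, days_ld = 2,
                                      days_tc = 4, days_dd = 0,
                                      evening_phase = 8, seed = 61)
  expect_no_warning(
    entrainment_stability(stable$activity, days = 3:6,
                          search_window = c(3, 11)))
  # a short free-running tau under 'TC' labels drifts ~1 h/day
  drifting <- simulate_locomotor_cohort(n_flies = 10, tau = 23, days_ld = 0,
                                        days_tc = 0, days_dd = 6,
                                        evening_phase = 8, seed = 62)
  drifting$activity$protocol <- "TC"
  expect_warning(
    entrainment_stability(drifting$activity, days = 2:5,
                          search_window = NULL),
    "drift")
})
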