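# Angle calibration, angular velocity, onset detection, markers, acceptance.

test_that("angle calibration anchors at 0, 30 and 90 degrees", {
  expect_equal(calibrate_angle(0, c(0, 1)), 0)
  expect_equal(calibrate_angle(1, c(0, 1)), 90)
  expect_equal(calibrate_angle(0.5, c(0, 1)), 30)
  # non-trivial calibration readings
  expect_equal(calibrate_angle(c(0.1, 2.1), c(0.1, 2.1)), c(0, 90))
  expect_error(calibrate_angle(0.5, c(1, 1)),
               class = "liftpost_error_bad_calibration")
  # calibration inverts the forward gravity map exactly
  th <- seq(0, 90, by = 0.5)
  expect_equal(calibrate_angle(sin(th * pi / 180), c(0, 1)), th,
               tolerance = 1e-12)
})

test_that("angular velocity differentiates ramps and sinusoids correctly", {
  rate <- 40
  expect_true(all(angular_velocity(rep(45, 100), rate) == 0))
  ramp <- seq(0, 90, length.out = 41)  # 0 -> 90 deg over 1 s
  om <- angular_velocity(ramp, rate, smooth = FALSE)
  expect_equal(om[2:40], rep(90, 39), tolerance = 1e-9)
  t_s <- seq(0, 3, by = 1 / rate)
  f <- 0.8; A <- 20
  om2 <- angular_velocity(A * sin(2 * pi * f * t_s), rate, smooth = FALSE)
  expect_equal(max(abs(om2[10:100])), A * 2 * pi * f,
               tolerance = 0.02)
  expect_error(angular_velocity(c(1, 2), rate),
               class = "liftpost_error_short_series")
})

test_that("flat acceleration yields no onsets; injected lifts are found to the sample", {
  expect_length(detect_lift_onsets(rep(0.01, 400), 40), 0)
  s <- generate_session(group_template("CTR"), n_lifts = 3, seed = 33)
  det <- detect_lift_onsets(s$record$channels$acc, 40)
  expect_length(det, 3)
  expect_true(all(abs(det - s$truth$onset_ms) <= 25))
})

test_that("a gradual rise without the jerk spike is still detected nearby", {
  # smooth counter-movement dip (no one-sample transient), then the lift
  rate <- 40
  t_ms <- (0:1199) * 25
  onset <- 8000
  th <- 90 * pgamma((t_ms - onset) / 1000, 3.2, 3.2 / 0.4)
  acc <- sin(th * pi / 180)
  dip <- 0.05 * rcbump_test(t_ms, onset - 50, onset + 250)
  det <- detect_lift_onsets(acc - dip, rate)
  expect_length(det, 1)
  expect_lte(abs(det - onset), 50)   # +/- 2 samples
})

test_that("onset detection is exact with zero false positives on 100 noise-free records", {
  tpl <- noisefree_template("CTR")
  tpl_ipd <- noisefree_template("IPD")
  set.seed(77)
  n_fp <- 0; n_miss <- 0
  for (i in 1:100) {
    tp <- if (i %% 2) tpl else tpl_ipd
    s <- generate_session(tp, n_lifts = 3)
    det <- detect_lift_onsets(s$record$channels$acc, 40)
    matched <- vapply(s$truth$onset_ms,
                      function(o) any(abs(det - o) <= 25), logical(1))
    n_miss <- n_miss + sum(!matched)
    n_fp <- n_fp + sum(vapply(det, function(d)
      all(abs(s$truth$onset_ms - d) > 25), logical(1)))
  }
  expect_equal(n_miss, 0)
  expect_equal(n_fp, 0)
})

test_that("grand-average markers land at the control landmarks", {
  res <- default_analysis("CTR")
  mk <- res$markers$CTR
  expect_lt(abs(mk$marker_a_ms - 400), 50)
  expect_lt(abs(mk$marker_b_ms - 1200), 75)
  expect_false(mk$flagged)
})

test_that("marker a is invariant to uniform scaling of omega", {
  res <- default_analysis("CTR")
  ga <- res$ga$CTR
  mk1 <- detect_markers(ga$axes$omega$mean, ga$axes$theta$mean, ga$time_ms)
  mk2 <- detect_markers(3.7 * ga$axes$omega$mean, ga$axes$theta$mean,
                        ga$time_ms)
  expect_equal(mk1$marker_a_ms, mk2$marker_a_ms)
})

test_that("a step to 90 degrees gives marker b at the first post-onset sample", {
  th <- ifelse(seg_time >= 0, 90, 0)
  om <- c(0, diff(th)) * 40
  mk <- detect_markers(om, th, seg_time)
  expect_equal(mk$marker_b_ms, 0)
})

test_that("trial acceptance rejects aborted, slow and unstable lifts", {
  s <- noisefree_cohort("CTR", n = 1, n_sessions = 1)
  res <- analyze_cohort(s)
  expect_true(all(res$qc$accepted))

  tpl <- noisefree_template("CTR")
  tr <- generate_trial(tpl, seed = 2)
  th <- calibrate_angle(tr$channels$acc, c(0, 1))
  om <- angular_velocity(th, 40)
  ev <- structure(list(onset_ms = 0, marker_a_ms = 400, marker_b_ms = 1200),
                  class = "lift_event")
  expect_true(accept_trial(ev, th, tr$time_ms)$accepted)
  # self-aborted: never beyond 40 degrees
  expect_equal(accept_trial(ev, pmin(th, 40), tr$time_ms)$reason,
               "self-aborted")
  # slow: reaches 80 degrees only after 3 s
  slow <- 90 * rcstep_test(tr$time_ms, 0, 3500)
  expect_equal(accept_trial(ev, slow, tr$time_ms)$reason, "slow")
  # unstable hold: drops below 70 degrees during the hold
  th2 <- th
  th2[tr$time_ms > 2500 & tr$time_ms < 2800] <- 60
  expect_equal(accept_trial(ev, th2, tr$time_ms)$reason, "unstable-hold")
})
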