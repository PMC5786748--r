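# Scalar postural metrics: constructed inputs, invariances, group ordering.

test_that("anticipatory window means: zero signal, linear ramp, IPD dip sign", {
  expect_equal(apa_window_means(make_segment()), rep(0, 4))
  # y = t (ms): the mean of a linear signal over each window sits close to
  # the window midpoint (the half-open 250-ms windows at 40 Hz hold 10
  # samples, offsetting the discrete mean by half a sample step)
  seg <- make_segment(y = seg_time)
  expect_equal(apa_window_means(seg), c(-887.5, -637.5, -387.5, -137.5))
  # IPD cohort: backward dip makes the fourth window negative
  res <- default_analysis("IPD")
  expect_lt(mean(res$trial_metrics$apa_4), 0)
})

test_that("forward peak finds a constructed raised-cosine bump exactly", {
  seg <- make_segment(y = 2 * rcbump_test(seg_time, 300, 2100))
  pk <- cpa_peak(seg)
  expect_equal(pk$amplitude_cm, 2)
  expect_equal(pk$latency_ms, 1200)
  # ties broken by the earliest sample
  segf <- make_segment(y = c(rep(0, 60), rep(3, 180)))
  expect_equal(cpa_peak(segf)$latency_ms, seg_time[61])
})

test_that("metrics are invariant to a constant added before baseline correction", {
  tpl <- noisefree_template("PSP")
  cv <- cop_template(tpl, seg_time)
  base <- make_segment(x = cv$x, y = cv$y, z = cv$z)
  shifted <- make_segment(x = cv$x + 4, y = cv$y - 2, z = cv$z + 0.1)
  a <- baseline_correct(base); b <- baseline_correct(shifted)
  expect_equal(cpa_peak(a), cpa_peak(b))
  expect_equal(return_offsets(a, 925), return_offsets(b, 925))
  expect_equal(apa_window_means(a), apa_window_means(b))
})

test_that("peak on a noise-free template equals the analytic maximum", {
  for (g in c("CTR", "IPD", "PSP")) {
    tpl <- noisefree_template(g)
    cv <- cop_template(tpl, seg_time)
    seg <- make_segment(x = cv$x, y = cv$y, z = cv$z)
    pk <- cpa_peak(seg)
    expect_lt(abs(pk$amplitude_cm - tpl$sagittal$peak_amp), 1e-9)
    expect_lte(abs(pk$latency_ms - tpl$sagittal$peak_latency), 25)
  }
})

test_that("return offsets: exact return gives zero; group ordering holds", {
  seg <- make_segment(y = rcbump_test(seg_time, 0, 2000))  # back at baseline
  offs <- return_offsets(seg, 1200)
  expect_equal(offs$offset_at_5000, 0)
  expect_equal(offs$min_offset_hold, 0)
  ctr <- default_analysis("CTR")$ga_metrics
  psp <- default_analysis("PSP")$ga_metrics
  ipd <- default_analysis("IPD")$ga_metrics
  expect_lt(ctr$offset_at_5000, 1)
  expect_gt(psp$offset_at_5000, 2)
  expect_lte(psp$min_offset_hold, 4)
  expect_gt(ipd$offset_at_5000, 4)
  expect_true(ipd$offset_at_5000 > psp$offset_at_5000)
  expect_true(psp$offset_at_5000 > ctr$offset_at_5000)
})

test_that("lateral indices: zero input, control lean left, PSP lean absent", {
  lat <- lateral_phase_indices(make_segment(), 400)
  expect_equal(lat$lateral_accel_excursion, 0)
  expect_equal(lat$lateral_lean_1000_3000, 0)
  ctr <- default_analysis("CTR")$ga_metrics
  expect_gt(ctr$lateral_accel_excursion, 0)       # rightward, toward weight
  expect_lt(ctr$lateral_lean_1000_3000, 0)        # compensatory left lean
  psp <- default_analysis("PSP")$ga_metrics
  expect_lt(abs(psp$lateral_lean_1000_3000), 0.2) # lean absent
})

test_that("oscillation estimator recovers pure tones and flags white noise", {
  o13 <- oscillation_frequency(0.5 * sin(2 * pi * 1.3 * seg_time / 1000),
                               seg_time)
  expect_lt(abs(o13$frequency_hz - 1.3), 0.05)
  expect_equal(o13$confidence, "ok")
  expect_equal(o13$wavelength_s, 1 / o13$frequency_hz)
  o03 <- oscillation_frequency(0.5 * sin(2 * pi * 0.3 * (seg_time - 1000) / 1000),
                               seg_time)
  expect_lt(abs(o03$frequency_hz - 0.3), 0.05)
  set.seed(9)
  wn <- oscillation_frequency(rnorm(240, 0, 0.2), seg_time)
  expect_equal(wn$confidence, "low")
  expect_error(oscillation_frequency(rnorm(240), seg_time,
                                     window_ms = c(1000, 2000)),
               class = "liftpost_error_window_too_short")
})

test_that("frequency recovery is reliable at estimable signal-to-noise ratios", {
  # 1.3 Hz carries ~5 cycles in the window and is estimable at SNR 3; at
  # 0.3 Hz the window holds only 1.2 cycles and the quadratic trend is
  # nearly collinear with the sinusoid, so reliable +/-10% recovery needs a
  # stronger oscillation (grand averages, where this estimate is used,
  # operate far above both levels).
  set.seed(71)
  reps <- 200
  for (cfg in list(list(f = 1.3, snr = 3), list(f = 0.3, snr = 10))) {
    ok <- logical(reps)
    for (r in seq_len(reps)) {
      x <- 0.15 * cfg$snr * sin(2 * pi * cfg$f * (seg_time - 1000) / 1000 +
                                  runif(1, 0, 2 * pi)) +
        rnorm(240, 0, 0.15)
      est <- oscillation_frequency(x, seg_time)
      ok[r] <- !is.na(est$frequency_hz) &&
        abs(est$frequency_hz - cfg$f) / cfg$f <= 0.10
    }
    expect_gte(mean(ok), 0.95)
  }
})

test_that("kinematic indices: ramps, triangles and the PSP > CTR ordering", {
  # ramp to plateau: initial acceleration = slope, braking 0 on the plateau
  t_ms <- seg_time
  om <- pmin(pmax(t_ms, 0), 1000) * 0.12          # 120 deg/s at 1 s
  ki <- kinematic_indices(om, t_ms, marker_a_ms = 1000, marker_b_ms = 4000)
  expect_equal(ki$initial_accel, 120, tolerance = 1e-9)
  expect_equal(ki$braking, 0)
  expect_equal(ki$peak_omega, 120)
  # symmetric triangle: braking mirrors the initial acceleration
  tri <- (1000 - abs(pmin(pmax(t_ms, 0), 2000) - 1000)) * 0.12
  kt <- kinematic_indices(tri, t_ms, marker_a_ms = 1000, marker_b_ms = 2000)
  expect_equal(kt$braking, -kt$initial_accel)
  # group ordering on the default cohorts
  psp <- default_analysis("PSP")$trial_metrics
  ctr <- default_analysis("CTR")$trial_metrics
  expect_gt(mean(psp$peak_omega), mean(ctr$peak_omega))
  expect_gt(mean(psp$initial_accel), mean(ctr$initial_accel))
  expect_lt(mean(psp$braking), mean(ctr$braking))   # harder braking
})

test_that("latency ordering across groups matches the disease signatures", {
  ipd <- default_analysis("IPD")$ga_metrics
  psp <- default_analysis("PSP")$ga_metrics
  expect_gt(ipd$cpa_peak_latency, psp$cpa_peak_latency)
  expect_gt(psp$osc_x_freq, ipd$osc_x_freq)
})
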