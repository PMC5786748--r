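## Postural metrics ----------------------------------------------------------

## Metric operations accept either a single baseline-corrected segment or a
## grand average (whose pointwise means are then analysed).
as_metric_traces <- function(obj) {
  if (inherits(obj, "grand_average")) {
    tr <- lapply(obj$axes, `[[`, "mean")
    c(list(time_ms = obj$time_ms), tr)
  } else {
    obj
  }
}

#' Anticipatory window means
#'
#' Mean anteroposterior COP in the four preset 250-ms windows preceding lift
#' onset: [-1000,-750), [-750,-500), [-500,-250), [-250,0) ms.
#'
#' @param seg a baseline-corrected `postural_segment` or a `grand_average`.
#' @return numeric vector of four window means, cm.
#' @export
apa_window_means <- function(seg) {
  tr <- as_metric_traces(seg)
  lo <- c(-1000, -750, -500, -250)
  vapply(lo, function(l) {
    mean(tr$y[tr$time_ms >= l & tr$time_ms < l + 250])
  }, numeric(1))
}

#' Compensatory peak: furthest forward COP displacement
#'
#' Maximum of the anteroposterior COP over (0, 5000] ms and its latency;
#' ties are broken by the earliest sample.
#'
#' @inheritParams apa_window_means
#' @return list with `amplitude_cm` and `latency_ms`.
#' @export
cpa_peak <- function(seg) {
  tr <- as_metric_traces(seg)
  post <- tr$time_ms > 0
  y <- tr$y[post]
  i <- which.max(y)                 # which.max returns the first maximum
  list(amplitude_cm = y[i], latency_ms = tr$time_ms[post][i])
}

#' Return-to-baseline offsets
#'
#' Planar (x, y) Euclidean distance of the COP from its pre-liftoff baseline
#' (the origin, after baseline correction): `offset_at_5000` is the distance
#' at the last segment sample; `min_offset_hold` is the closest approach
#' during the holding phase, from marker "b" to the end of the segment.
#' Per-axis offsets at the end of the hold are reported alongside.
#'
#' @inheritParams apa_window_means
#' @param marker_b_ms arrival of the weight at the 90-degree position, ms.
#' @return list with `offset_at_5000`, `min_offset_hold`, `offset_x`,
#'   `offset_y` (cm).
#' @export
return_offsets <- function(seg, marker_b_ms) {
  tr <- as_metric_traces(seg)
  d <- sqrt(tr$x^2 + tr$y^2)
  n <- length(d)
  hold <- tr$time_ms >= marker_b_ms
  list(offset_at_5000 = d[n],
       min_offset_hold = if (any(hold)) min(d[hold]) else NA_real_,
       offset_x = tr$x[n], offset_y = tr$y[n])
}

#' Lateral compensation indices
#'
#' `lateral_accel_excursion`: the signed lateral COP extremum during the arm
#' acceleration phase [0, marker "a"] (positive = rightward, ipsilateral to
#' the lifting arm).  `lateral_lean_1000_3000`: mean lateral COP in the
#' 1000-3000 ms phase, where healthy subjects lean left (negative values)
#' to counterbalance the extended weight.
#'
#' @inheritParams apa_window_means
#' @param marker_a_ms latency of peak angular velocity, ms.
#' @return list with `lateral_accel_excursion` and `lateral_lean_1000_3000`
#'   (cm).
#' @export
lateral_phase_indices <- function(seg, marker_a_ms) {
  tr <- as_metric_traces(seg)
  acc <- tr$time_ms >= 0 & tr$time_ms <= marker_a_ms
  xa <- tr$x[acc]
  exc <- if (length(xa)) xa[which.max(abs(xa))] else NA_real_
  lean <- mean(tr$x[tr$time_ms >= 1000 & tr$time_ms <= 3000])
  list(lateral_accel_excursion = exc, lateral_lean_1000_3000 = lean)
}

#' Dominant oscillation frequency of a COP axis
#'
#' Estimates the dominant frequency of body oscillations in an analysis
#' window (default the return/hold phase, [1000, 5000) ms).  The series is
#' detrended by a 2nd-order polynomial fit; the primary estimate is
#' `1 / (2 * median inter-extremum interval)` over extrema whose swing
#' exceeds `prominence_k` times the noise MAD (noise estimated from the
#' first differences of the detrended series).  The extremum estimator is
#' primary because a 4-s window holds only about one cycle of a slow 0.3-Hz
#' sway, below reliable spectral resolution; a zero-padded periodogram peak
#' (0.1-5 Hz) is reported as a cross-check, and the estimate is flagged
#' low-confidence when the two disagree by more than 30% or fewer than two
#' prominent extrema are found.
#'
#' @param x numeric series (one COP axis) or a `postural_segment` /
#'   `grand_average` (use `axis`).
#' @param time_ms time axis, ms (ignored when `x` is a segment object).
#' @param axis axis name when `x` is a segment or grand average.
#' @param window_ms half-open analysis window, ms; must span at least 2 s.
#' @param prominence_k swing threshold in units of the noise MAD.
#' @param pad FFT length for the periodogram.
#' @return list with `frequency_hz`, `wavelength_s`, `spectral_hz`,
#'   `n_extrema`, `confidence` (`"ok"` or `"low"`).
#' @export
oscillation_frequency <- function(x, time_ms = NULL, axis = "x",
                                  window_ms = c(1000, 5000),
                                  prominence_k = 2, pad = 4096) {
  if (inherits(x, c("postural_segment", "grand_average"))) {
    tr <- as_metric_traces(x)
    time_ms <- tr$time_ms
    x <- tr[[axis]]
  }
  w <- time_ms >= window_ms[1] & time_ms < window_ms[2]
  if (diff(range(time_ms[w])) < 2000)
    lp_stop("window_too_short", "analysis window must span at least 2 s")
  ts <- time_ms[w] / 1000
  xs <- x[w]
  r <- resid(lm(xs ~ ts + I(ts^2)))
  dt <- diff(ts[1:2])
  noise_mad <- mad(diff(r)) / sqrt(2)

  ## Extrema are taken on a lightly smoothed residual (centered 5-sample
  ## moving average, ~8 Hz at 40 Hz sampling, well above the 0.1-5 Hz band
  ## of interest) while the swing threshold keeps the raw noise scale;
  ## without the smoothing, sample-to-sample noise extrema overwhelm the
  ## interval statistic at trial-level signal-to-noise ratios.
  rs <- moving_average(r, 5)
  d <- diff(rs)
  ext <- which(d[-1] * d[-length(d)] < 0) + 1
  thr <- prominence_k * noise_mad
  while (length(ext) >= 2) {
    swings <- abs(diff(rs[ext]))
    if (!length(swings) || min(swings) >= thr) break
    j <- which.min(swings)
    ext <- ext[-c(j, j + 1)]        # drop the smallest wiggle pair
  }
  ## zero-padded periodogram cross-check
  spec <- Mod(fft(c(r, numeric(pad - length(r)))))^2
  fr <- (seq_along(spec) - 1) / (pad * dt)
  band <- fr >= 0.1 & fr <= 5
  spectral <- fr[band][which.max(spec[band])]

  if (length(ext) >= 2) {
    f0 <- 1 / (2 * median(diff(ts[ext])))
    ## Refine by profiling the joint quadratic-plus-sinusoid fit over
    ## frequency: fitting trend and oscillation sequentially biases the
    ## extremum spacing when the window holds close to one cycle (the
    ## quadratic absorbs part of the sine), whereas the joint fit recovers
    ## a pure sinusoid exactly.  Both the extremum and the periodogram
    ## estimates seed the profile search and the better-fitting frequency
    ## is kept, so an occasional noise-corrupted extremum set cannot drag
    ## the estimate off on its own.
    rss <- function(f) {
      s <- sin(2 * pi * f * ts); cc <- cos(2 * pi * f * ts)
      sum(resid(lm(xs ~ ts + I(ts^2) + s + cc))^2)
    }
    fits <- lapply(unique(c(f0, spectral)), function(fs)
      stats::optimize(rss, c(max(0.55 * fs, 0.05), min(1.45 * fs, 6)),
                      tol = 1e-4))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    freq <- best$minimum
    wavelength <- 1 / freq
    s <- sin(2 * pi * freq * ts); cc <- cos(2 * pi * freq * ts)
    bf <- coef(lm(xs ~ ts + I(ts^2) + s + cc))
    amp_fit <- sqrt(bf[["s"]]^2 + bf[["cc"]]^2)
  } else {
    wavelength <- NA_real_
    freq <- NA_real_
    amp_fit <- 0
  }

  ## The 30% agreement rule with the spectral estimate is only meaningful
  ## above the Rayleigh resolution of the window (1/T); below it the
  ## periodogram peak cannot pin the frequency down any tighter.
  span_s <- diff(range(ts))
  conf <- "ok"
  if (length(ext) < 2 || is.na(freq) ||
      amp_fit < prominence_k * noise_mad ||
      abs(freq - spectral) > max(0.3 * max(freq, spectral), 1.5 / span_s))
    conf <- "low"
  list(frequency_hz = freq, wavelength_s = wavelength,
       spectral_hz = spectral, amplitude = unname(amp_fit),
       n_extrema = length(ext), confidence = conf)
}

#' Barbell kinematic indices of one lift
#'
#' `peak_omega`: maximum angular velocity (deg/s).  `initial_accel`: mean
#' angular acceleration over the first 200 ms after onset (deg/s^2).
#' `braking`: the most negative angular acceleration between markers "a"
#' and "b" (deg/s^2), i.e. how hard the movement is stopped at the 90-degree
#' position.
#'
#' @param omega angular-velocity course, deg/s.
#' @param time_ms time axis, ms relative to onset.
#' @param marker_a_ms,marker_b_ms the per-trial (or grand-average) markers.
#' @param rate sampling rate, Hz.
#' @return list with `peak_omega`, `initial_accel`, `braking`.
#' @export
kinematic_indices <- function(omega, time_ms, marker_a_ms, marker_b_ms,
                              rate = 40) {
  post <- time_ms >= 0
  peak <- max(omega[post])
  acc <- diff(omega) * rate
  mid <- (time_ms[-1] + time_ms[-length(time_ms)]) / 2
  init <- mean(acc[mid >= 0 & mid < 200])
  if (!is.na(marker_b_ms)) {
    brw <- mid > marker_a_ms & mid <= marker_b_ms
    braking <- if (any(brw)) min(acc[brw]) else NA_real_
  } else braking <- NA_real_
  list(peak_omega = peak, initial_accel = init, braking = braking)
}

#' Per-trial metric row
#'
#' Computes the full scalar metric set of one accepted, baseline-corrected
#' trial, keyed by subject, group and condition; one row of the metrics
#' table that feeds the group statistics.
#'
#' @param seg a baseline-corrected `postural_segment`.
#' @param event the matching `lift_event`.
#' @return one-row `data.frame`.
#' @export
trial_metrics <- function(seg, event) {
  apa <- apa_window_means(seg)
  peak <- cpa_peak(seg)
  offs <- return_offsets(seg, event$marker_b_ms)
  lat <- lateral_phase_indices(seg, event$marker_a_ms)
  osc <- oscillation_frequency(seg, axis = "x")
  data.frame(
    subject_id = seg$subject_id, group = seg$group,
    condition = seg$condition, onset_ms = seg$onset_ms,
    apa_1 = apa[1], apa_2 = apa[2], apa_3 = apa[3], apa_4 = apa[4],
    cpa_peak_amp = peak$amplitude_cm, cpa_peak_latency = peak$latency_ms,
    offset_at_5000 = offs$offset_at_5000,
    min_offset_hold = offs$min_offset_hold,
    lateral_accel_excursion = lat$lateral_accel_excursion,
    lateral_lean_1000_3000 = lat$lateral_lean_1000_3000,
    osc_x_freq = osc$frequency_hz,
    osc_x_confidence = osc$confidence,
    marker_a_ms = event$marker_a_ms, marker_b_ms = event$marker_b_ms,
    peak_omega = event$peak_omega, initial_accel = event$initial_accel,
    braking = event$braking,
    stringsAsFactors = FALSE
  )
}
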