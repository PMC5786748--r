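## Barbell kinematics --------------------------------------------------------

#' Calibrate the accelerometer signal to barbell angle
#'
#' The one-axis accelerometer aligned with the lifting plane measures the
#' gravity component `g * sin(theta)`: reading `a0` with the weight hanging
#' down (0 degrees) and `a1` in the 90-degree forward position.  The angle is
#' recovered as `theta = asin((acc - a0) / (a1 - a0))` with the normalized
#' signal clipped to [0, 1]; dynamic acceleration during the movement is
#' accepted as part of the position-equivalent signal.
#'
#' @param acc_raw accelerometer signal, g.
#' @param calibration numeric `c(a0, a1)`, readings at 0 and 90 degrees.
#' @return angle in degrees.
#' @export
calibrate_angle <- function(acc_raw, calibration = c(0, 1)) {
  if (calibration[1] == calibration[2])
    lp_stop("bad_calibration", "calibration readings a0 and a1 must differ")
  u <- (acc_raw - calibration[1]) / (calibration[2] - calibration[1])
  asin(pmin(pmax(u, 0), 1)) * 180 / pi
}

#' Angular velocity of the barbell
#'
#' Central differences of the (optionally 5-sample smoothed) angle series;
#' one-sided differences at the endpoints.
#'
#' @param theta angle series, degrees.
#' @param rate sampling rate, Hz.
#' @param smooth logical, apply the moving-average pre-smoothing.
#' @param window smoothing window in samples (odd).
#' @return angular velocity, deg/s.
#' @export
angular_velocity <- function(theta, rate, smooth = TRUE, window = 5) {
  n <- length(theta)
  if (n < 3) lp_stop("short_series", "need at least 3 samples")
  th <- if (smooth) moving_average(theta, window) else theta
  dt <- 1 / rate
  om <- numeric(n)
  om[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / (2 * dt)
  om[1] <- (th[2] - th[1]) / dt
  om[n] <- (th[n] - th[n - 1]) / dt
  om
}

#' Detect lift onsets from the accelerometer trace
#'
#' The trigger (marker "0") is the first negative peak of the first
#' difference of the lightly smoothed acceleration signal.  Candidate minima
#' must fall below `-max(k * MAD, floor)` where the MAD is taken over the
#' whole derivative series (the record is mostly quiet stance, so this is a
#' robust noise-floor estimate).  Candidates are clustered (minima closer
#' than `refractory_s` collapse to the first), must start from the hanging
#' position (angle below `confirm_deg`), and must be followed within
#' `confirm_s` by the angle exceeding `confirm_deg`; this removes derivative
#' minima caused by lowering the weight after the hold.
#'
#' @param acc_raw accelerometer series, g.
#' @param rate sampling rate, Hz.
#' @param calibration accelerometer calibration, see [calibrate_angle()].
#' @param k MAD multiplier of the trigger threshold.
#' @param floor_g absolute minimum threshold (g per sample), the fallback for
#'   noise-free input where the MAD is degenerate.
#' @param smooth_window pre-smoothing window in samples (odd; 1 disables).
#' @param refractory_s minimum separation of distinct onsets, s.
#' @param confirm_deg,confirm_s angle-confirmation gate.
#' @return onset times in ms (possibly empty).
#' @export
detect_lift_onsets <- function(acc_raw, rate, calibration = c(0, 1), k = 5,
                               floor_g = 0.005, smooth_window = 3,
                               refractory_s = 2, confirm_deg = 45,
                               confirm_s = 3) {
  n <- length(acc_raw)
  if (n < rate) lp_stop("short_series", "need at least 1 s of data")
  sm <- moving_average(acc_raw, smooth_window)
  d <- c(NA, diff(sm))
  thr <- max(k * mad(d, na.rm = TRUE), floor_g)
  cand <- which(!is.na(d) & d < -thr)
  ## local minima only
  cand <- cand[vapply(cand, function(i) {
    (i == 2 || is.na(d[i - 1]) || d[i] <= d[i - 1]) &&
      (i == n || d[i] <= d[i + 1])
  }, logical(1))]
  if (!length(cand)) return(numeric(0))
  ## undo the group delay of the centered pre-smoothing
  shift <- (smooth_window - 1) %/% 2
  theta <- calibrate_angle(acc_raw, calibration)
  refr <- refractory_s * rate
  keep <- integer(0)
  prev <- -Inf
  for (i in cand) {
    new_cluster <- (i - prev) >= refr
    prev <- i
    if (!new_cluster) next                      # same cluster: keep first only
    at <- min(i + shift, n)
    if (theta[at] >= confirm_deg) next          # not starting from hanging
    horizon <- if (at < n) seq(at + 1, min(at + confirm_s * rate, n))
               else integer(0)
    if (length(horizon) && any(theta[horizon] > confirm_deg))
      keep <- c(keep, at)
  }
  (keep - 1) * 1000 / rate
}

#' Detect grand-average markers "a" and "b"
#'
#' Marker "a" is the latency of the peak angular velocity of the
#' grand-average omega trace; marker "b" is the first time the grand-average
#' angle reaches `frac` (default 0.95) of its hold-phase plateau median.
#'
#' @param omega,theta grand-average angular velocity (deg/s) and angle (deg).
#' @param time_ms common time axis, ms relative to onset.
#' @param plateau_window window (ms) over which the plateau median is taken.
#' @param frac fraction of the plateau defining arrival.
#' @return list with `marker_a_ms`, `marker_b_ms` and `flagged` (`TRUE` when
#'   the plateau criterion is never reached and `marker_b_ms` is `NA`).
#' @export
detect_markers <- function(omega, theta, time_ms,
                           plateau_window = c(2500, 5000), frac = 0.95) {
  post <- time_ms >= 0
  marker_a <- time_ms[post][which.max(omega[post])]
  pw <- time_ms >= plateau_window[1] & time_ms < plateau_window[2]
  plateau <- median(theta[pw])
  hit <- which(post & theta >= frac * plateau)
  if (!length(hit)) {
    return(list(marker_a_ms = marker_a, marker_b_ms = NA_real_,
                flagged = TRUE))
  }
  list(marker_a_ms = marker_a, marker_b_ms = time_ms[hit[1]], flagged = FALSE)
}

#' Build per-lift kinematic events
#'
#' For each detected onset, extracts the 0..+5000 ms angle and velocity
#' course and computes the per-trial markers and indices: peak angular
#' velocity and its latency (marker "a"), arrival at the 90-degree plateau
#' (marker "b", 0.95-of-plateau criterion), the initial angular acceleration
#' (mean over the first 200 ms) and the braking index (most negative angular
#' acceleration between the two markers).
#'
#' @param theta,omega record-level angle (deg) and angular velocity (deg/s).
#' @param onsets_ms detected onset times, ms.
#' @param rate sampling rate, Hz.
#' @return list of `lift_event` objects (fields `onset_ms`, `marker_a_ms`,
#'   `marker_b_ms`, `peak_omega`, `initial_accel`, `braking`, `flagged`).
#' @export
lift_events <- function(theta, omega, onsets_ms, rate) {
  n <- length(theta)
  t_ms <- (seq_len(n) - 1) * 1000 / rate
  lapply(onsets_ms, function(o) {
    w <- which(t_ms >= o & t_ms < o + 5000)
    tau <- t_ms[w] - o
    mk <- detect_markers(omega[w], theta[w], time_ms = tau)
    idx <- kinematic_indices(omega[w], tau, mk$marker_a_ms, mk$marker_b_ms,
                             rate)
    structure(c(list(onset_ms = o), mk[c("marker_a_ms", "marker_b_ms")],
                idx, list(flagged = mk$flagged)),
              class = "lift_event")
  })
}

#' Accept or reject a lift trial
#'
#' Rejection rules for insufficient lifts: `self-aborted` when the barbell
#' never reaches `complete_deg`; `slow` when it takes longer than `slow_ms`
#' to get there; `unstable-hold` when the angle drops below `hold_deg` within
#' 5 s of marker "b" (evaluated over the part of the hold covered by the
#' segment).  The thresholds are conventions of this implementation, chosen
#' to pass obviously complete lifts and fail the named failure modes.
#'
#' @param event a `lift_event` from [lift_events()].
#' @param theta_seg angle course of the segment, degrees.
#' @param time_ms segment time axis, ms relative to onset.
#' @param complete_deg,slow_ms,hold_deg thresholds described above.
#' @return list with `accepted` (logical) and `reason` (`NA` or the rule
#'   name).
#' @export
accept_trial <- function(event, theta_seg, time_ms, complete_deg = 80,
                         slow_ms = 2500, hold_deg = 70) {
  post <- time_ms >= 0
  reached <- which(post & theta_seg >= complete_deg)
  if (!length(reached))
    return(list(accepted = FALSE, reason = "self-aborted"))
  if (time_ms[reached[1]] > slow_ms)
    return(list(accepted = FALSE, reason = "slow"))
  b <- event$marker_b_ms
  if (!is.na(b)) {
    hold <- time_ms >= b & time_ms <= b + 5000
    if (any(theta_seg[hold] < hold_deg))
      return(list(accepted = FALSE, reason = "unstable-hold"))
  }
  list(accepted = TRUE, reason = NA_character_)
}
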