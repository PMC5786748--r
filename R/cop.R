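## Centre-of-pressure computation --------------------------------------------

#' Force-plate geometry
#'
#' Sensor layout of a rectangular four-sensor piezoelectric plate: sensors at
#' (+a,+b), (-a,+b), (-a,-b), (+a,-b) where `a = half_width` (lateral, cm)
#' and `b = half_depth` (anteroposterior, cm), plus the height of the plate
#' surface above the sensor plane (used only for the optional shear-force
#' correction).
#'
#' @param half_width,half_depth half sensor spacing in cm.
#' @param surface_height plate surface height above the sensor plane, cm.
#' @return object of class `plate_geometry`.
#' @export
plate_geometry <- function(half_width = 12, half_depth = 20,
                           surface_height = 3) {
  if (half_width <= 0 || half_depth <= 0)
    lp_stop("bad_geometry", "sensor half spacings must be positive")
  structure(list(half_width = half_width, half_depth = half_depth,
                 surface_height = surface_height), class = "plate_geometry")
}

#' Compute the COP trace from a session record
#'
#' The centre of foot pressure is the vertical-force-weighted centroid of the
#' four sensor positions:
#' `x = a * (fz1 - fz2 - fz3 + fz4) / Fz`, `y = b * (fz1 + fz2 - fz3 - fz4) / Fz`.
#' If shear channels `fx`/`fy` are present the standard surface-height
#' correction `- h * (Fx, Fy) / Fz` is subtracted.  The third axis is the
#' normalized vertical load deviation `z = Fz / W - 1`, with the quiet-stance
#' load `W` estimated as the median total vertical force of the record (a
#' static plate cannot measure the height of the centre of mass; the
#' oscillation analysis that uses this axis only needs its dynamics).
#'
#' A zero-phase 2nd-order Butterworth low-pass (default 10 Hz) is applied
#' after the COP computation; set `lowpass = FALSE` for the raw centroid.
#'
#' @param record a [session_record()].
#' @param geometry a [plate_geometry()].
#' @param lowpass logical, apply the zero-phase low-pass filter.
#' @param cutoff_hz low-pass corner frequency, Hz.
#' @return object of class `cop_trace` with `time_ms`, `x`, `y`, `z` and
#'   `sampling_rate`.
#' @export
compute_cop <- function(record, geometry = plate_geometry(), lowpass = TRUE,
                        cutoff_hz = 10) {
  ch <- record$channels
  fz <- ch$fz1 + ch$fz2 + ch$fz3 + ch$fz4
  bad <- which(fz <= 0)
  if (length(bad))
    lp_stop("nonpositive_force",
            "total vertical force is not positive at sample %d", bad[1])
  a <- geometry$half_width; b <- geometry$half_depth
  x <- a * (ch$fz1 - ch$fz2 - ch$fz3 + ch$fz4) / fz
  y <- b * (ch$fz1 + ch$fz2 - ch$fz3 - ch$fz4) / fz
  if (!is.null(ch$fx)) x <- x - geometry$surface_height * ch$fx / fz
  if (!is.null(ch$fy)) y <- y - geometry$surface_height * ch$fy / fz
  z <- fz / median(fz) - 1
  if (lowpass) {
    wn <- cutoff_hz / (record$sampling_rate / 2)
    if (wn < 1) {
      bf <- signal::butter(2, wn)
      x <- signal::filtfilt(bf, x)
      y <- signal::filtfilt(bf, y)
      z <- signal::filtfilt(bf, z)
    }
  }
  n <- length(x)
  structure(list(time_ms = (seq_len(n) - 1) * 1000 / record$sampling_rate,
                 x = x, y = y, z = z,
                 sampling_rate = record$sampling_rate),
            class = "cop_trace")
}

#' Quiet-stance baseline position
#'
#' Per-axis mean COP over a time window, used as the pre-liftoff reference.
#'
#' @param cop a `cop_trace`.
#' @param window_ms two-element vector, ms (closed interval).
#' @return named vector `c(x0, y0)` in cm.
#' @export
quiet_stance_baseline <- function(cop, window_ms) {
  w <- cop$time_ms >= window_ms[1] & cop$time_ms <= window_ms[2]
  if (!any(w)) lp_stop("empty_window", "baseline window contains no samples")
  c(x0 = mean(cop$x[w]), y0 = mean(cop$y[w]))
}
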