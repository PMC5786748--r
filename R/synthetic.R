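## Synthetic session generator ------------------------------------------------

.lp_groups <- c("CTR", "IPD", "PSP")
.lp_conditions <- c("EO", "EC")

#' Construct a session record
#'
#' A session record holds the uniformly sampled multichannel recording of one
#' 30-s platform session: the four vertical force-sensor channels (`fz1` ..
#' `fz4`, N), the barbell accelerometer channel (`acc`, g), optional shear
#' channels (`fx`, `fy`, N), plus a manifest describing subject, group,
#' viewing condition, barbell mass and accelerometer calibration.
#'
#' @param channels named list of equal-length numeric vectors; must contain
#'   `fz1`..`fz4` and `acc`; unknown channels are preserved.
#' @param manifest named list with at least `subject_id`, `group` (one of
#'   CTR/IPD/PSP), `condition` (EO/EC), `barbell_mass` (0.5 or 1 kg) and
#'   `calibration` (accelerometer readings at 0 and 90 degrees).
#' @param sampling_rate sampling rate in Hz.
#' @return an object of class `session_record`.
#' @export
session_record <- function(channels, manifest, sampling_rate = 40) {
  rec <- structure(list(sampling_rate = sampling_rate, channels = channels,
                        manifest = manifest), class = "session_record")
  validate_session(rec)
}

validate_session <- function(rec) {
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    lp_stop("bad_rate", "sampling_rate must be positive")
  required <- c("fz1", "fz2", "fz3", "fz4", "acc")
  missing <- setdiff(required, names(rec$channels))
  if (length(missing))
    lp_stop("missing_channel", "missing channel: %s",
            paste(missing, collapse = ", "))
  lens <- vapply(rec$channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    lp_stop("ragged_channels", "channels have unequal lengths (%s)",
            paste(unique(lens), collapse = ", "))
  mf <- rec$manifest
  if (!is.null(mf$group) && !mf$group %in% .lp_groups)
    lp_stop("bad_vocab", "unknown group '%s' (expected %s)", mf$group,
            paste(.lp_groups, collapse = "/"))
  if (!is.null(mf$condition) && !mf$condition %in% .lp_conditions)
    lp_stop("bad_vocab", "unknown condition '%s' (expected EO/EC)",
            mf$condition)
  cal <- mf$calibration
  if (!is.null(cal) && length(cal) == 2 && cal[1] == cal[2])
    lp_stop("bad_calibration", "calibration readings a0 and a1 must differ")
  rec
}

#' @export
print.session_record <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<session_record %s %s/%s: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$manifest$subject_id %||% "?", x$manifest$group %||% "?",
              x$manifest$condition %||% "?", length(x$channels), n,
              x$sampling_rate, n / x$sampling_rate))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Distribute total vertical force over the four sensors so that their
## force-weighted centroid reproduces the requested COP path exactly.
synth_forces <- function(x, y, z, tpl, geometry) {
  w_n <- (tpl$subject_mass_kg + tpl$barbell_mass_kg) * 9.80665
  fz <- w_n * (1 + z)
  a <- geometry$half_width; b <- geometry$half_depth
  list(
    fz1 = fz / 4 * (1 + x / a + y / b),
    fz2 = fz / 4 * (1 - x / a + y / b),
    fz3 = fz / 4 * (1 - x / a - y / b),
    fz4 = fz / 4 * (1 + x / a - y / b)
  )
}

## Injected per-trial metric values, computed from the closed-form curves on
## the analysis grid; this is the oracle the pipeline is tested against.
truth_from_template <- function(tpl) {
  tau <- seq(-1000, 4975, by = 25)
  cp <- cop_template(tpl, tau)
  b <- tpl$barbell$time_to_90
  hold <- tau >= b & tau < 5000
  dist <- sqrt(cp$x^2 + cp$y^2)
  list(
    marker_a_ms = tpl$barbell$peak_omega_latency,
    marker_b_ms = b,
    cpa_amp_cm = tpl$sagittal$peak_amp,
    cpa_latency_ms = tpl$sagittal$peak_latency,
    offset_end_cm = dist[length(dist)],
    min_offset_hold_cm = min(dist[hold]),
    osc_freq_hz = tpl$oscillation$freq,
    peak_omega_dps = tpl$barbell$peak_omega,
    end_offset_cm = tpl$sagittal$end_offset
  )
}

#' Generate one noise-controlled lift trial
#'
#' Produces the channel segments of a single lift over the -1000..+5000 ms
#' analysis window: four vertical force channels whose weighted centroid is
#' the template COP path plus white noise, and an accelerometer trace
#' consistent with the angle profile (gravity component `g * sin(theta)` plus
#' a one-sample negative jerk transient at onset).
#'
#' @param template a [group_template()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return list with `time_ms`, `channels` (fz1..fz4, acc), `truth` (the
#'   injected landmark values) and the template.
#' @export
generate_trial <- function(template, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_template(template)
  tau <- seq(-1000, 4975, by = 25)
  cp <- cop_template(template, tau)
  ns <- template$noise
  x <- cp$x + rnorm(length(tau), 0, ns$cop_sd)
  y <- cp$y + rnorm(length(tau), 0, ns$cop_sd)
  z <- cp$z + rnorm(length(tau), 0, ns$z_sd)
  th <- theta_template(template, tau)
  cal <- template$calibration
  acc <- cal[1] + (cal[2] - cal[1]) * sin(th * pi / 180) +
    rnorm(length(tau), 0, ns$acc_sd)
  acc[tau == 0] <- acc[tau == 0] - template$jerk_amp_g
  ch <- synth_forces(x, y, z, template, plate_geometry())
  ch$acc <- acc
  list(time_ms = tau, channels = ch,
       truth = c(list(onset_ms = 0), truth_from_template(template)),
       template = template)
}

#' Generate a 30-s platform session
#'
#' One 30-s record at `rate` Hz containing `n_lifts` self-paced lifts at
#' randomized onset times (separated by well over 6.5 s so that consecutive
#' lift-hold-lower cycles do not overlap), with the session manifest filled
#' in and a ground-truth sidecar listing every injected onset.
#'
#' @param template a [group_template()].
#' @param n_lifts number of lifts (>= 1); an error is raised when that many
#'   6-s analysis windows cannot fit into 30 s.
#' @param condition viewing condition, `"EO"` or `"EC"`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param subject_id identifier stored in the manifest.
#' @param duration_s record duration, s.
#' @param rate sampling rate, Hz.
#' @return list with components `record` (a [session_record()]) and `truth`
#'   (list with `onset_ms` and the injected metric values).
#' @export
generate_session <- function(template, n_lifts = 3,
                             condition = c("EO", "EC"), seed = NULL,
                             subject_id = "S01", duration_s = 30, rate = 40) {
  condition <- match.arg(condition)
  if (!is.null(seed)) set.seed(seed)
  validate_template(template)
  if (n_lifts < 1) lp_stop("infeasible_lifts", "n_lifts must be >= 1")
  first <- c(1300, 2000)          # ms window for the first onset
  gap <- c(10000, 10800)          # ms window for inter-onset separation
  if (first[1] + (n_lifts - 1) * gap[1] + 5000 > duration_s * 1000)
    lp_stop("infeasible_lifts",
            "%d lifts with 6-s analysis windows do not fit into %g s",
            n_lifts, duration_s)
  dt <- 1000 / rate
  onsets <- cumsum(c(runif(1, first[1], first[2]),
                     if (n_lifts > 1) runif(n_lifts - 1, gap[1], gap[2])))
  onsets <- round(onsets / dt) * dt
  n <- duration_s * rate
  t_ms <- (seq_len(n) - 1) * dt

  x <- y <- z <- th <- numeric(n)
  b <- template$barbell$time_to_90
  for (o in onsets) {
    idx <- which(t_ms >= o - 1000 & t_ms <= o + b + 6500)
    tau <- t_ms[idx] - o
    cp <- cop_template(template, tau)
    x[idx] <- x[idx] + cp$x
    y[idx] <- y[idx] + cp$y
    z[idx] <- z[idx] + cp$z
    th[idx] <- th[idx] + theta_template(template, tau)
  }
  ns <- template$noise
  x <- x + rnorm(n, 0, ns$cop_sd)
  y <- y + rnorm(n, 0, ns$cop_sd)
  z <- z + rnorm(n, 0, ns$z_sd)
  cal <- template$calibration
  acc <- cal[1] + (cal[2] - cal[1]) * sin(th * pi / 180) +
    rnorm(n, 0, ns$acc_sd)
  acc[t_ms %in% onsets] <- acc[t_ms %in% onsets] - template$jerk_amp_g
  ch <- synth_forces(x, y, z, template, plate_geometry())
  ch$acc <- acc

  rec <- session_record(ch, manifest = list(
    subject_id = subject_id, group = template$group, condition = condition,
    barbell_mass = template$barbell_mass_kg,
    calibration = unname(template$calibration),
    subject_mass = template$subject_mass_kg
  ), sampling_rate = rate)
  list(record = rec,
       truth = list(onset_ms = onsets, metrics = truth_from_template(template)))
}

#' Generate a synthetic cohort
#'
#' Simulates `sizes[i]` subjects of each requested group.  Each subject gets
#' an individually jittered template (see [jitter_template()]) so that
#' between-subject variance is non-zero, and performs `n_sessions` 30-s
#' sessions alternating eyes-open / eyes-closed (EO, EC, EO, ...), each with
#' `n_lifts` lifts.
#'
#' @param sizes integer vector of group sizes (recycled against `groups`).
#' @param groups character vector of group labels.
#' @param seed integer seed controlling the whole cohort; identical seeds
#'   give identical cohorts.
#' @param n_sessions sessions per subject (default 20: 10 EO + 10 EC).
#' @param n_lifts lifts per session.
#' @param jitter_sd between-subject jitter SD passed to [jitter_template()];
#'   0 gives every subject the group template exactly.
#' @param template_args named list of overrides passed to [group_template()]
#'   (e.g. `list(noise = list(cop_sd = 0))` for noise-free cohorts).
#' @return object of class `lift_cohort`: list of subjects, each with
#'   `subject_id`, `group`, `template`, `truth` (injected metrics) and
#'   `sessions` (list of `record` + `truth` pairs).
#' @examples
#' coh <- generate_cohort(2, "CTR", seed = 1, n_sessions = 2)
#' length(coh$subjects)
#' @export
generate_cohort <- function(sizes, groups = c("CTR", "IPD", "PSP"), seed = 1,
                            n_sessions = 20, n_lifts = 3, jitter_sd = 0.05,
                            template_args = list()) {
  if (any(sizes < 1)) lp_stop("bad_cohort", "group sizes must be >= 1")
  n_grp <- max(length(sizes), length(groups))
  sizes <- rep_len(sizes, n_grp)
  groups <- rep_len(groups, n_grp)
  set.seed(seed)
  subjects <- list()
  for (gi in seq_len(n_grp)) {
    g <- groups[gi]
    base <- do.call(group_template, c(list(group = g), template_args))
    for (s in seq_len(sizes[gi])) {
      tpl <- if (jitter_sd > 0) jitter_template(base, jitter_sd) else base
      sid <- sprintf("%s%02d", g, s)
      sessions <- lapply(seq_len(n_sessions), function(i) {
        generate_session(tpl, n_lifts = n_lifts,
                         condition = .lp_conditions[(i - 1) %% 2 + 1],
                         subject_id = sid)
      })
      subjects[[sid]] <- list(subject_id = sid, group = g, template = tpl,
                              truth = truth_from_template(tpl),
                              sessions = sessions)
    }
  }
  structure(list(subjects = subjects, seed = seed), class = "lift_cohort")
}

#' @export
print.lift_cohort <- function(x, ...) {
  grp <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("<lift_cohort: %d subjects (%s), seed %s>\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", names(grp), grp), collapse = ", "),
              format(x$seed)))
  invisible(x)
}
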