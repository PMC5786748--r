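## Synthetic group templates --------------------------------------------------
##
## A template is a closed-form description of the average postural response of
## one subject group (CTR, IPD, PSP) to a single self-triggered barbell lift,
## expressed as sums of raised-cosine segments (COP axes) plus a gamma-shaped
## angular-velocity pulse for the barbell.  Closed form means every curve can
## be evaluated exactly at any time, which is what makes the generator usable
## as a ground-truth oracle for the whole pipeline.

## Shape parameter of the gamma-shaped angular-velocity pulse.  Chosen so that
## with peak angular velocity at 400 ms the barbell angle crosses 95% of its
## 90-degree plateau at 1200 ms (the control-group landmark latencies).
.lp_alpha <- 2.1956

#' Postural response template for one subject group
#'
#' Builds the parametric single-lift response template for healthy controls
#' (`CTR`), idiopathic Parkinson's disease (`IPD`) or progressive supranuclear
#' palsy (`PSP`).  The defaults encode the published group signatures: controls
#' show a forward COP peak at 1200 ms that settles back to within 1 cm of the
#' pre-lift position, with a rightward excursion during arm acceleration and a
#' compensatory leftward lean while the weight is held; PSP show a faster,
#' harder-braked lift, a sagittally aligned forward overshoot that stays 2-4 cm
#' forward, no leftward lean, and 1.3-Hz lateral/vertical oscillations; IPD
#' show a backward dip at onset, a delayed forward push peaking about 1.4 s
#' after PSP, a 0.3-Hz lateral oscillation and a final offset beyond 4 cm.
#'
#' All times are ms relative to lift onset, amplitudes in cm (COP) or g
#' (accelerometer).  Any element of the parameter lists can be overridden.
#'
#' @param group `"CTR"`, `"IPD"` or `"PSP"`.
#' @param sagittal,lateral,oscillation,barbell,noise named lists overriding
#'   individual template fields, see Details.
#' @param jerk_amp_g amplitude (g) of the one-sample negative transient added
#'   to the accelerometer signal at motion onset; this is what makes the
#'   "first negative peak of the acceleration derivative" trigger well posed.
#' @param subject_mass_kg,barbell_mass_kg masses used to scale the vertical
#'   force channels.
#'
#' @details Fields: `sagittal` has `dip_amp` (backward dip, cm), `peak_amp`
#'   (forward peak, cm), `peak_latency` (ms), `end_offset` (cm at the end of
#'   the 5-s hold) and `decay_dur` (ms of the post-peak settling phase).
#'   `lateral` has `excursion` (signed rightward excursion during arm
#'   acceleration), `exc_win`, `lean` (magnitude of the leftward hold-phase
#'   lean), `lean_on`, `lean_off`.  `oscillation` has `freq` (Hz), `amp` (cm,
#'   lateral), `amp_z` (dimensionless, vertical), `axes`, `onset` and `ramp`
#'   (ms).  `barbell` has `peak_omega_latency` (ms).  `noise` has `cop_sd`
#'   (cm), `z_sd` (dimensionless) and `acc_sd` (g).
#'
#' @return An object of class `group_template`.
#' @examples
#' tpl <- group_template("CTR")
#' curve <- cop_template(tpl, seq(-1000, 4975, by = 25))
#' max(curve$y)  # forward peak amplitude, cm
#' @export
group_template <- function(group = c("CTR", "IPD", "PSP"),
                           sagittal = list(), lateral = list(),
                           oscillation = list(), barbell = list(),
                           noise = list(), jerk_amp_g = 0.12,
                           subject_mass_kg = 75, barbell_mass_kg = 1) {
  group <- match.arg(group)
  def <- .lp_template_defaults[[group]]
  tpl <- list(
    group = group,
    sagittal = modifyList(def$sagittal, sagittal),
    lateral = modifyList(def$lateral, lateral),
    oscillation = modifyList(def$oscillation, oscillation),
    barbell = modifyList(def$barbell, barbell),
    noise = modifyList(list(cop_sd = 0.15, z_sd = 0.003, acc_sd = 3e-4),
                       noise),
    jerk_amp_g = jerk_amp_g,
    subject_mass_kg = subject_mass_kg,
    barbell_mass_kg = barbell_mass_kg,
    calibration = c(a0 = 0, a1 = 1)
  )
  class(tpl) <- "group_template"
  validate_template(build_template(tpl))
}

.lp_template_defaults <- list(
  CTR = list(
    sagittal = list(dip_amp = 0, peak_amp = 2.0, peak_latency = 1200,
                    end_offset = 0.5, rise_end = 1000, bump_half = 900,
                    latency_ref = 1200),
    lateral = list(excursion = 0.6, exc_win = c(0, 500), lean = 0.8,
                   lean_on = c(700, 1300), lean_off = c(3500, 5000)),
    oscillation = list(freq = 0, amp = 0, amp_z = 0, axes = character(0),
                       onset = 1500, ramp = 600),
    barbell = list(peak_omega_latency = 400)
  ),
  PSP = list(
    sagittal = list(dip_amp = 0, peak_amp = 4.0, peak_latency = 1200,
                    end_offset = 3.0, rise_end = 800, bump_half = 700,
                    latency_ref = 1200),
    lateral = list(excursion = 0.15, exc_win = c(0, 400), lean = 0,
                   lean_on = c(700, 1300), lean_off = c(3500, 5000)),
    oscillation = list(freq = 1.3, amp = 0.45, amp_z = 0.012,
                       axes = c("x", "z"), onset = 1500, ramp = 600),
    ## 1.3x the control peak angular velocity
    barbell = list(peak_omega_latency = 400 / 1.3)
  ),
  IPD = list(
    sagittal = list(dip_amp = 1.0, peak_amp = 5.5, peak_latency = 2600,
                    end_offset = 5.0, rise_end = 1000, bump_half = 800,
                    latency_ref = 2600),
    lateral = list(excursion = 0.4, exc_win = c(0, 700), lean = 0.4,
                   lean_on = c(800, 1600), lean_off = c(3800, 5000)),
    oscillation = list(freq = 0.3, amp = 1.0, amp_z = 0, axes = "x",
                       onset = 1000, ramp = 800),
    ## rigidity: 0.75x the control peak angular velocity
    barbell = list(peak_omega_latency = 400 / 0.75)
  )
)

## Derive the quantities that depend on the primary fields: barbell landmark
## latencies and the raised-cosine knot table of each COP axis.  Called at
## construction and again after jitter so the knots always match the fields.
build_template <- function(tpl) {
  ta <- tpl$barbell$peak_omega_latency
  ta_s <- ta / 1000
  tpl$barbell$shape <- .lp_alpha
  ## latency at which the angle crosses 95% of the 90-degree plateau
  tpl$barbell$time_to_90 <- ta * qgamma(0.95, .lp_alpha + 1, .lp_alpha)
  tpl$barbell$peak_omega <- 90 * dgamma(ta_s, .lp_alpha + 1, .lp_alpha / ta_s)
  b <- tpl$barbell$time_to_90

  ## The sagittal curve is a rise to the hold plateau (the end-of-hold
  ## offset) plus a symmetric raised-cosine peak bump centred on the peak
  ## latency, so the curve's maximum sits exactly at that latency and equals
  ## the peak amplitude.  Knot times scale with the (possibly jittered)
  ## latency so jittered subjects keep the group's curve shape.
  sg <- tpl$sagittal
  L <- sg$peak_latency
  fl <- L / sg$latency_ref
  if (tpl$group == "IPD") {
    ## two-phase forward push: fast shoulder, then slow exaggerated lean
    rise <- rbind(
      c(0.84 * sg$end_offset, 300 * fl, 1400 * fl),
      c(0.16 * sg$end_offset, 1400 * fl, 2200 * fl)
    )
  } else {
    rise <- rbind(c(sg$end_offset, 0, sg$rise_end * fl))
  }
  sag_steps <- rbind(
    rise,
    ## return to neutral once the weight is lowered again (outside the
    ## -1000..+5000 ms analysis window)
    c(-sg$end_offset, b + 5000, b + 6500)
  )
  colnames(sag_steps) <- c("amp", "t0", "t1")
  tpl$curves <- list(
    sag_steps = sag_steps,
    sag_peak = c(sg$peak_amp - sg$end_offset,
                 L - sg$bump_half * fl, L + sg$bump_half * fl),
    sag_dip = c(sg$dip_amp, -100, 700),
    lat_steps = rbind(
      c(-tpl$lateral$lean, tpl$lateral$lean_on),
      c(tpl$lateral$lean, tpl$lateral$lean_off)
    ),
    exc = c(tpl$lateral$excursion, tpl$lateral$exc_win),
    ## vertical load transient of the lift (push-off then brake), scaled to
    ## the vigour of the movement
    z_bumps = rbind(
      c(0.010 * tpl$barbell$peak_omega / 128, 0, 500),
      c(-0.008 * tpl$barbell$peak_omega / 128, 500, 1200)
    )
  )
  tpl
}

#' Validate a group template
#'
#' Checks the structural invariants of a [group_template()] and fails with an
#' error naming the offending field.
#' @param tpl a `group_template`.
#' @return `tpl`, invisibly valid.
#' @export
validate_template <- function(tpl) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) lp_stop("invalid_template",
                             "invalid template parameter '%s': %s", field, why)
  }
  chk(tpl$sagittal$peak_latency > 0, "sagittal$peak_latency",
      "forward peak latency must be positive")
  chk(tpl$sagittal$peak_amp >= tpl$sagittal$end_offset,
      "sagittal$end_offset", "end-of-hold offset cannot exceed the peak")
  chk(tpl$barbell$time_to_90 > tpl$barbell$peak_omega_latency,
      "barbell$time_to_90", "time to 90 degrees must follow the velocity peak")
  chk(tpl$oscillation$amp == 0 || tpl$oscillation$freq > 0,
      "oscillation$freq", "frequency must be positive when amplitude > 0")
  chk(all(unlist(tpl$noise) >= 0), "noise", "noise SDs must be non-negative")
  chk(tpl$jerk_amp_g >= 0, "jerk_amp_g", "must be non-negative")
  tpl
}

#' Evaluate the noise-free COP template curves
#'
#' @param tpl a [group_template()].
#' @param tau_ms times in ms relative to lift onset.
#' @return list with components `x` (lateral, cm, rightward positive), `y`
#'   (anteroposterior, cm, forward positive) and `z` (normalized vertical
#'   load deviation, dimensionless).
#' @export
cop_template <- function(tpl, tau_ms) {
  cv <- tpl$curves
  y <- -cv$sag_dip[1] * rcbump(tau_ms, cv$sag_dip[2], cv$sag_dip[3]) +
    cv$sag_peak[1] * rcbump(tau_ms, cv$sag_peak[2], cv$sag_peak[3])
  for (i in seq_len(nrow(cv$sag_steps))) {
    s <- cv$sag_steps[i, ]
    y <- y + s[1] * rcstep(tau_ms, s[2], s[3])
  }
  x <- cv$exc[1] * rcbump(tau_ms, cv$exc[2], cv$exc[3])
  for (i in seq_len(nrow(cv$lat_steps))) {
    s <- cv$lat_steps[i, ]
    x <- x + s[1] * rcstep(tau_ms, s[2], s[3])
  }
  z <- numeric(length(tau_ms))
  for (i in seq_len(nrow(cv$z_bumps))) {
    s <- cv$z_bumps[i, ]
    z <- z + s[1] * rcbump(tau_ms, s[2], s[3])
  }
  os <- tpl$oscillation
  if (os$amp > 0 || os$amp_z > 0) {
    env <- (rcstep(tau_ms, os$onset, os$onset + os$ramp) -
              rcstep(tau_ms, 5000, 6000))
    wave <- env * sin(2 * pi * os$freq * (tau_ms - os$onset) / 1000)
    if ("x" %in% os$axes) x <- x + os$amp * wave
    if ("y" %in% os$axes) y <- y + os$amp * wave
    if ("z" %in% os$axes) z <- z + os$amp_z * wave
  }
  list(x = x, y = y, z = z)
}

#' Evaluate the noise-free barbell angle template
#'
#' The lift is a gamma-shaped angular-velocity pulse (peak at
#' `barbell$peak_omega_latency`) whose integral approaches the 90-degree
#' forward position; after a 5-s hold the weight is lowered back.
#'
#' @inheritParams cop_template
#' @return angle in degrees (0 hanging down, 90 forward horizontal).
#' @export
theta_template <- function(tpl, tau_ms) {
  ta_s <- tpl$barbell$peak_omega_latency / 1000
  a <- tpl$barbell$shape
  b <- tpl$barbell$time_to_90
  th <- 90 * pgamma(tau_ms / 1000, a + 1, a / ta_s)
  th * (1 - rcstep(tau_ms, b + 5200, b + 6200))
}

#' Evaluate the noise-free barbell angular-velocity template
#'
#' Analytic derivative of [theta_template()], in deg/s.
#' @inheritParams cop_template
#' @export
omega_template <- function(tpl, tau_ms) {
  ta_s <- tpl$barbell$peak_omega_latency / 1000
  a <- tpl$barbell$shape
  b <- tpl$barbell$time_to_90
  rise <- 90 * dgamma(tau_ms / 1000, a + 1, a / ta_s)
  cdf <- 90 * pgamma(tau_ms / 1000, a + 1, a / ta_s)
  t0 <- b + 5200; t1 <- b + 6200
  u <- pmin(pmax((tau_ms - t0) / (t1 - t0), 0), 1)
  dstep <- ifelse(tau_ms > t0 & tau_ms < t1,
                  pi / (t1 - t0) * sin(pi * u) / 2 * 1000, 0)
  rise * (1 - rcstep(tau_ms, t0, t1)) - cdf * dstep
}

#' Perturb a template to emulate one subject
#'
#' Applies multiplicative Gaussian jitter (default 5% SD, factors clipped to
#' `clip`) to the main amplitude and latency fields; one factor per curve
#' family so each subject's curves keep the group's shape and ordering.
#' Oscillation frequencies and noise levels are not jittered.
#'
#' @param tpl a [group_template()].
#' @param sd relative SD of the jitter factors.
#' @param clip allowed range for the jitter factors.
#' @return a new `group_template`.  Uses the current RNG stream.
#' @export
jitter_template <- function(tpl, sd = 0.05, clip = c(0.85, 1.15)) {
  f <- function() min(max(1 + rnorm(1, 0, sd), clip[1]), clip[2])
  f_sag_amp <- f(); f_sag_lat <- f(); f_lat_amp <- f()
  f_osc_amp <- f(); f_bar_lat <- f()
  tpl$sagittal$dip_amp <- tpl$sagittal$dip_amp * f_sag_amp
  tpl$sagittal$peak_amp <- tpl$sagittal$peak_amp * f_sag_amp
  tpl$sagittal$end_offset <- tpl$sagittal$end_offset * f_sag_amp
  tpl$sagittal$peak_latency <- tpl$sagittal$peak_latency * f_sag_lat
  tpl$lateral$excursion <- tpl$lateral$excursion * f_lat_amp
  tpl$lateral$lean <- tpl$lateral$lean * f_lat_amp
  tpl$oscillation$amp <- tpl$oscillation$amp * f_osc_amp
  tpl$oscillation$amp_z <- tpl$oscillation$amp_z * f_osc_amp
  tpl$barbell$peak_omega_latency <- tpl$barbell$peak_omega_latency * f_bar_lat
  validate_template(build_template(tpl))
}

#' @export
print.group_template <- function(x, ...) {
  cat(sprintf("<group_template %s>\n", x$group))
  cat(sprintf("  forward peak     : %.2f cm at %.0f ms (end offset %.2f cm)\n",
              x$sagittal$peak_amp, x$sagittal$peak_latency,
              x$sagittal$end_offset))
  cat(sprintf("  lateral          : excursion %+.2f cm, lean %.2f cm\n",
              x$lateral$excursion, x$lateral$lean))
  if (x$oscillation$amp > 0 || x$oscillation$amp_z > 0)
    cat(sprintf("  oscillation      : %.2f Hz on %s from %.0f ms\n",
                x$oscillation$freq, paste(x$oscillation$axes, collapse = ","),
                x$oscillation$onset))
  cat(sprintf("  barbell          : peak omega %.0f deg/s at %.0f ms, 90 deg at %.0f ms\n",
              x$barbell$peak_omega, x$barbell$peak_omega_latency,
              x$barbell$time_to_90))
  invisible(x)
}
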