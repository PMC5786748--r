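## Segmentation and grand averaging ------------------------------------------

.lp_seg_time <- function(rate = 40) seq(-1000, 5000 - 1000 / rate,
                                        by = 1000 / rate)

#' Cut per-lift segments around each onset
#'
#' Extracts, for every accepted lift event, the half-open analysis window
#' [-1000, +5000) ms around the detected onset (240 samples at 40 Hz) from
#' the COP and barbell traces.  Events whose window overruns the record edges
#' are dropped; the dropped onsets and reasons are attached as attribute
#' `"dropped"`.
#'
#' @param cop a `cop_trace` from [compute_cop()].
#' @param theta,omega record-level barbell angle (deg) and angular velocity
#'   (deg/s).
#' @param onsets_ms onset times, ms.
#' @param meta named list with `subject_id`, `group`, `condition`.
#' @return list of `postural_segment` objects (fields `time_ms`, `x`, `y`,
#'   `z`, `theta`, `omega`, `subject_id`, `group`, `condition`, `onset_ms`,
#'   `accepted`).
#' @export
segment_trials <- function(cop, theta, omega, onsets_ms, meta = list()) {
  rate <- cop$sampling_rate
  dt <- 1000 / rate
  n <- length(cop$x)
  pre <- 1000 / dt                  # samples before onset
  len <- 6000 / dt                  # total samples
  segs <- list()
  dropped <- data.frame(onset_ms = numeric(0), reason = character(0))
  for (o in onsets_ms) {
    i0 <- round(o / dt) + 1 - pre
    idx <- seq(i0, length.out = len)
    if (idx[1] < 1 || idx[len] > n) {
      dropped <- rbind(dropped,
                       data.frame(onset_ms = o, reason = "window-overrun"))
      next
    }
    segs[[length(segs) + 1L]] <- structure(list(
      time_ms = .lp_seg_time(rate),
      x = cop$x[idx], y = cop$y[idx], z = cop$z[idx],
      theta = theta[idx], omega = omega[idx],
      subject_id = meta$subject_id %||% NA_character_,
      group = meta$group %||% NA_character_,
      condition = meta$condition %||% NA_character_,
      onset_ms = o, accepted = TRUE, sampling_rate = rate
    ), class = "postural_segment")
  }
  attr(segs, "dropped") <- dropped
  segs
}

#' Baseline-correct a segment
#'
#' Subtracts the per-axis mean of the `window_ms` (default the first 100 ms
#' of the segment, [-1000, -900] ms) from the COP axes, so that every trial
#' is expressed relative to its own pre-liftoff stance.  The window precedes
#' the four pre-onset analysis windows, which therefore stay untouched.
#'
#' @param seg a `postural_segment`.
#' @param window_ms closed baseline interval, ms.
#' @return the corrected segment.
#' @export
baseline_correct <- function(seg, window_ms = c(-1000, -900)) {
  w <- seg$time_ms >= window_ms[1] & seg$time_ms <= window_ms[2]
  if (!any(w)) lp_stop("empty_window", "baseline window contains no samples")
  for (ax in c("x", "y", "z")) seg[[ax]] <- seg[[ax]] - mean(seg[[ax]][w])
  seg
}

#' Two-stage grand average with pointwise confidence band
#'
#' Trials are first averaged within each subject, then subject means are
#' averaged across subjects; the pointwise band is the t-based interval on
#' the subject means, `mean +/- t_(ci_level, n-1) * SE`, so the subject (not
#' the trial) is the unit of inference, matching the repeated-measures
#' design.  `ci_level` is the per-bound level: the default 0.975 gives a
#' two-sided 95% band.
#'
#' @param segments list of (baseline-corrected) `postural_segment`s of one
#'   group/condition cell.
#' @param ci_level one-sided coverage of each bound.
#' @param axes which traces to average.
#' @return object of class `grand_average`: per-axis `mean`/`lo`/`hi`
#'   matrices plus `time_ms`, `n_subjects`, `n_trials`, `ci_level`; the band
#'   is `NA` (and `flagged` is `TRUE`) with fewer than 2 subjects.
#' @export
grand_average <- function(segments, ci_level = 0.975,
                          axes = c("x", "y", "z", "theta", "omega")) {
  if (!length(segments)) lp_stop("no_segments", "no segments to average")
  if (ci_level <= 0.5 || ci_level >= 1)
    lp_stop("bad_ci", "ci_level must be in (0.5, 1)")
  subj <- vapply(segments, `[[`, "", "subject_id")
  time_ms <- segments[[1]]$time_ms
  out <- list(time_ms = time_ms, axes = list(),
              n_subjects = length(unique(subj)), n_trials = length(segments),
              ci_level = ci_level, flagged = length(unique(subj)) < 2,
              group = segments[[1]]$group)
  for (ax in axes) {
    tr <- vapply(segments, `[[`, numeric(length(time_ms)), ax)
    ## stage 1: trials -> subject means (columns: subjects)
    sm <- vapply(split(seq_along(subj), subj),
                 function(ii) rowMeans(tr[, ii, drop = FALSE]),
                 numeric(length(time_ms)))
    m <- rowMeans(sm)
    ns <- ncol(sm)
    if (ns >= 2) {
      se <- apply(sm, 1, sd) / sqrt(ns)
      tq <- qt(ci_level, ns - 1)
      lo <- m - tq * se; hi <- m + tq * se
    } else {
      lo <- hi <- rep(NA_real_, length(m))
    }
    out$axes[[ax]] <- list(mean = m, lo = lo, hi = hi)
  }
  class(out) <- "grand_average"
  out
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("<grand_average%s: %d subjects, %d trials, axes %s, band %.1f%%>\n",
              if (!is.na(x$group)) paste0(" ", x$group) else "",
              x$n_subjects, x$n_trials,
              paste(names(x$axes), collapse = "/"),
              100 * (2 * x$ci_level - 1)))
  invisible(x)
}

#' Plot a grand average
#'
#' One panel per axis: grand-average mean with the shaded pointwise
#' confidence band, time locked to lift onset.
#'
#' @param x a `grand_average`.
#' @param axes axes to draw.
#' @param col trace colour.
#' @param ... passed to [graphics::plot()].
#' @export
plot.grand_average <- function(x, axes = c("y", "x", "z"), col = "black",
                               ...) {
  old <- graphics::par(mfrow = c(length(axes), 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  labs <- c(x = "lateral COP (cm)", y = "anteroposterior COP (cm)",
            z = "vertical load (norm.)", theta = "barbell angle (deg)",
            omega = "angular velocity (deg/s)")
  for (ax in axes) {
    a <- x$axes[[ax]]
    ylim <- range(a$mean, a$lo, a$hi, na.rm = TRUE)
    graphics::plot(x$time_ms, a$mean, type = "n", ylim = ylim,
                   xlab = "time from lift onset (ms)",
                   ylab = labs[[ax]] %||% ax, ...)
    if (!all(is.na(a$lo)))
      graphics::polygon(c(x$time_ms, rev(x$time_ms)), c(a$lo, rev(a$hi)),
                        col = grDevices::adjustcolor(col, 0.2), border = NA)
    graphics::lines(x$time_ms, a$mean, col = col)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}

#' Top-view COP path of a grand average
#'
#' Draws the averaged lateral-vs-anteroposterior COP trajectory over the
#' whole segment, with the final (+5 s) position circled.
#'
#' @param ga a `grand_average` (or a list of them to overlay).
#' @param col colour(s).
#' @export
plot_cop_path <- function(ga, col = c("black", "blue", "red")) {
  if (inherits(ga, "grand_average")) ga <- list(ga)
  xs <- unlist(lapply(ga, function(g) g$axes$x$mean))
  ys <- unlist(lapply(ga, function(g) g$axes$y$mean))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys), asp = 1,
                 xlab = "lateral COP (cm)", ylab = "anteroposterior COP (cm)")
  for (i in seq_along(ga)) {
    g <- ga[[i]]
    graphics::lines(g$axes$x$mean, g$axes$y$mean, col = col[i])
    n <- length(g$axes$x$mean)
    graphics::points(g$axes$x$mean[n], g$axes$y$mean[n], col = col[i],
                     cex = 1.6)
  }
  invisible(ga)
}
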