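## End-to-end pipeline -------------------------------------------------------

#' Pipeline configuration
#'
#' Collects and validates every tunable of the simulate -> detect -> segment
#' -> metrics -> stats chain.  Validation happens before any computation;
#' invalid fields raise classed errors.
#'
#' @param groups named integer vector of simulated group sizes.
#' @param seed base seed; group `i` of a simulated study uses `seed + i - 1`.
#' @param n_sessions,n_lifts,jitter_sd cohort design, see
#'   [generate_cohort()].
#' @param ci_level per-bound confidence level of grand-average bands.
#' @param alpha significance level of the group statistics.
#' @param lowpass,cutoff_hz COP filtering, see [compute_cop()].
#' @param detection named list of [detect_lift_onsets()] overrides.
#' @param out_dir optional output directory for written artifacts.
#' @return validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(groups = c(CTR = 16, IPD = 15, PSP = 17),
                            seed = 7, n_sessions = 20, n_lifts = 3,
                            jitter_sd = 0.05, ci_level = 0.975,
                            alpha = 0.05, lowpass = TRUE, cutoff_hz = 10,
                            detection = list(), out_dir = NULL) {
  cfg <- list(groups = groups, seed = seed, n_sessions = n_sessions,
              n_lifts = n_lifts, jitter_sd = jitter_sd,
              ci_level = ci_level, alpha = alpha, lowpass = lowpass,
              cutoff_hz = cutoff_hz, detection = detection,
              out_dir = out_dir)
  if (is.null(names(cfg$groups)) || !all(names(cfg$groups) %in% .lp_groups))
    lp_stop("bad_config", "groups must be named with labels from %s",
            paste(.lp_groups, collapse = "/"))
  if (any(cfg$groups < 1)) lp_stop("bad_config", "group sizes must be >= 1")
  if (cfg$ci_level <= 0.5 || cfg$ci_level >= 1)
    lp_stop("bad_config", "ci_level must be in (0.5, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    lp_stop("bad_config", "alpha must be in (0, 1)")
  if (cfg$n_sessions < 1 || cfg$n_lifts < 1)
    lp_stop("bad_config", "n_sessions and n_lifts must be >= 1")
  if (cfg$jitter_sd < 0) lp_stop("bad_config", "jitter_sd must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Analyse one session record
#'
#' COP computation, angle calibration, onset detection, event building,
#' segmentation, baseline correction and trial acceptance for a single
#' 30-s record.
#'
#' @param record a [session_record()].
#' @param geometry a [plate_geometry()].
#' @param lowpass,cutoff_hz COP filtering.
#' @param detection list of [detect_lift_onsets()] overrides.
#' @return list with `segments` (accepted, baseline-corrected), `events`,
#'   `qc` (one row per detected onset with acceptance and reason).
#' @export
analyze_session <- function(record, geometry = plate_geometry(),
                            lowpass = TRUE, cutoff_hz = 10,
                            detection = list()) {
  rate <- record$sampling_rate
  cal <- unlist(record$manifest$calibration) %||% c(0, 1)
  cop <- compute_cop(record, geometry, lowpass = lowpass,
                     cutoff_hz = cutoff_hz)
  theta <- calibrate_angle(record$channels$acc, cal)
  omega <- angular_velocity(theta, rate)
  onsets <- do.call(detect_lift_onsets,
                    c(list(acc_raw = record$channels$acc, rate = rate,
                           calibration = cal), detection))
  events <- lift_events(theta, omega, onsets, rate)
  meta <- record$manifest[c("subject_id", "group", "condition")]
  segs <- segment_trials(cop, theta, omega, onsets, meta = meta)
  dropped <- attr(segs, "dropped")
  kept_onsets <- vapply(segs, `[[`, numeric(1), "onset_ms")
  events <- events[onsets %in% kept_onsets]

  qc <- data.frame(onset_ms = numeric(0), accepted = logical(0),
                   reason = character(0))
  accepted <- list()
  kept_events <- list()
  for (i in seq_along(segs)) {
    seg <- baseline_correct(segs[[i]])
    dec <- accept_trial(events[[i]], seg$theta, seg$time_ms)
    qc <- rbind(qc, data.frame(onset_ms = seg$onset_ms,
                               accepted = dec$accepted,
                               reason = dec$reason %||% NA_character_))
    if (dec$accepted) {
      accepted[[length(accepted) + 1L]] <- seg
      kept_events[[length(kept_events) + 1L]] <- events[[i]]
    }
  }
  if (nrow(dropped))
    qc <- rbind(qc, data.frame(onset_ms = dropped$onset_ms, accepted = FALSE,
                               reason = dropped$reason))
  list(segments = accepted, events = kept_events, qc = qc)
}

#' Analyse a cohort of one or more groups
#'
#' Runs [analyze_session()] over every session of every subject, pools the
#' accepted segments, and per group forms the grand average (conditions
#' pooled), re-detects the grand-average markers "a"/"b", and computes the
#' grand-average metric set and the per-trial metrics table.
#'
#' @param cohort a [generate_cohort()] result, or any list of subjects with
#'   the same layout (e.g. assembled from [read_session()] records).
#' @param ci_level per-bound confidence level for the bands.
#' @param ... passed on to [analyze_session()].
#' @return list with `ga` (named list of grand averages per group),
#'   `markers` (per group), `ga_metrics` (data.frame, one row per group),
#'   `trial_metrics` (data.frame), `counts` (QC accounting per group).
#' @export
analyze_cohort <- function(cohort, ci_level = 0.975, ...) {
  subjects <- cohort$subjects %||% cohort
  segs <- list()
  qc <- list()
  metrics <- list()
  for (sub in subjects) {
    for (sess in sub$sessions) {
      rec <- sess$record %||% sess
      res <- analyze_session(rec, ...)
      qc[[length(qc) + 1L]] <-
        cbind(subject_id = rec$manifest$subject_id %||% sub$subject_id,
              group = rec$manifest$group %||% sub$group, res$qc)
      for (i in seq_along(res$segments)) {
        segs[[length(segs) + 1L]] <- res$segments[[i]]
        metrics[[length(metrics) + 1L]] <-
          trial_metrics(res$segments[[i]], res$events[[i]])
      }
    }
  }
  qc <- do.call(rbind, qc)
  metrics <- do.call(rbind, metrics)
  groups <- unique(vapply(segs, `[[`, "", "group"))

  ga <- list(); markers <- list(); ga_metrics <- list()
  for (g in groups) {
    gsegs <- segs[vapply(segs, `[[`, "", "group") == g]
    gga <- grand_average(gsegs, ci_level = ci_level)
    mk <- detect_markers(gga$axes$omega$mean, gga$axes$theta$mean,
                         gga$time_ms)
    offs <- return_offsets(gga, mk$marker_b_ms)
    peak <- cpa_peak(gga)
    lat <- lateral_phase_indices(gga, mk$marker_a_ms)
    osc_x <- oscillation_frequency(gga, axis = "x")
    osc_z <- oscillation_frequency(gga, axis = "z")
    kin <- kinematic_indices(gga$axes$omega$mean, gga$time_ms,
                             mk$marker_a_ms, mk$marker_b_ms)
    ga[[g]] <- gga
    markers[[g]] <- mk
    ga_metrics[[g]] <- data.frame(
      group = g, n_subjects = gga$n_subjects, n_trials = gga$n_trials,
      marker_a_ms = mk$marker_a_ms, marker_b_ms = mk$marker_b_ms,
      cpa_peak_amp = peak$amplitude_cm, cpa_peak_latency = peak$latency_ms,
      offset_at_5000 = offs$offset_at_5000,
      min_offset_hold = offs$min_offset_hold,
      lateral_accel_excursion = lat$lateral_accel_excursion,
      lateral_lean_1000_3000 = lat$lateral_lean_1000_3000,
      osc_x_freq = osc_x$frequency_hz, osc_x_confidence = osc_x$confidence,
      osc_z_freq = osc_z$frequency_hz, osc_z_confidence = osc_z$confidence,
      peak_omega = kin$peak_omega, initial_accel = kin$initial_accel,
      braking = kin$braking, stringsAsFactors = FALSE
    )
  }
  list(ga = ga, markers = markers,
       ga_metrics = do.call(rbind, ga_metrics),
       trial_metrics = metrics, qc = qc,
       counts = qc_counts(qc))
}

qc_counts <- function(qc) {
  if (is.null(qc) || !nrow(qc)) return(NULL)
  agg <- stats::aggregate(onset_ms ~ group + accepted, data = qc, FUN = length)
  names(agg)[3] <- "n"
  agg
}

#' Aggregate per-trial metrics to subject x condition means
#'
#' @param trial_metrics data.frame from [analyze_cohort()].
#' @param metric column to aggregate.
#' @return data.frame with `subject`, `group`, `condition`, `value`.
#' @export
subject_condition_means <- function(trial_metrics, metric) {
  agg <- stats::aggregate(trial_metrics[[metric]],
                          by = list(subject = trial_metrics$subject_id,
                                    group = trial_metrics$group,
                                    condition = trial_metrics$condition),
                          FUN = mean, na.rm = TRUE)
  names(agg)[4] <- "value"
  agg
}

#' Run the full simulate-analyse-report pipeline
#'
#' Simulates the configured cohorts (one seed per group, `seed + i - 1`),
#' analyses them end to end, runs the split-plot ANOVA (group x EO/EC) on
#' the forward-peak amplitude and latency, and assembles a run report whose
#' every number traces back to a metrics-table row or a statistics output.
#' With `out_dir` set, the metrics table, grand averages and the report JSON
#' are written out.
#'
#' @param config a [pipeline_config()].
#' @return object of class `lift_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  cohorts <- lapply(seq_along(config$groups), function(i) {
    generate_cohort(config$groups[i], names(config$groups)[i],
                    seed = config$seed + i - 1,
                    n_sessions = config$n_sessions,
                    n_lifts = config$n_lifts,
                    jitter_sd = config$jitter_sd)
  })
  all_subjects <- unlist(lapply(cohorts, `[[`, "subjects"),
                         recursive = FALSE)
  res <- analyze_cohort(list(subjects = all_subjects),
                        ci_level = config$ci_level,
                        lowpass = config$lowpass,
                        cutoff_hz = config$cutoff_hz,
                        detection = config$detection)

  stats_out <- list()
  if (length(config$groups) >= 2) {
    for (metric in c("cpa_peak_latency", "cpa_peak_amp")) {
      tab <- subject_condition_means(res$trial_metrics, metric)
      stats_out[[metric]] <- split_plot_anova(tab, value = "value",
                                              subject = "subject",
                                              group = "group",
                                              within = "condition")
    }
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("liftpost")),
    seeds = config$seed + seq_along(config$groups) - 1,
    config = unclass(config),
    counts = res$counts,
    landmarks = res$ga_metrics,
    anova = stats_out,
    qc = res$qc
  ), class = "lift_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics(res$trial_metrics,
                  file.path(config$out_dir, "trial_metrics.csv"))
    write_metrics(res$ga_metrics,
                  file.path(config$out_dir, "landmarks.csv"))
    for (g in names(res$ga))
      write_grand_average(res$ga[[g]],
                          file.path(config$out_dir,
                                    sprintf("grand_average_%s.tsv", g)))
    rep_json <- report
    rep_json$anova <- lapply(stats_out, function(a)
      list(table = a$table, epsilon = a$epsilon,
           mauchly_W = a$mauchly$W, mauchly_p = a$mauchly$p.value))
    rep_json$qc <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.lift_report <- function(x, ...) {
  cat(sprintf("liftpost run (v%s, seeds %s)\n", x$version,
              paste(x$seeds, collapse = ",")))
  cat("\nTrial accounting:\n"); print(x$counts, row.names = FALSE)
  cat("\nGrand-average landmarks:\n")
  lm <- x$landmarks
  num <- vapply(lm, is.numeric, logical(1))
  lm[num] <- lapply(lm[num], function(v) signif(v, 4))
  print(lm[, c("group", "marker_a_ms", "marker_b_ms", "cpa_peak_amp",
               "cpa_peak_latency", "offset_at_5000", "min_offset_hold",
               "osc_x_freq")], row.names = FALSE)
  for (m in names(x$anova)) {
    cat(sprintf("\nANOVA on %s:\n", m)); print(x$anova[[m]])
  }
  invisible(x)
}
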