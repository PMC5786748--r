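# Shared fixtures, generated in code and cached per test run.

.lp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lp_cache[[key]])) .lp_cache[[key]] <- force(expr)
  .lp_cache[[key]]
}

# Default study cohorts: the group sizes of the study design (16 controls,
# 15 IPD, 17 PSP) with one fixed seed per group.
default_cohort <- function(group) {
  spec <- switch(group,
                 CTR = list(n = 16, seed = 1),
                 IPD = list(n = 15, seed = 2),
                 PSP = list(n = 17, seed = 3))
  cached(paste0("cohort_", group),
         generate_cohort(spec$n, group, seed = spec$seed))
}

default_analysis <- function(group) {
  cached(paste0("analysis_", group), analyze_cohort(default_cohort(group)))
}

# Small noise-free, jitter-free cohort for oracle-style checks.
noisefree_cohort <- function(group, n = 2, n_sessions = 2, seed = 5) {
  cached(paste0("nf_", group, n, n_sessions, seed),
         generate_cohort(n, group, seed = seed, n_sessions = n_sessions,
                         jitter_sd = 0,
                         template_args = list(noise = list(cop_sd = 0,
                                                           z_sd = 0,
                                                           acc_sd = 0))))
}

noisefree_template <- function(group) {
  group_template(group, noise = list(cop_sd = 0, z_sd = 0, acc_sd = 0))
}

# Build a session_record straight from template curves (no generator noise).
record_from_trial <- function(trial, group = trial$template$group) {
  session_record(trial$channels,
                 manifest = list(subject_id = "T01", group = group,
                                 condition = "EO", barbell_mass = 1,
                                 calibration = c(0, 1)))
}

seg_time <- seq(-1000, 4975, by = 25)

# smooth test waveforms
rcstep_test <- function(t, t0, t1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  (1 - cos(pi * u)) / 2
}
rcbump_test <- function(t, t0, t1) {
  u <- (t - t0) / (t1 - t0)
  ifelse(u > 0 & u < 1, (1 - cos(2 * pi * u)) / 2, 0)
}

# Hand-made segment with prescribed traces (defaults all-zero).
make_segment <- function(x = 0, y = 0, z = 0, theta = 90, omega = 0,
                         subject_id = "S01", group = "CTR",
                         condition = "EO") {
  n <- length(seg_time)
  structure(list(time_ms = seg_time,
                 x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
                 theta = rep_len(theta, n), omega = rep_len(omega, n),
                 subject_id = subject_id, group = group,
                 condition = condition, onset_ms = 0, accepted = TRUE,
                 sampling_rate = 40),
            class = "postural_segment")
}
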