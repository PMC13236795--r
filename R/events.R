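# Event detection and the six per-trial outcome variables.

#' Initial posture
#'
#' Mean anteroposterior centre-of-pressure position over the 500 ms
#' window before face onset, in cm.
#'
#' @param yP CP position, m.
#' @param time time base, s.
#' @param face_onset s.
#' @return initial posture, cm.
#' @export
initial_posture <- function(yP, time, face_onset) {
  idx <- which(time >= face_onset - 0.5 & time < face_onset)
  dt <- if (length(time) > 1) time[2] - time[1] else Inf
  assert_that(length(idx) >= round(0.5 / dt) - 1,
              "need >= 500 ms of pre-onset data", "stepinit_insufficient_baseline")
  mean(yP[idx]) * 100
}

#' Detect the onset of anteroposterior postural modification (t0y)
#'
#' Finds the first backward-directed (negative) local extremum of the CP
#' velocity after face onset whose magnitude exceeds a noise floor, then
#' walks backward from that peak to the last time at which the velocity
#' magnitude was below 10 % of the peak; the crossing is located by
#' linear interpolation between samples. The noise floor defaults to
#' five times the pre-onset standard deviation of the CP velocity, with
#' an absolute floor for noise-free signals.
#'
#' @param yP_vel CP velocity, m/s.
#' @param time time base, s.
#' @param face_onset s.
#' @param search_horizon s after face onset to search (default 2.5).
#' @param noise_mult multiplier on the baseline SD (default 5).
#' @param min_floor absolute minimum peak magnitude, m/s (default 0.005).
#' @param rel_floor minimum peak magnitude as a fraction of the largest
#'   backward velocity excursion in the search window (default 0.2);
#'   rejects small filter-ringing dips that precede a sharp excursion.
#' @return list with `t0y`, `t_peak`, `v_peak` (s, s, m/s). Signals a
#'   classed error `stepinit_no_onset` when no qualifying peak exists.
#' @export
detect_t0y <- function(yP_vel, time, face_onset, search_horizon = 2.5,
                       noise_mult = 5, min_floor = 0.005, rel_floor = 0.2) {
  base <- which(time >= face_onset - 0.5 & time < face_onset)
  floor_v <- max(noise_mult * stats::sd(yP_vel[base]), min_floor)
  win <- which(time > face_onset & time <= face_onset + search_horizon)
  assert_that(length(win) > 2, "empty search window", "stepinit_bad_window")
  i_lo <- win[1]
  i_hi <- win[length(win)]
  idx <- (i_lo + 1):(i_hi - 1)
  v <- yP_vel
  floor_v <- max(floor_v, rel_floor * abs(min(c(v[idx], 0))))
  is_min <- v[idx] < 0 & abs(v[idx]) > floor_v &
    v[idx] <= v[idx - 1] & v[idx] <= v[idx + 1] &
    (v[idx] < v[idx - 1] | v[idx] < v[idx + 1])
  if (!any(is_min)) {
    stop_stepinit("no qualifying backward CP-velocity peak (movement omission)",
                  "stepinit_no_onset")
  }
  i_peak <- idx[which(is_min)[1]]
  th <- -0.10 * abs(v[i_peak])
  before <- i_lo:i_peak
  above <- before[v[before] > th]   # still inside the +-10 % band
  if (length(above) == 0) {
    stop_stepinit("CP velocity never inside the 10 % band before the peak",
                  "stepinit_no_onset")
  }
  j <- max(above)
  if (j >= i_peak) {
    t0y <- time[i_peak]
  } else {
    # linear interpolation of the downward crossing of th in [j, j+1]
    t0y <- time[j] + (th - v[j]) / (v[j + 1] - v[j]) * (time[j + 1] - time[j])
  }
  list(t0y = t0y, t_peak = time[i_peak], v_peak = v[i_peak])
}

#' Reaction time
#'
#' Delay from face onset to the onset of postural modification, ms.
#'
#' @param t0y s.
#' @param face_onset s.
#' @return ms.
#' @export
reaction_time <- function(t0y, face_onset) {
  assert_that(t0y > face_onset, "t0y must follow face onset",
              "stepinit_bad_events")
  (t0y - face_onset) * 1000
}

#' APA duration and amplitude
#'
#' The anticipatory-postural-adjustment phase runs from `t0y` to the
#' first backward peak of the CP (the first local minimum of `yP` after
#' `t0y`). Duration is the elapsed time in ms; amplitude is the signed CP
#' shift from `yP(t0y)` (linearly interpolated) to the peak, in cm
#' (negative = backward).
#'
#' @param yP CP position, m.
#' @param time time base, s.
#' @param t0y onset, s.
#' @return list with `apa_duration_ms`, `apa_amplitude_cm`, `t_apa_peak`.
#'   Signals `stepinit_no_backward_peak` if the CP moves monotonically
#'   forward after `t0y`.
#' @export
apa_phase <- function(yP, time, t0y) {
  n <- length(time)
  start <- which(time > t0y)[1]
  assert_that(!is.na(start) && start < n - 1, "t0y too close to record end",
              "stepinit_bad_events")
  idx <- (max(start, 2)):(n - 1)
  is_min <- yP[idx] <= yP[idx - 1] & yP[idx] <= yP[idx + 1] &
    (yP[idx] < yP[idx - 1] | yP[idx] < yP[idx + 1])
  y_t0 <- stats::approx(time, yP, xout = t0y)$y
  cand <- idx[is_min]
  cand <- cand[yP[cand] < y_t0]
  if (length(cand) == 0) {
    stop_stepinit("no backward CP peak after t0y",
                  "stepinit_no_backward_peak")
  }
  i_peak <- cand[1]
  list(apa_duration_ms = (time[i_peak] - t0y) * 1000,
       apa_amplitude_cm = (yP[i_peak] - y_t0) * 100,
       t_apa_peak = time[i_peak])
}

#' Peak forward centre-of-mass velocity and its time
#'
#' `v_peak` is the global maximum of the CM velocity over the record
#' (earliest sample on ties); `t_v` is its delay from face onset in ms.
#'
#' @param yG_vel CM velocity, m/s.
#' @param time time base, s.
#' @param face_onset s.
#' @return list with `v_peak_mps`, `t_v_ms`, `t_v_peak`. Signals
#'   `stepinit_no_forward_velocity` if the velocity is never positive.
#' @export
com_peak <- function(yG_vel, time, face_onset) {
  m <- max(yG_vel)
  if (m <= 0) {
    stop_stepinit("CM velocity never positive (no forward progression)",
                  "stepinit_no_forward_velocity")
  }
  i <- which(yG_vel == m)[1]
  list(v_peak_mps = m, t_v_ms = (time[i] - face_onset) * 1000,
       t_v_peak = time[i])
}

#' Compute the six outcome variables for one go trial
#'
#' Runs the kinematic reduction and event detection chain on one record:
#' initial posture, onset detection, reaction time, APA duration and
#' amplitude, CM velocity integration from the detected onset, and the
#' forward velocity peak.
#'
#' @param record a `force_plate_record`.
#' @param cutoff,order,z_offset,filter_stage passed to
#'   [compute_kinematics()].
#' @param search_horizon,noise_mult,min_floor,rel_floor passed to
#'   [detect_t0y()].
#' @return one-row data.frame: trial metadata, the six outcomes
#'   (`rt_ms`, `initial_posture_cm`, `apa_duration_ms`,
#'   `apa_amplitude_cm`, `v_mps`, `tv_ms`), event times (`t0y_s`,
#'   `t_apa_peak_s`, `t_v_peak_s`) and the pre-onset CP peak-to-peak
#'   excursion `baseline_pp_cm` used by the QC stage.
#' @export
compute_outcomes <- function(record, cutoff = 10, order = 4, z_offset = 0,
                             filter_stage = "raw", search_horizon = 2.5,
                             noise_mult = 5, min_floor = 0.005,
                             rel_floor = 0.2) {
  kin <- compute_kinematics(record, cutoff, order, z_offset, filter_stage)
  base_idx <- attr(kin, "baseline_idx")
  posture <- initial_posture(kin$yP, kin$time, record$face_onset)
  baseline_pp <- diff(range(kin$yP[base_idx])) * 100
  ev <- detect_t0y(kin$yP_vel, kin$time, record$face_onset,
                   search_horizon, noise_mult, min_floor, rel_floor)
  rt <- reaction_time(ev$t0y, record$face_onset)
  apa <- apa_phase(kin$yP, kin$time, ev$t0y)
  yG_vel <- cm_velocity(kin$yG_acc, kin$time, ev$t0y)
  pk <- com_peak(yG_vel, kin$time, record$face_onset)

  meta <- record$meta
  meta_cols <- intersect(c("participant_id", "condition", "group", "block",
                           "presentation_index", "face_id", "gender",
                           "expression", "trial_type"), names(meta))
  out <- as.data.frame(meta[meta_cols], stringsAsFactors = FALSE)
  if (nrow(out) == 0) out <- data.frame(row.names = 1)
  out$rt_ms <- rt
  out$initial_posture_cm <- posture
  out$apa_duration_ms <- apa$apa_duration_ms
  out$apa_amplitude_cm <- apa$apa_amplitude_cm
  out$v_mps <- pk$v_peak_mps
  out$tv_ms <- pk$t_v_ms
  out$t0y_s <- ev$t0y
  out$t_apa_peak_s <- apa$t_apa_peak
  out$t_v_peak_s <- pk$t_v_peak
  out$baseline_pp_cm <- baseline_pp
  rownames(out) <- NULL
  out
}

#' Compute outcomes, capturing event-detection failures
#'
#' Wrapper around [compute_outcomes()] that catches the classed
#' event-detection errors and returns them as data instead of stopping,
#' so a single bad trial never aborts a pipeline run.
#'
#' @inheritParams compute_outcomes
#' @return list with `ok` (logical), `outcome` (data.frame or NULL),
#'   `failure` (condition class string or NA) and `baseline_pp_cm`.
#' @export
try_outcomes <- function(record, ...) {
  res <- tryCatch(
    list(ok = TRUE, outcome = compute_outcomes(record, ...), failure = NA_character_),
    stepinit_no_onset = function(e)
      list(ok = FALSE, outcome = NULL, failure = "stepinit_no_onset"),
    stepinit_no_backward_peak = function(e)
      list(ok = FALSE, outcome = NULL, failure = "stepinit_no_backward_peak"),
    stepinit_no_forward_velocity = function(e)
      list(ok = FALSE, outcome = NULL, failure = "stepinit_no_forward_velocity")
  )
  if (res$ok) {
    res$baseline_pp_cm <- res$outcome$baseline_pp_cm
  } else {
    kin <- compute_kinematics(record)
    res$baseline_pp_cm <- diff(range(kin$yP[attr(kin, "baseline_idx")])) * 100
  }
  res
}
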