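#' Zero-lag low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward so the net
#' phase shift is zero and the magnitude response is the square of the
#' single-pass response (a 10 Hz cutoff therefore passes a 10 Hz sine at
#' amplitude 0.5). The signal is extended at both ends by odd reflection
#' (pad length three times the filter polynomial length) and each pass is
#' started from steady-state initial conditions, so edge transients do not
#' leak into the returned samples.
#'
#' @param x numeric signal on a uniform grid.
#' @param sampling_rate Hz.
#' @param cutoff low-pass cutoff, Hz (default 10).
#' @param order per-pass filter order (default 4).
#' @return filtered signal, same length as `x`.
#' @export
lowpass_zero_lag <- function(x, sampling_rate, cutoff = 10, order = 4) {
  assert_that(is.numeric(x) && length(x) > 0, "x must be numeric",
              "stepinit_bad_signal")
  assert_that(cutoff > 0 && cutoff < sampling_rate / 2,
              "cutoff must lie in (0, sampling_rate/2)",
              "stepinit_bad_filter")
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  b <- bf$b
  a <- bf$a
  padlen <- 3 * max(length(a), length(b))
  assert_that(length(x) > 3 * padlen,
              sprintf("signal too short to filter (need > %d samples)",
                      3 * padlen),
              "stepinit_signal_too_short")
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  xp <- c(front, x, back)
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(padlen + 1):(padlen + length(x))]
}

# Single IIR pass with steady-state (DC) initial conditions at x[1].
iir_pass <- function(b, a, x) {
  nb <- length(b)
  na <- length(a)
  xe <- c(rep(x[1], nb - 1), x)
  v <- stats::filter(xe, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xe)]
  # recursive part: past outputs assumed at the DC steady state x[1]
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(x[1], na - 1))
  as.numeric(y)
}

#' Anteroposterior centre of pressure from plate channels
#'
#' `yP = (Mx - Fy * z_offset) / Fz`, with the forward direction positive
#' and the plate origin at its geometric centre. `z_offset` is the
#' distance from the transducer origin to the plate surface (0 for a
#' surface-origin plate).
#'
#' @param Fy anteroposterior shear force, N.
#' @param Fz vertical force, N (must be positive throughout).
#' @param Mx moment about the mediolateral axis, N m.
#' @param z_offset m (default 0).
#' @return yP, m.
#' @export
cop_ap <- function(Fy, Fz, Mx, z_offset = 0) {
  assert_that(all(Fz > 0), "Fz must be positive throughout",
              "stepinit_nonpositive_fz")
  (Mx - Fy * z_offset) / Fz
}

#' Numerical derivative on a uniform grid
#'
#' Central differences in the interior, one-sided differences at the two
#' edges; exact for linear signals.
#'
#' @param x numeric signal (length >= 3).
#' @param sampling_rate Hz.
#' @return derivative of `x`, same length.
#' @export
differentiate <- function(x, sampling_rate) {
  n <- length(x)
  assert_that(n >= 3, "need at least 3 samples to differentiate",
              "stepinit_signal_too_short")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * sampling_rate
  d[n] <- (x[n] - x[n - 1]) * sampling_rate
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sampling_rate / 2
  d
}

#' Centre-of-mass anteroposterior acceleration from Newton's law
#'
#' `y''G = (Fy - baseline mean of Fy) / mass`. Subtracting the quiet-
#' standing baseline mean removes any static channel bias so the
#' acceleration is zero at rest.
#'
#' @param Fy anteroposterior shear force, N.
#' @param mass body mass, kg.
#' @param baseline_idx integer indices of the quiet-standing baseline
#'   window (the 500 ms before face onset in the pipeline).
#' @return acceleration, m/s^2.
#' @export
cm_acceleration <- function(Fy, mass, baseline_idx) {
  assert_that(is.numeric(mass) && length(mass) == 1 && mass > 0,
              "mass must be a positive scalar", "stepinit_bad_mass")
  assert_that(length(baseline_idx) > 0 &&
                all(baseline_idx >= 1 & baseline_idx <= length(Fy)),
              "baseline_idx out of range", "stepinit_bad_window")
  (Fy - mean(Fy[baseline_idx])) / mass
}

#' Centre-of-mass velocity by trapezoidal integration from movement onset
#'
#' Integrates the acceleration cumulatively (trapezoid rule) starting at
#' the movement-onset time `t0y`, imposing `y'G(t0y) = 0`; samples before
#' `t0y` are set to zero.
#'
#' @param yG_acc acceleration, m/s^2.
#' @param time time base, s.
#' @param t0y movement onset, s (must lie within the record).
#' @return velocity, m/s.
#' @export
cm_velocity <- function(yG_acc, time, t0y) {
  n <- length(time)
  assert_that(length(yG_acc) == n, "series lengths differ",
              "stepinit_bad_signal")
  assert_that(t0y >= time[1] && t0y <= time[n],
              "t0y outside the record", "stepinit_bad_window")
  i0 <- which(time >= t0y)[1]
  v <- numeric(n)
  if (i0 < n) {
    dt <- diff(time[i0:n])
    v[(i0 + 1):n] <- cumsum((yG_acc[i0:(n - 1)] + yG_acc[(i0 + 1):n]) / 2 * dt)
  }
  v
}

#' Reduce a force-plate record to kinematic series
#'
#' Filters the three raw channels with the zero-lag Butterworth filter,
#' computes the anteroposterior centre-of-pressure position and velocity,
#' and the centre-of-mass acceleration (baseline window: the 500 ms
#' before face onset). Centre-of-mass velocity is added later, once the
#' movement onset has been detected (see [compute_outcomes()]).
#'
#' @param record a `force_plate_record` (see [synthesize_trial()] /
#'   [read_record()]).
#' @param cutoff,order filter settings passed to [lowpass_zero_lag()].
#' @param z_offset plate origin-to-surface distance, m.
#' @param filter_stage `"raw"` (default) filters the force/moment
#'   channels before the centre-of-pressure computation; `"cp"` computes
#'   the centre of pressure from raw channels and filters it afterwards.
#' @return data.frame with columns `time`, `yP`, `yP_vel`, `yG_acc` and
#'   attribute `baseline_idx`.
#' @export
compute_kinematics <- function(record, cutoff = 10, order = 4, z_offset = 0,
                               filter_stage = c("raw", "cp")) {
  stopifnot(inherits(record, "force_plate_record"))
  filter_stage <- match.arg(filter_stage)
  fs <- record$sampling_rate
  baseline_idx <- which(record$time >= record$face_onset - 0.5 &
                          record$time < record$face_onset)
  assert_that(length(baseline_idx) >= 0.5 * fs - 1,
              "record must cover >= 500 ms before face onset",
              "stepinit_insufficient_baseline")
  if (filter_stage == "raw") {
    Fy <- lowpass_zero_lag(record$Fy, fs, cutoff, order)
    Fz <- lowpass_zero_lag(record$Fz, fs, cutoff, order)
    Mx <- lowpass_zero_lag(record$Mx, fs, cutoff, order)
    yP <- cop_ap(Fy, Fz, Mx, z_offset)
  } else {
    Fy <- lowpass_zero_lag(record$Fy, fs, cutoff, order)
    yP <- lowpass_zero_lag(cop_ap(record$Fy, record$Fz, record$Mx, z_offset),
                           fs, cutoff, order)
  }
  kin <- data.frame(
    time = record$time,
    yP = yP,
    yP_vel = differentiate(yP, fs),
    yG_acc = cm_acceleration(Fy, record$mass, baseline_idx)
  )
  attr(kin, "baseline_idx") <- baseline_idx
  kin
}
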