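# Synthetic force-plate trial generator.
#
# The generator works backwards from the pipeline's own event
# definitions: the centre-of-pressure (CP) backward excursion is built
# from a smooth asymmetric velocity lobe whose 10 %-of-peak crossing,
# first backward peak and net drop land exactly on the latent reaction
# time, APA duration and APA amplitude; the centre-of-mass (CM)
# acceleration is a full-sine lobe whose running integral peaks at
# exactly V at tV. All calibration constants below are closed forms.
#
# CP velocity profile (u = time since lobe start, scale D):
#   attack  u in [0, D/2]        v = -vpk sin^4(pi u / D)
#   release u in [D/2, D/2 + R]  v = -vpk cos(pi (u - D/2) / (2 R))
#   forward u beyond             quarter-cosine rise to +vpk, cos^2 decay
# with R = .APA_R_RATIO * D. The sin^4 attack keeps CP acceleration
# continuous at the lobe start, so the 10 Hz zero-lag filter leaves the
# 10 % crossing in place to well under one sample; the quarter-cosine
# release crosses zero with nonzero slope, giving a sharp (quadratic,
# well-conditioned) first backward CP peak at exactly D/2 + R.

.APA_R_RATIO <- 0.25

# fraction of the virtual full sin^4 lobe elapsed at the 10 % crossing
.apa_alpha <- function() asin(0.1^0.25) / pi

# Integral of vpk * sin^4(pi u / D) from 0 to u, valid for u <= D / 2.
.sin4_attack_int <- function(u, D, vpk) {
  u <- pmin(pmax(u, 0), D / 2)
  y <- pi * u / D
  vpk * (D / pi) * (3 * y / 8 - sin(2 * y) / 4 + sin(4 * y) / 32)
}

# fraction of vpk * D already travelled at the 10 % crossing
.apa_drop_coef <- function() {
  y <- pi * .apa_alpha()
  (3 * y / 8 - sin(2 * y) / 4 + sin(4 * y) / 32) / pi
}

# fraction of vpk * D travelled over the whole backward excursion
# (attack 3/16, release 2R/(pi D))
.apa_depth_coef <- function() 3 / 16 + 2 * .APA_R_RATIO / pi

#' Synthesize one clean force-plate go trial
#'
#' Builds a mechanically self-consistent record from one row of latent
#' outcomes: the anteroposterior shear force equals mass times the CM
#' acceleration template (a full-sine lobe starting at movement onset
#' whose integral peaks at exactly `v_mps` at `tv_ms`); the vertical
#' force is mass times g (plus channel noise); and the mediolateral-axis
#' moment is chosen so that [cop_ap()] recovers the intended CP
#' trajectory exactly. The CP trajectory holds the initial posture
#' through the baseline, descends backward through a smooth (sin^4)
#' velocity lobe calibrated so the pipeline's 10 %-crossing onset equals
#' `face_onset + rt_ms` and its first backward peak sits
#' `apa_duration_ms` later at depth `apa_amplitude_cm`, then moves
#' forward.
#'
#' @param latent one-row data.frame as returned by
#'   [sample_latent_outcomes()] (trial metadata plus the six latent
#'   outcomes and `mass_kg`).
#' @param params [generative_params()] object (sampling rate and channel
#'   noise levels). Pass `noise = FALSE` for an exact, noise-free record.
#' @param seed integer seed for the channel noise.
#' @param noise logical; add Gaussian channel noise (default TRUE).
#' @param face_onset face-onset time within the record, s (default 2,
#'   the fixation duration).
#' @param z_offset plate origin-to-surface distance, m.
#' @param stepping_limb limb used for the step, recorded in the metadata
#'   (`"dominant"` unless simulating a wrong-limb error).
#' @return object of class `force_plate_record`: a list with `time`,
#'   `Fy`, `Fz`, `Mx`, `sampling_rate`, `face_onset`, `mass`, `meta`.
#' @export
synthesize_trial <- function(latent, params, seed = 1L, noise = TRUE,
                             face_onset = 2, z_offset = 0,
                             stepping_limb = "dominant") {
  stopifnot(inherits(params, "generative_params"))
  rt <- latent$rt_ms / 1000
  dur <- latent$apa_duration_ms / 1000
  amp <- abs(latent$apa_amplitude_cm) / 100
  v_peak <- latent$v_mps
  tv <- latent$tv_ms / 1000
  y0 <- latent$initial_posture_cm / 100
  mass <- latent$mass_kg %||% params$mass_mean
  assert_that(tv - rt >= 0.05 && dur > 0 && v_peak > 0,
              "infeasible latent outcome (tV too close to RT, or nonpositive duration/velocity)",
              "stepinit_infeasible_template")

  fs <- params$sampling_rate
  alpha <- .apa_alpha()
  r <- .APA_R_RATIO
  # extracted duration = D2 (1/2 + r - alpha); solve for the lobe scale
  D2 <- dur / (0.5 + r - alpha)
  R <- r * D2
  ts <- face_onset + rt - alpha * D2      # lobe start
  vpk <- amp / ((.apa_depth_coef() - .apa_drop_coef()) * D2)
  assert_that(ts >= face_onset - 0.25,
              "APA lobe would start too far before face onset",
              "stepinit_infeasible_template")
  t_mid <- ts + D2 / 2                    # backward velocity peak
  te <- t_mid + R                         # backward CP peak (trough)
  depth <- vpk * D2 * .apa_depth_coef()   # full drop of the excursion
  fwd_decay <- 0.35                       # cos^2 decay of the forward phase
  Tacc <- 2 * (tv - rt)                   # full-sine acceleration lobe
  t0 <- face_onset + rt
  a_pk <- pi * v_peak / Tacc

  t_end <- face_onset +
    max(2.6, (t0 + Tacc - face_onset) + 0.3,
        (te + R + fwd_decay - face_onset) + 0.3)
  time <- seq(0, t_end, by = 1 / fs)
  n <- length(time)

  # CP trajectory (m), integrated from the piecewise velocity profile
  yP <- rep(y0, n)
  seg <- time > ts & time <= t_mid
  yP[seg] <- y0 - .sin4_attack_int(time[seg] - ts, D2, vpk)
  y_mid <- y0 - vpk * D2 * 3 / 16
  # release + forward quarter-cosines: v = -vpk cos(pi s / (2 R)),
  # s = time since t_mid, valid to s = 2 R where v = +vpk
  seg <- time > t_mid & time <= t_mid + 2 * R
  s <- time[seg] - t_mid
  yP[seg] <- y_mid - vpk * (2 * R / pi) * sin(pi * s / (2 * R))
  # cos^2 decay of the forward velocity from +vpk to 0 over fwd_decay
  y_fwd <- y_mid  # sin(pi) = 0: position back at y_mid when v = +vpk
  seg <- time > t_mid + 2 * R
  s <- pmin(time[seg] - (t_mid + 2 * R), fwd_decay)
  yP[seg] <- y_fwd + vpk * (s / 2 + fwd_decay * sin(pi * s / fwd_decay) /
                              (2 * pi))

  # CM acceleration template (m/s^2)
  acc <- numeric(n)
  in_lobe <- time >= t0 & time <= t0 + Tacc
  acc[in_lobe] <- a_pk * sin(2 * pi * (time[in_lobe] - t0) / Tacc)

  # First-order pre-compensation of the pipeline's zero-lag low-pass:
  # encoding 2 yP - F(yP) in the moment channel makes the filtered CP
  # equal yP to second order in the filter distortion, so event times
  # survive the reduction exactly even for brisk excursions.
  yP_enc <- 2 * yP - lowpass_zero_lag(yP, fs, params$filter_cutoff_hz, 4)

  g <- 9.81
  with_seed(if (noise) seed else NULL, {
    Fy <- mass * acc +
      if (noise) rnorm(n, 0, params$noise_force_sd) else 0
    Fz <- rep(mass * g, n) +
      if (noise) rnorm(n, 0, params$noise_force_sd) else 0
    Mx <- yP_enc * Fz + Fy * z_offset +
      if (noise) rnorm(n, 0, params$noise_moment_sd) else 0
  })

  meta_cols <- intersect(c("participant_id", "condition", "group",
                           "presentation_index", "face_id", "gender",
                           "expression", "trial_type", "block"),
                         names(latent))
  meta <- as.list(latent[1, meta_cols, drop = FALSE])
  meta$trial_type <- meta$trial_type %||% "go"
  meta$stepping_limb <- stepping_limb
  meta$dominant_limb <- "dominant"
  meta$latent <- as.list(latent[1, intersect(OUTCOMES, names(latent)),
                                drop = FALSE])

  structure(list(time = time, Fy = Fy, Fz = Fz, Mx = Mx,
                 sampling_rate = fs, face_onset = face_onset, mass = mass,
                 meta = meta),
            class = "force_plate_record")
}

#' @export
print.force_plate_record <- function(x, ...) {
  cat(sprintf(
    "<force_plate_record> %.2f s @ %g Hz, face onset %.2f s, mass %.1f kg\n",
    max(x$time), x$sampling_rate, x$face_onset, x$mass))
  invisible(x)
}

#' Synthesize an artifact go trial for a quality-control rule
#'
#' Produces a go-trial record that the QC module must reject with
#' exactly one reason: `"no_step"` (flat CP and force after face onset;
#' rule a), `"wrong_limb"` (clean step, mismatching stepping-limb
#' metadata; rule b), `"early_rt"` / `"late_rt"` (clean step with a
#' latent reaction time of 150 / 2100 ms; rule c), `"baseline_motion"`
#' (2 cm smooth forward CP drift inside the 500 ms pre-onset window,
#' then a clean step; rule d).
#'
#' @param kind one of `"no_step"`, `"wrong_limb"`, `"early_rt"`,
#'   `"late_rt"`, `"baseline_motion"`.
#' @param params [generative_params()] object.
#' @param seed integer seed.
#' @param noise logical; add channel noise.
#' @return a `force_plate_record`.
#' @export
synthesize_artifact_trial <- function(kind, params, seed = 1L, noise = TRUE) {
  stopifnot(inherits(params, "generative_params"))
  kind <- match.arg(kind, c("no_step", "wrong_limb", "early_rt", "late_rt",
                            "baseline_motion"))
  base_latent <- data.frame(
    participant_id = 0L, condition = "neutral_vs_emotional", group = "all",
    presentation_index = 0L, face_id = "M01", gender = "male",
    expression = "fearful", trial_type = "go",
    rt_ms = 600, initial_posture_cm = -44, apa_duration_ms = 250,
    apa_amplitude_cm = -4.5, v_mps = 0.56, tv_ms = 950,
    mass_kg = params$mass_mean, stringsAsFactors = FALSE
  )
  if (kind == "no_step") {
    fs <- params$sampling_rate
    face_onset <- 2
    time <- seq(0, face_onset + 2.6, by = 1 / fs)
    n <- length(time)
    mass <- params$mass_mean
    y0 <- -0.44
    with_seed(if (noise) seed else NULL, {
      Fy <- if (noise) rnorm(n, 0, params$noise_force_sd) else numeric(n)
      Fz <- rep(mass * 9.81, n) +
        if (noise) rnorm(n, 0, params$noise_force_sd) else 0
      Mx <- y0 * Fz + if (noise) rnorm(n, 0, params$noise_moment_sd) else 0
    })
    meta <- as.list(base_latent[1, c("participant_id", "condition", "group",
                                     "presentation_index", "face_id",
                                     "gender", "expression", "trial_type")])
    meta$stepping_limb <- "dominant"
    meta$dominant_limb <- "dominant"
    return(structure(list(time = time, Fy = Fy, Fz = Fz, Mx = Mx,
                          sampling_rate = fs, face_onset = face_onset,
                          mass = mass, meta = meta),
                     class = "force_plate_record"))
  }
  if (kind == "wrong_limb") {
    return(synthesize_trial(base_latent, params, seed, noise,
                            stepping_limb = "nondominant"))
  }
  if (kind == "early_rt") {
    base_latent$rt_ms <- 150
    base_latent$tv_ms <- 470
    return(synthesize_trial(base_latent, params, seed, noise))
  }
  if (kind == "late_rt") {
    base_latent$rt_ms <- 2100
    base_latent$tv_ms <- 2420
    base_latent$apa_duration_ms <- 220
    return(synthesize_trial(base_latent, params, seed, noise))
  }
  # baseline_motion: splice a smooth 2 cm forward drift into the 500 ms
  # pre-onset window of an otherwise clean trial (larger, brisker APA so
  # the onset detector's noise floor, inflated by the drift, still sees it)
  base_latent$apa_amplitude_cm <- -6
  base_latent$apa_duration_ms <- 200
  rec <- synthesize_trial(base_latent, params, seed, noise)
  drift_start <- rec$face_onset - 0.45
  drift_dur <- 0.35
  # smooth 2 cm forward drift: half a sin^4 attack up, mirrored down is
  # not needed - a single attack segment reaching 2 cm suffices
  u <- pmin(pmax(rec$time - drift_start, 0), drift_dur)
  drift <- 0.02 * (u / drift_dur - sin(2 * pi * u / drift_dur) / (2 * pi))
  rec$Mx <- rec$Mx + drift * rec$Fz
  rec
}

#' Write / read a force-plate record as a tab-separated signal table
#'
#' Header lines (`# key: value`) carry the sampling rate, face onset,
#' mass and trial metadata, followed by columns `time_s`, `Fy_N`,
#' `Fz_N`, `Mx_Nm`.
#'
#' @param record a `force_plate_record`.
#' @param path file path.
#' @return `read_record` returns the `force_plate_record`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "force_plate_record"))
  meta <- record$meta
  meta$latent <- NULL
  hdr <- c(
    sprintf("# sampling_rate: %.10g", record$sampling_rate),
    sprintf("# face_onset: %.10g", record$face_onset),
    sprintf("# mass: %.10g", record$mass),
    vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]), "")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- data.frame(time_s = record$time, Fy_N = record$Fy,
                    Fz_N = record$Fz, Mx_Nm = record$Mx)
  write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", hdr), ":\\s*")
  meta <- setNames(lapply(kv, function(p) paste(p[-1], collapse = ":")),
                   vapply(kv, `[[`, "", 1))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  num <- function(k) as.numeric(meta[[k]])
  core <- c("sampling_rate", "face_onset", "mass")
  extra <- meta[setdiff(names(meta), core)]
  for (k in c("participant_id", "presentation_index")) {
    if (!is.null(extra[[k]])) extra[[k]] <- as.integer(extra[[k]])
  }
  structure(list(time = tab$time_s, Fy = tab$Fy_N, Fz = tab$Fz_N,
                 Mx = tab$Mx_Nm, sampling_rate = num("sampling_rate"),
                 face_onset = num("face_onset"), mass = num("mass"),
                 meta = extra),
            class = "force_plate_record")
}
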