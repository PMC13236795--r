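#' Default generative cell means
#'
#' Emotion-by-condition cell means for the six outcome variables. The
#' per-condition marginal means follow the published estimated marginal
#' means of the study design this package models; emotion structure is
#' confined to the neutral-vs-emotional condition (the reported
#' interaction pattern), and cells not individually reported are chosen
#' once so that every reported marginal is reproduced. See the methods
#' vignette for the full derivation.
#'
#' @return data.frame with columns `condition`, `emotion`, `rt_ms`,
#'   `initial_posture_cm`, `apa_duration_ms`, `apa_amplitude_cm`,
#'   `v_mps`, `tv_ms`.
#' @export
default_cell_means <- function() {
  fg <- data.frame(
    condition = "face_gender",
    emotion = EMOTIONS,
    rt_ms = 604, initial_posture_cm = -44,
    apa_duration_ms = 265, apa_amplitude_cm = -4.57,
    v_mps = 0.563, tv_ms = 948,
    stringsAsFactors = FALSE
  )
  nve <- data.frame(
    condition = "neutral_vs_emotional",
    emotion = c("fearful", "angry", "happy"),
    rt_ms = 637, initial_posture_cm = -43.9,
    apa_duration_ms = c(260, 238, 252),
    apa_amplitude_cm = c(-4.27, -3.51, -4.13),
    v_mps = 0.563,
    tv_ms = c(974, 992, 1016),
    stringsAsFactors = FALSE
  )
  rbind(fg, nve)
}

#' Default variance components of the generative model
#'
#' Participant, face and residual standard deviations per outcome. These
#' are plausible values back-derived from the published standard errors of
#' the marginal means (trial-level SDs are not published); see the methods
#' vignette.
#'
#' @return data.frame with columns `outcome`, `sd_participant`, `sd_face`,
#'   `sd_residual`.
#' @export
default_sds <- function() {
  data.frame(
    outcome = c("rt_ms", "initial_posture_cm", "apa_duration_ms",
                "apa_amplitude_cm", "v_mps", "tv_ms"),
    sd_participant = c(60, 1.7, 42, 1.05, 0.115, 135),
    sd_face = c(10, 0.05, 6, 0.10, 0.010, 12),
    sd_residual = c(90, 1.2, 55, 0.90, 0.100, 110),
    stringsAsFactors = FALSE
  )
}

#' Generative model parameters
#'
#' Bundles everything the synthetic-trial generator needs: the emotion x
#' condition cell-mean table, crossed variance components, body-mass
#' distribution, sampling rate and channel-noise levels.
#'
#' @param cell_means data.frame as [default_cell_means()].
#' @param sds data.frame as [default_sds()].
#' @param mass_mean,mass_sd body mass distribution, kg.
#' @param sampling_rate Hz.
#' @param noise_force_sd additive Gaussian noise SD on force channels, N.
#' @param noise_moment_sd additive Gaussian noise SD on the moment
#'   channel, N m.
#' @param filter_cutoff_hz low-pass cutoff the pipeline will use (needed
#'   for the Nyquist validity check).
#' @return An object of class `generative_params` (a named list).
#' @export
generative_params <- function(cell_means = default_cell_means(),
                              sds = default_sds(),
                              mass_mean = 70, mass_sd = 10,
                              sampling_rate = 1000,
                              noise_force_sd = 0.5,
                              noise_moment_sd = 0.3,
                              filter_cutoff_hz = 10) {
  assert_that(all(c("condition", "emotion") %in% names(cell_means)),
              "cell_means must carry condition and emotion columns",
              "stepinit_bad_params")
  assert_that(all(cell_means$apa_amplitude_cm <= 0),
              "APA amplitude cell means must be <= 0 (backward shift)",
              "stepinit_bad_params")
  assert_that(all(cell_means$tv_ms > cell_means$rt_ms),
              "tV cell means must exceed RT cell means",
              "stepinit_bad_params")
  assert_that(all(unlist(sds[, c("sd_participant", "sd_face",
                                 "sd_residual")]) >= 0),
              "standard deviations must be non-negative",
              "stepinit_bad_params")
  assert_that(sampling_rate > 2 * filter_cutoff_hz,
              "sampling_rate must exceed twice the filter cutoff",
              "stepinit_bad_params")
  structure(list(
    cell_means = cell_means, sds = sds,
    mass_mean = mass_mean, mass_sd = mass_sd,
    sampling_rate = sampling_rate,
    noise_force_sd = noise_force_sd,
    noise_moment_sd = noise_moment_sd,
    filter_cutoff_hz = filter_cutoff_hz
  ), class = "generative_params")
}

OUTCOMES <- c("rt_ms", "initial_posture_cm", "apa_duration_ms",
              "apa_amplitude_cm", "v_mps", "tv_ms")

#' Sample latent per-trial outcomes under the crossed generative model
#'
#' For every go trial of `schedule`, draws the six latent outcomes as
#' `mu_cell(emotion, condition) + u_participant + w_face + eps`, with
#' independent zero-mean Gaussian random intercepts at the standard
#' deviations of `params$sds`. Draws are reproducible from `seed`.
#' Mild physical consistency is enforced after sampling: APA amplitude is
#' capped below zero, APA duration below at 80 ms, and `tv_ms` at least
#' 150 ms after `rt_ms` (the acceleration template needs a positive rise
#' time); clamping is rare at the default SDs.
#'
#' @param params [generative_params()] object.
#' @param schedule schedule data.frame (go and no-go rows; latents are
#'   produced for go rows only).
#' @param seed integer seed.
#' @return data.frame: the go rows of `schedule` plus `mass_kg` and the
#'   six latent outcome columns.
#' @export
sample_latent_outcomes <- function(params, schedule, seed = 1L) {
  stopifnot(inherits(params, "generative_params"))
  go <- schedule[schedule$trial_type == "go", , drop = FALSE]
  assert_that(nrow(go) > 0, "schedule contains no go trials",
              "stepinit_bad_schedule")
  assert_that(!any(go$expression == "neutral"),
              "neutral-expression trials carry no latent outcome",
              "stepinit_neutral_go")
  participants <- sort(unique(go$participant_id))
  faces <- sort(unique(go$face_id))
  sds <- params$sds
  cm <- params$cell_means

  with_seed(seed, {
    mass <- setNames(rnorm(length(participants), params$mass_mean,
                           params$mass_sd),
                     participants)
    mass <- pmax(mass, 40)
    for (oc in OUTCOMES) {
      s <- sds[sds$outcome == oc, ]
      u <- setNames(rnorm(length(participants), 0, s$sd_participant),
                    participants)
      w <- setNames(rnorm(length(faces), 0, s$sd_face), faces)
      mu <- cm[[oc]][match(paste(go$condition, go$expression),
                           paste(cm$condition, cm$emotion))]
      assert_that(!anyNA(mu),
                  "cell_means lacks a row for some condition x emotion cell",
                  "stepinit_bad_params")
      go[[oc]] <- mu + u[as.character(go$participant_id)] +
        w[go$face_id] + rnorm(nrow(go), 0, s$sd_residual)
    }
    go$mass_kg <- mass[as.character(go$participant_id)]
  })

  # physical consistency clamps (documented in the methods vignette)
  go$apa_amplitude_cm <- pmin(go$apa_amplitude_cm, -0.5)
  go$apa_duration_ms <- pmax(go$apa_duration_ms, 80)
  go$rt_ms <- pmax(go$rt_ms, 120)
  go$tv_ms <- pmax(go$tv_ms, go$rt_ms + 150)
  go$v_mps <- pmax(go$v_mps, 0.05)
  rownames(go) <- NULL
  go
}
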