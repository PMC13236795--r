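# Shared fixtures: latent-outcome rows and small generative setups.

make_latent <- function(rt = 637, posture = -44, dur = 250, amp = -3.97,
                        v = 0.563, tv = 948, mass = 70,
                        condition = "neutral_vs_emotional",
                        expression = "fearful") {
  data.frame(
    participant_id = 1L, condition = condition, group = "all",
    presentation_index = 1L, face_id = "M01", gender = "male",
    expression = expression, trial_type = "go",
    rt_ms = rt, initial_posture_cm = posture, apa_duration_ms = dur,
    apa_amplitude_cm = amp, v_mps = v, tv_ms = tv, mass_kg = mass,
    stringsAsFactors = FALSE
  )
}

default_params <- generative_params()

# Zero-variance parameter set: latents equal the cell means exactly.
zero_sd_params <- local({
  s <- default_sds()
  s$sd_participant <- 0
  s$sd_face <- 0
  s$sd_residual <- 0
  generative_params(sds = s)
})

extract_outcomes <- function(latent, params = default_params, ...) {
  rec <- synthesize_trial(latent, params, noise = FALSE, ...)
  compute_outcomes(rec)
}
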