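test_that("zero-noise trials round-trip the latent outcomes through the pipeline", {
  cases <- expand.grid(rt = c(250, 637, 900), dur = c(150, 250, 400),
                       amp = c(-7, -3.97, -2))
  for (i in seq_len(nrow(cases))) {
    lat <- make_latent(rt = cases$rt[i], dur = cases$dur[i],
                       amp = cases$amp[i], tv = cases$rt[i] + 311)
    out <- extract_outcomes(lat)
    expect_equal(out$rt_ms, lat$rt_ms, tolerance = 1 / lat$rt_ms)
    expect_equal(out$apa_duration_ms, lat$apa_duration_ms,
                 tolerance = 1 / lat$apa_duration_ms)
    expect_equal(out$tv_ms, lat$tv_ms, tolerance = 1 / lat$tv_ms)
    expect_lt(abs(out$apa_amplitude_cm - lat$apa_amplitude_cm), 0.05)
    expect_lt(abs(out$v_mps - lat$v_mps), 0.005)
    expect_lt(abs(out$initial_posture_cm - lat$initial_posture_cm), 0.01)
  }
})

test_that("zero-noise records are mechanically self-consistent", {
  lat <- make_latent()
  rec <- synthesize_trial(lat, default_params, noise = FALSE)
  # pre-onset: quiet standing at the initial posture, no shear force
  pre <- rec$time < rec$face_onset - 0.1
  yP_raw <- rec$Mx / rec$Fz
  expect_lt(max(abs(yP_raw[pre] - lat$initial_posture_cm / 100)), 1e-9)
  expect_lt(max(abs(rec$Fy[pre])), 1e-9)
  expect_equal(rec$Fz, rep(rec$mass * 9.81, length(rec$time)))
  # Newton consistency: Fy / mass integrates to the latent velocity peak
  kin <- compute_kinematics(rec)
  t0 <- rec$face_onset + lat$rt_ms / 1000
  v <- cm_velocity(kin$yG_acc, rec$time, t0)
  expect_equal(max(v), lat$v_mps, tolerance = 1e-3)
})

test_that("channel noise is reproducible and at the configured scale", {
  lat <- make_latent()
  a <- synthesize_trial(lat, default_params, seed = 5, noise = TRUE)
  b <- synthesize_trial(lat, default_params, seed = 5, noise = TRUE)
  d <- synthesize_trial(lat, default_params, seed = 6, noise = TRUE)
  expect_identical(a$Fy, b$Fy)
  expect_false(identical(a$Fy, d$Fy))
  clean <- synthesize_trial(lat, default_params, noise = FALSE)
  expect_equal(sd(a$Fy - clean$Fy), default_params$noise_force_sd,
               tolerance = 0.05)
  # the moment channel carries the CP encoding times the (noisy) vertical
  # force plus its own noise; remove the propagated Fz noise first
  yP_enc <- clean$Mx / clean$Fz
  own_noise <- (a$Mx - clean$Mx) - (a$Fz - clean$Fz) * yP_enc
  expect_equal(sd(own_noise), default_params$noise_moment_sd,
               tolerance = 0.05)
})

test_that("infeasible latent outcomes are refused", {
  lat <- make_latent(tv = 660)  # only 23 ms after RT
  expect_error(synthesize_trial(lat, default_params),
               class = "stepinit_infeasible_template")
})

test_that("records survive the tab-separated round trip", {
  lat <- make_latent()
  rec <- synthesize_trial(lat, default_params, seed = 2, noise = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_record(rec, path)
  rec2 <- read_record(path)
  expect_equal(rec2$sampling_rate, rec$sampling_rate)
  expect_equal(rec2$face_onset, rec$face_onset)
  expect_equal(rec2$mass, rec$mass)
  expect_equal(rec2$time, rec$time, tolerance = 1e-8)
  expect_equal(rec2$Fy, rec$Fy, tolerance = 1e-6)
  expect_equal(rec2$Mx, rec$Mx, tolerance = 1e-6)
  expect_equal(rec2$meta$face_id, rec$meta$face_id)
  expect_equal(rec2$meta$stepping_limb, "dominant")
  # outcomes computed from the re-read record agree
  out <- compute_outcomes(rec)
  out2 <- compute_outcomes(rec2)
  expect_equal(out2$rt_ms, out$rt_ms, tolerance = 1e-4)
})

test_that("moment matching: noisy cell means converge to the latent means", {
  # one cell, many noisy replicates of the same latent trial: the mean
  # extracted outcomes approach the latent values
  lat <- make_latent()
  outs <- do.call(rbind, lapply(1:25, function(i) {
    rec <- synthesize_trial(lat, default_params, seed = i, noise = TRUE)
    compute_outcomes(rec)
  }))
  expect_equal(mean(outs$rt_ms), lat$rt_ms, tolerance = 0.01)
  expect_equal(mean(outs$apa_amplitude_cm), lat$apa_amplitude_cm,
               tolerance = 0.05)
  expect_equal(mean(outs$v_mps), lat$v_mps, tolerance = 0.02)
})
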