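fs <- 1000

test_that("zero-lag filter passes DC unchanged and halves a cutoff-frequency sine", {
  x <- rep(2.75, 1500)
  expect_equal(lowpass_zero_lag(x, fs), x, tolerance = 1e-9)
  t <- seq(0, 6, by = 1 / fs)
  y <- lowpass_zero_lag(sin(2 * pi * 10 * t), fs, cutoff = 10, order = 4)
  mid <- y[2000:4000]
  # two passes of a Butterworth at its -3 dB point: amplitude gain 1/2
  expect_equal(max(mid), 0.5, tolerance = 0.005)
})

test_that("filtering is zero-phase: symmetric pulses keep their peak sample", {
  t <- seq_len(4000)
  for (width in c(30, 80, 200)) {
    pulse <- exp(-((t - 2000) / width)^2)
    expect_equal(which.max(lowpass_zero_lag(pulse, fs)), 2000)
  }
  # white noise on a trend: peak cross-correlation with the raw signal at lag 0
  set.seed(1)
  x <- cumsum(rnorm(4000)) / 10 + sin(2 * pi * 2 * t / fs)
  y <- lowpass_zero_lag(x, fs)
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter rejects invalid input", {
  expect_error(lowpass_zero_lag(rnorm(40), fs), class = "stepinit_signal_too_short")
  expect_error(lowpass_zero_lag(rnorm(2000), fs, cutoff = 600),
               class = "stepinit_bad_filter")
})

test_that("centre of pressure follows the moment/force formula", {
  # direct substitution at the study's posture scale (~ -44 cm)
  expect_equal(cop_ap(0, 600, -264), -0.44)
  expect_equal(cop_ap(0, 700, 0), 0)
  # homogeneity: scaling Mx and Fz jointly leaves yP unchanged
  expect_equal(cop_ap(0, 1200, -528), -0.44)
  # z-offset moves the shear-force term
  expect_equal(cop_ap(10, 500, -200, z_offset = 0.04),
               (-200 - 10 * 0.04) / 500)
  # linear in Mx at fixed Fz
  expect_equal(cop_ap(0, 600, -132), -0.22)
  expect_error(cop_ap(0, c(600, -1), 0), class = "stepinit_nonpositive_fz")
})

test_that("differentiation is exact on ramps and bounded on sines", {
  x <- 3.5 * seq(0, 1, by = 1 / fs)
  d <- differentiate(x, fs)
  expect_equal(d[2:(length(d) - 1)], rep(3.5, length(d) - 2), tolerance = 1e-9)
  expect_equal(differentiate(rep(1, 100), fs), rep(0, 100))
  # central differences: |error| <= (2 pi f)^3 / (6 fs^2) for a unit sine
  f <- 5
  t <- seq(0, 2, by = 1 / fs)
  d <- differentiate(sin(2 * pi * f * t), fs)
  truth <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 2:(length(t) - 1)
  bound <- (2 * pi * f)^3 / (6 * fs^2)
  expect_lt(max(abs(d[interior] - truth[interior])), bound * 1.0000001)
  expect_error(differentiate(c(1, 2), fs), class = "stepinit_signal_too_short")
})

test_that("Newton's law and baseline removal give centre-of-mass acceleration", {
  expect_equal(cm_acceleration(rep(0, 100), 70, 1:50), rep(0, 100))
  Fy <- c(rep(0, 50), rep(70, 50))
  expect_equal(cm_acceleration(Fy, 70, 1:50), c(rep(0, 50), rep(1, 50)))
  # constant bias throughout is removed by the baseline mean
  expect_equal(cm_acceleration(rep(5, 100), 70, 1:50), rep(0, 100))
  expect_error(cm_acceleration(Fy, -1, 1:50), class = "stepinit_bad_mass")
})

test_that("velocity integration starts at zero at movement onset", {
  time <- seq(0, 2, by = 1 / fs)
  acc <- rep(2, length(time))
  v <- cm_velocity(acc, time, t0y = 1)
  expect_equal(v[time < 1], rep(0, sum(time < 1)))
  expect_equal(v[time >= 1], 2 * (time[time >= 1] - 1), tolerance = 1e-9)
  expect_equal(cm_velocity(rep(0, length(time)), time, 0.5),
               rep(0, length(time)))
  # raised-cosine acceleration pulse: closed-form running integral
  T0 <- 0.4
  apk <- 3
  acc <- ifelse(time >= 1 & time <= 1 + T0,
                apk / 2 * (1 - cos(2 * pi * (time - 1) / T0)), 0)
  v <- cm_velocity(acc, time, t0y = 1)
  v_true <- apk / 2 * (T0 - T0 * sin(2 * pi) / (2 * pi))  # value at pulse end
  i_end <- which.min(abs(time - (1 + T0)))
  expect_equal(v[i_end], v_true, tolerance = 1e-6 * v_true)
  expect_error(cm_velocity(acc, time, t0y = 5), class = "stepinit_bad_window")
})

test_that("differentiate-then-integrate round trips smooth signals", {
  time <- seq(0, 3, by = 1 / fs)
  x <- 0.05 * sin(2 * pi * 1.5 * time)^2
  v <- differentiate(x, fs)
  x_rec <- x[1] + cm_velocity(v, time, t0y = 0)
  expect_lt(max(abs(x_rec - x)), 1e-5)
})
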