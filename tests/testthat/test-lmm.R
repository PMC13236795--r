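make_crossed_data <- function(n_p = 6, n_f = 4, reps = 2, sd_p = 0, sd_f = 0,
                              sd_e = 1, delta = c(0, 0, 0), seed = 1,
                              center_groups = FALSE) {
  set.seed(seed)
  d <- expand.grid(participant_id = seq_len(n_p),
                   face_id = sprintf("f%d", seq_len(n_f)),
                   emotion = c("fearful", "angry", "happy"),
                   condition = c("neutral_vs_emotional", "face_gender"),
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  u <- rnorm(n_p, 0, sd_p)
  w <- setNames(rnorm(n_f, 0, sd_f), unique(d$face_id))
  mu <- delta[match(d$emotion, c("fearful", "angry", "happy"))]
  e <- rnorm(nrow(d), 0, sd_e)
  if (center_groups) {
    # remove all participant- and face-level variation from the noise so
    # both REML variance components sit exactly on the zero boundary
    e <- e - ave(e, d$participant_id) - ave(e, d$face_id) + mean(e)
  }
  d$y <- mu + u[d$participant_id] + w[d$face_id] + e
  d
}

test_that("with no random-effect variance the fit collapses to least squares", {
  d <- make_crossed_data(sd_p = 0, sd_f = 0, sd_e = 1,
                         delta = c(2, -1, 0), seed = 4, center_groups = TRUE)
  fit <- fit_crossed_lmm(d, "y")
  dd <- data.frame(value = d$y, emotion = factor(d$emotion),
                   condition = factor(d$condition))
  contrasts(dd$emotion) <- contr.sum(3)
  contrasts(dd$condition) <- contr.sum(2)
  ols <- lm(value ~ emotion * condition, dd)
  expect_lt(max(abs((lme4::fixef(fit) - coef(ols)) / coef(ols))), 1e-6)
  # with both components at the zero boundary, Satterthwaite denominator
  # degrees of freedom reduce to the fixed-effects residual df, N - p
  expect_true(attr(fit, "boundary"))
  a <- anova_satterthwaite(fit)
  expect_equal(a$df_den, rep(nrow(d) - 6, 3), tolerance = 1e-6)
  expect_true(all(a$F >= 0))
  expect_true(all(a$df_den <= nrow(d) - 6 + 1e-6))
})

test_that("variance components are recovered on a large balanced design", {
  d <- make_crossed_data(n_p = 30, n_f = 10, reps = 4,
                         sd_p = 2, sd_f = 1, sd_e = 1, seed = 7)
  fit <- fit_crossed_lmm(d, "y")
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_hat <- setNames(vc$sdcor, vc$grp)
  expect_equal(unname(sd_hat["participant"]), 2, tolerance = 0.35)
  expect_equal(unname(sd_hat["face"]), 1, tolerance = 0.45)
  expect_equal(unname(sd_hat["Residual"]), 1, tolerance = 0.1)
})

test_that("a constant outcome is flagged as a boundary fit", {
  d <- make_crossed_data(seed = 2)
  d$y <- 7
  fit <- fit_crossed_lmm(d, "y")
  expect_true(attr(fit, "boundary"))
})

test_that("the semi-partial R2 formula behaves across its range", {
  expect_equal(semipartial_r2(0, 2, 100), 0)
  ratio <- 1 * 10 / 90
  expect_equal(semipartial_r2(10, 1, 90), ratio / (1 + ratio))
  expect_gt(semipartial_r2(1e8, 2, 100), 0.999)
  # monotone in F
  expect_true(all(diff(sapply(c(0, 1, 5, 20), semipartial_r2,
                              df_num = 2, df_den = 50)) > 0))
  expect_error(semipartial_r2(1, 0, 10), class = "stepinit_bad_df")
  expect_error(semipartial_r2(-1, 1, 10), class = "stepinit_bad_df")
})

test_that("marginal means equal arithmetic cell means on balanced data", {
  d <- make_crossed_data(sd_p = 1, sd_f = 0.5, sd_e = 1,
                         delta = c(1, 0, -1), seed = 9)
  fit <- fit_crossed_lmm(d, "y")
  emm <- emmeans_cells(fit)
  cell <- aggregate(y ~ emotion + condition, d, mean)
  m <- merge(emm, cell, by = c("emotion", "condition"))
  expect_equal(m$emmean, m$y, tolerance = 1e-6)
  # a contrast of two cells equals the difference of their marginal means
  ctr <- tukey_contrasts(fit, ~ emotion, by = "condition")
  fear_fg <- emm$emmean[emm$emotion == "fearful" &
                          emm$condition == "face_gender"]
  angry_fg <- emm$emmean[emm$emotion == "angry" &
                           emm$condition == "face_gender"]
  est <- ctr$estimate[ctr$contrast == "angry - fearful" &
                        ctr$condition == "face_gender"]
  expect_equal(est, angry_fg - fear_fg, tolerance = 1e-8)
})

test_that("Tukey adjustment uses the studentized range and is conservative", {
  d <- make_crossed_data(sd_p = 0.5, sd_f = 0.3, sd_e = 1,
                         delta = c(0.8, -0.4, 0), seed = 11)
  fit <- fit_crossed_lmm(d, "y")
  ctr <- tukey_contrasts(fit, ~ emotion)   # family of 3 means
  manual <- ptukey(abs(ctr$t) * sqrt(2), 3, ctr$df, lower.tail = FALSE)
  expect_equal(ctr$p, manual, tolerance = 1e-6)
  unadj <- 2 * pt(abs(ctr$t), ctr$df, lower.tail = FALSE)
  expect_true(all(ctr$p >= unadj - 1e-12))
  # family of two means: the adjustment vanishes
  d2 <- d[d$emotion != "happy", ]
  fit2 <- suppressMessages(fit_crossed_lmm(d2, "y"))
  ctr2 <- tukey_contrasts(fit2, ~ emotion)
  unadj2 <- 2 * pt(abs(ctr2$t), ctr2$df, lower.tail = FALSE)
  expect_equal(ctr2$p, unadj2, tolerance = 1e-8)
  # at study scale (|t| = 2.67, k = 3, df ~ 1367, the anger-fear APA
  # duration contrast), the adjusted p lands near the reported 0.025;
  # the printed t and p are rounded, hence the 0.005 tolerance
  p_study <- ptukey(2.67 * sqrt(2), 3, 1367.5, lower.tail = FALSE)
  expect_lt(abs(p_study - 0.025), 0.005)
})

test_that("lmm input validation catches broken designs", {
  d <- make_crossed_data()
  expect_error(fit_crossed_lmm(d[, -which(names(d) == "face_id")], "y"),
               class = "stepinit_bad_lmm_data")
  d1 <- d[d$participant_id == 1, ]
  expect_error(fit_crossed_lmm(d1, "y"), class = "stepinit_bad_lmm_data")
  d2 <- d[!(d$emotion == "happy" & d$condition == "face_gender"), ]
  expect_error(fit_crossed_lmm(d2, "y"), class = "stepinit_bad_lmm_data")
})
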