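# Simulation-based power analysis for the crossed design.

# Simulate one latent outcome table on a compact balanced design:
# n_participants x n_faces-ish cells, trials_per_cell per emotion x
# condition cell per participant, crossed random intercepts.
simulate_power_dataset <- function(effect, n_participants, n_faces,
                                   trials_per_cell, sd_participant, sd_face,
                                   sd_residual) {
  emotions <- EMOTIONS
  conditions <- c("neutral_vs_emotional", "face_gender")
  d <- expand.grid(
    participant_id = seq_len(n_participants),
    emotion = emotions,
    condition = conditions,
    rep = seq_len(trials_per_cell),
    stringsAsFactors = FALSE
  )
  # faces cycle deterministically through the cells of each participant
  d$face_id <- sprintf("f%02d",
                       (seq_len(nrow(d)) + d$participant_id) %% n_faces + 1)
  sd_total <- sqrt(sd_participant^2 + sd_face^2 + sd_residual^2)
  delta <- effect * sd_total
  # injected emotion effect: fearful +delta/2, angry -delta/2, happy 0
  mu <- ifelse(d$emotion == "fearful", delta / 2,
               ifelse(d$emotion == "angry", -delta / 2, 0))
  u <- rnorm(n_participants, 0, sd_participant)
  w <- setNames(rnorm(n_faces, 0, sd_face), sprintf("f%02d", seq_len(n_faces)))
  d$value <- mu + u[d$participant_id] + w[d$face_id] +
    rnorm(nrow(d), 0, sd_residual)
  d
}

#' Simulation-based power for the emotion effect
#'
#' simr-style procedure: simulate responses from the crossed generative
#' model with a standardized emotion effect injected (Cohen's d on the
#' total-SD scale, realized as a fearful-minus-angry difference of
#' `d * sd_total`), refit the crossed mixed model, test the emotion term
#' with the Satterthwaite F at `alpha`, and report the rejection
#' fraction with its exact (Clopper-Pearson) binomial 95% confidence
#' interval.
#'
#' @param effect standardized effect size (Cohen's d; 0 gives the null
#'   calibration run).
#' @param n_sims number of simulations (the study's own analysis used
#'   1000).
#' @param alpha test level (default 0.05).
#' @param n_participants,n_faces design size (defaults 24 and 10).
#' @param trials_per_cell go trials per emotion-by-condition cell per
#'   participant.
#' @param sd_participant,sd_face,sd_residual variance components of the
#'   simulated outcome.
#' @param seed integer seed.
#' @return list with `power`, `ci` (length-2 vector), `n_sims`,
#'   `rejections`, `effect`.
#' @export
power_simulation <- function(effect, n_sims = 200, alpha = 0.05,
                             n_participants = 24, n_faces = 10,
                             trials_per_cell = 2,
                             sd_participant = 1, sd_face = 0.3,
                             sd_residual = 2, seed = 1L) {
  assert_that(n_sims >= 1, "n_sims must be >= 1", "stepinit_bad_power")
  assert_that(effect >= 0, "effect size must be non-negative",
              "stepinit_bad_power")
  rej <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      d <- simulate_power_dataset(effect, n_participants, n_faces,
                                  trials_per_cell, sd_participant, sd_face,
                                  sd_residual)
      names(d)[names(d) == "value"] <- "y"
      fit <- fit_crossed_lmm(d, "y")
      a <- anova_satterthwaite(fit)
      a$p[a$term == "emotion"] < alpha
    }, logical(1))
  })
  k <- sum(rej)
  ci <- as.numeric(stats::binom.test(k, n_sims)$conf.int)
  list(power = k / n_sims, ci = ci, n_sims = n_sims, rejections = k,
       effect = effect)
}

#' Power curve over a grid of effect sizes
#'
#' Runs [power_simulation()] for each effect size with sub-seeds derived
#' from the master seed.
#'
#' @param effects numeric vector of standardized effect sizes.
#' @param ... passed to [power_simulation()].
#' @param seed master seed.
#' @return data.frame with `effect`, `power`, `ci_lower`, `ci_upper`,
#'   `n_sims`.
#' @export
power_curve <- function(effects, ..., seed = 1L) {
  rows <- lapply(seq_along(effects), function(i) {
    r <- power_simulation(effects[i], ..., seed = derive_seed(seed, i))
    data.frame(effect = r$effect, power = r$power, ci_lower = r$ci[1],
               ci_upper = r$ci[2], n_sims = r$n_sims)
  })
  do.call(rbind, rows)
}
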