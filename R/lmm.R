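# Crossed random-intercept mixed-model inference for the six outcomes.
#
# The model for each outcome is
#   value ~ emotion * condition + (1 | participant) + (1 | face)
# fitted by REML with sum-to-zero factor coding so the type-III F tests
# respect marginality. Fitting, Satterthwaite denominator degrees of
# freedom, marginal means and studentized-range adjustment are delegated
# to lme4/lmerTest/emmeans; the semi-partial R^2 effect size and the
# power procedure are implemented here.

#' Fit the crossed random-intercept linear mixed model for one outcome
#'
#' @param data long-format data.frame of accepted go trials with columns
#'   `participant_id`, `face_id`, `emotion` (fearful/angry/happy),
#'   `condition`, and the outcome column.
#' @param outcome name of the outcome column.
#' @return an object of class `lmerModLmerTest` (REML fit, sum-to-zero
#'   contrasts). Boundary (zero) variance components are permitted; the
#'   fit carries an attribute `boundary` flagging them.
#' @export
fit_crossed_lmm <- function(data, outcome) {
  assert_that(all(c("participant_id", "face_id", "emotion", "condition",
                    outcome) %in% names(data)),
              "data must carry participant_id, face_id, emotion, condition and the outcome",
              "stepinit_bad_lmm_data")
  d <- data.frame(
    value = data[[outcome]],
    emotion = factor(data$emotion),
    condition = factor(data$condition),
    participant = factor(data$participant_id),
    face = factor(data$face_id)
  )
  assert_that(nlevels(d$participant) >= 2 && nlevels(d$face) >= 2,
              "need >= 2 participants and >= 2 faces",
              "stepinit_bad_lmm_data")
  assert_that(all(table(d$emotion, d$condition) > 0),
              "empty emotion x condition cell", "stepinit_bad_lmm_data")
  contrasts(d$emotion) <- stats::contr.sum(nlevels(d$emotion))
  contrasts(d$condition) <- stats::contr.sum(nlevels(d$condition))
  degenerate <- stats::var(d$value) == 0
  fitter <- function() lmerTest::lmer(
    value ~ emotion * condition + (1 | participant) + (1 | face),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = TRUE)
  )
  # a constant outcome pins every variance component to the zero
  # boundary; the optimizer's convergence complaints carry no information
  fit <- if (degenerate) suppressWarnings(fitter()) else fitter()
  attr(fit, "boundary") <- degenerate ||
    lme4::isSingular(fit, tol = 1e-5) || stats::sigma(fit) < 1e-10
  attr(fit, "outcome") <- outcome
  fit
}

#' Type-III F tests with Satterthwaite denominator degrees of freedom
#'
#' @param fit result of [fit_crossed_lmm()].
#' @return data.frame with one row per fixed term: `term`, `F`,
#'   `df_num`, `df_den` (Satterthwaite), `p`, and the semi-partial `r2`
#'   effect size from [semipartial_r2()].
#' @export
anova_satterthwaite <- function(fit) {
  a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  out <- data.frame(
    term = rownames(a),
    F = a$`F value`,
    df_num = a$NumDF,
    df_den = a$DenDF,
    p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  out$r2 <- mapply(semipartial_r2, out$F, out$df_num, out$df_den)
  rownames(out) <- NULL
  out
}

#' Semi-partial R-squared from an F statistic
#'
#' Effect size on the proportion-of-variance scale:
#' `R2 = (q F / d) / (1 + q F / d)` with `q` the numerator and `d` the
#' denominator degrees of freedom. With the Satterthwaite `d` this is an
#' approximation to the Kenward-Roger-based version of the statistic
#' (see the methods vignette for the divergence).
#'
#' @param F F statistic (>= 0).
#' @param df_num,df_den degrees of freedom (> 0).
#' @return R-squared in `[0, 1)`.
#' @export
semipartial_r2 <- function(F, df_num, df_den) {
  assert_that(is.finite(df_num) && is.finite(df_den) &&
                df_num > 0 && df_den > 0,
              "degrees of freedom must be positive", "stepinit_bad_df")
  assert_that(F >= 0, "F must be non-negative", "stepinit_bad_df")
  ratio <- df_num * F / df_den
  ratio / (1 + ratio)
}

#' Estimated marginal means for the emotion-by-condition cells
#'
#' Model-based cell means averaged with equal factor-level weights, with
#' standard errors from the fixed-effect covariance and Satterthwaite
#' degrees of freedom.
#'
#' @param fit result of [fit_crossed_lmm()].
#' @param spec emmeans specification (default `~ emotion * condition`).
#' @return data.frame with the factor columns plus `emmean`, `se`, `df`.
#' @export
emmeans_cells <- function(fit, spec = ~ emotion * condition) {
  emm <- emmeans::emmeans(fit, spec, lmer.df = "satterthwaite")
  s <- as.data.frame(summary(emm))
  names(s)[names(s) == "SE"] <- "se"
  s
}

#' Tukey-adjusted pairwise contrasts of marginal means
#'
#' All pairwise differences of the estimated marginal means, with
#' p values adjusted through the studentized-range distribution (family
#' size = number of means compared; Satterthwaite degrees of freedom).
#'
#' @param fit result of [fit_crossed_lmm()].
#' @param spec factors to compare (default `~ emotion`).
#' @param by optional conditioning factor (e.g. `"condition"` for
#'   within-condition emotion contrasts).
#' @return data.frame with `contrast`, estimate, `se`, `df`, `t`, and
#'   Tukey-adjusted `p`.
#' @export
tukey_contrasts <- function(fit, spec = ~ emotion, by = NULL) {
  emm <- emmeans::emmeans(fit, spec, by = by, lmer.df = "satterthwaite")
  prs <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "tukey"))
  names(prs)[names(prs) == "SE"] <- "se"
  names(prs)[names(prs) == "t.ratio"] <- "t"
  names(prs)[names(prs) == "p.value"] <- "p"
  prs
}

#' Analyse all outcomes of a long table
#'
#' Fits the crossed model per outcome and collects the ANOVA table,
#' cell marginal means, and within-condition emotion contrasts.
#'
#' @param outcomes data.frame of accepted go trials (long format with
#'   the six outcome columns).
#' @param outcome_names outcome columns to analyse.
#' @return named list (per outcome) of lists with elements `fit`,
#'   `anova`, `emm`, `contrasts`.
#' @export
analyze_outcomes <- function(outcomes, outcome_names = OUTCOMES) {
  res <- lapply(outcome_names, function(oc) {
    fit <- fit_crossed_lmm(outcomes, oc)
    list(fit = fit,
         anova = anova_satterthwaite(fit),
         emm = emmeans_cells(fit),
         contrasts = tukey_contrasts(fit, ~ emotion, by = "condition"))
  })
  names(res) <- outcome_names
  res
}
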