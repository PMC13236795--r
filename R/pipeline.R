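# Pipeline orchestration: schedule -> synthesis -> kinematics -> events
# -> QC -> statistics, reproducible from one master seed.

#' Default pipeline configuration
#'
#' Flat named list of every tunable of the run: design size, generative
#' parameters, filter settings, event-detection and QC thresholds, and
#' statistics settings. Serializable to/from YAML with
#' [write_config()] / [read_config()].
#'
#' @param n_participants even number of participants.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @return named list of class `stepinit_config`.
#' @export
default_config <- function(n_participants = 24, seed = 1L) {
  structure(list(
    n_participants = n_participants,
    seed = as.integer(seed),
    sampling_rate = 1000,
    filter_cutoff_hz = 10,
    filter_order = 4,
    filter_stage = "raw",
    z_offset_m = 0,
    noise_force_sd = 0.5,
    noise_moment_sd = 0.3,
    mass_mean_kg = 70,
    mass_sd_kg = 10,
    search_horizon_s = 2.5,
    onset_noise_mult = 5,
    onset_min_floor = 0.005,
    qc_rt_min_ms = 200,
    qc_rt_max_ms = 2000,
    qc_baseline_pp_cm = 1,
    alpha = 0.05
  ), class = c("stepinit_config", "list"))
}

#' @rdname default_config
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

config_params <- function(config) {
  generative_params(
    mass_mean = config$mass_mean_kg, mass_sd = config$mass_sd_kg,
    sampling_rate = config$sampling_rate,
    noise_force_sd = config$noise_force_sd,
    noise_moment_sd = config$noise_moment_sd,
    filter_cutoff_hz = config$filter_cutoff_hz
  )
}

#' Run the full pipeline
#'
#' Builds the experiment schedule, samples latent outcomes, synthesizes
#' every go trial, reduces it to kinematics, extracts events and the six
#' outcomes, applies the QC rules, and fits the crossed mixed model per
#' outcome on the accepted trials. Each trial is processed independently
#' (a failing trial is rejected, never fatal). With `out_dir` set, the
#' outcomes table, QC report, per-outcome statistics tables and a
#' machine-readable run manifest are written as tab-separated / JSON
#' files.
#'
#' @param config list from [default_config()] / [read_config()].
#' @param out_dir optional output directory.
#' @param noise logical; generate noisy channels (default TRUE).
#' @param stats logical; fit the mixed models (default TRUE).
#' @return list with `schedule`, `latents`, `outcomes` (accepted trials),
#'   `qc` (per-trial QC rows), `qc_summary`, `stats` (per-outcome list
#'   or NULL), `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         noise = TRUE, stats = TRUE) {
  params <- config_params(config)
  schedule <- build_experiment(config$n_participants, config$seed)
  latents <- sample_latent_outcomes(params, schedule,
                                    seed = derive_seed(config$seed, 104729))
  qc_rows <- vector("list", nrow(latents))
  out_rows <- vector("list", nrow(latents))
  thr <- qc_thresholds(config$qc_rt_min_ms, config$qc_rt_max_ms,
                       config$qc_baseline_pp_cm)
  for (i in seq_len(nrow(latents))) {
    rec <- synthesize_trial(latents[i, ], params,
                            seed = derive_seed(config$seed, i),
                            noise = noise, z_offset = config$z_offset_m)
    res <- try_outcomes(rec,
                        cutoff = config$filter_cutoff_hz,
                        order = config$filter_order,
                        z_offset = config$z_offset_m,
                        filter_stage = config$filter_stage,
                        search_horizon = config$search_horizon_s,
                        noise_mult = config$onset_noise_mult,
                        min_floor = config$onset_min_floor)
    qc_rows[[i]] <- assess_trial(rec, res, thr)
    if (res$ok && qc_rows[[i]]$accepted) out_rows[[i]] <- res$outcome
  }
  qc <- do.call(rbind, qc_rows)
  outcomes <- do.call(rbind, out_rows[!vapply(out_rows, is.null, TRUE)])
  names(outcomes)[names(outcomes) == "expression"] <- "emotion"
  qc_summary <- summarize_rejections(qc)
  stats_res <- if (stats) analyze_outcomes(outcomes) else NULL

  result <- list(schedule = schedule, latents = latents, outcomes = outcomes,
                 qc = qc, qc_summary = qc_summary, stats = stats_res,
                 config = config)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(result$schedule, "schedule.tsv")
  tsv(result$outcomes, "outcomes.tsv")
  tsv(result$qc, "qc_report.tsv")
  if (!is.null(result$stats)) {
    for (oc in names(result$stats)) {
      tsv(result$stats[[oc]]$anova, sprintf("anova_%s.tsv", oc))
      tsv(result$stats[[oc]]$emm, sprintf("emmeans_%s.tsv", oc))
      tsv(result$stats[[oc]]$contrasts, sprintf("contrasts_%s.tsv", oc))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("stepinit")),
    r_version = R.version.string,
    config = unclass(result$config),
    n_trials_go = nrow(result$qc),
    n_accepted = sum(result$qc$accepted),
    rejections = as.list(result$qc_summary$counts),
    fraction_rejected = result$qc_summary$fraction_rejected
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
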