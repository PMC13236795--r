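# Go-trial rejection rules.

#' Quality-control thresholds
#'
#' @param rt_min_ms,rt_max_ms accepted reaction-time range, inclusive
#'   (200 and 2000 ms).
#' @param baseline_pp_cm maximum accepted peak-to-peak CP excursion over
#'   the 500 ms pre-onset window, cm. The threshold is configurable; the
#'   default of 1 cm sits an order of magnitude below typical APA
#'   amplitudes.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(rt_min_ms = 200, rt_max_ms = 2000,
                          baseline_pp_cm = 1) {
  list(rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
       baseline_pp_cm = baseline_pp_cm)
}

#' Apply the four go-trial rejection rules to one trial
#'
#' Rules, in order (the first failing rule is reported):
#' \describe{
#'   \item{a (`no_go_response`)}{no qualifying postural onset was found
#'     within the search horizon (movement omission);}
#'   \item{b (`wrong_limb`)}{the stepping limb recorded in the metadata
#'     mismatches the dominant limb;}
#'   \item{c (`rt_out_of_range`)}{reaction time outside 200-2000 ms
#'     (bounds inclusive);}
#'   \item{d (`baseline_motion`)}{peak-to-peak CP excursion over the
#'     500 ms pre-onset window above the threshold.}
#' }
#'
#' @param record a `force_plate_record` (must be a go trial).
#' @param result result of [try_outcomes()] for the record; computed
#'   here if omitted.
#' @param thresholds [qc_thresholds()] list.
#' @return one-row data.frame: trial metadata, `accepted`, `reason`
#'   (`"none"`, `"a_no_go_response"`, `"b_wrong_limb"`,
#'   `"c_rt_out_of_range"`, `"d_baseline_motion"`).
#' @export
assess_trial <- function(record, result = NULL,
                         thresholds = qc_thresholds()) {
  stopifnot(inherits(record, "force_plate_record"))
  tt <- record$meta$trial_type %||% "go"
  assert_that(identical(tt, "go"), "QC applies to go trials only",
              "stepinit_not_go_trial")
  if (is.null(result)) result <- try_outcomes(record)

  reason <- "none"
  if (!result$ok) {
    reason <- "a_no_go_response"
  } else if (!identical(record$meta$stepping_limb %||% "dominant",
                        record$meta$dominant_limb %||% "dominant")) {
    reason <- "b_wrong_limb"
  } else if (result$outcome$rt_ms < thresholds$rt_min_ms ||
             result$outcome$rt_ms > thresholds$rt_max_ms) {
    reason <- "c_rt_out_of_range"
  } else if (result$baseline_pp_cm > thresholds$baseline_pp_cm) {
    reason <- "d_baseline_motion"
  }

  meta <- record$meta
  meta_cols <- intersect(c("participant_id", "condition", "group", "block",
                           "presentation_index", "face_id", "expression"),
                         names(meta))
  out <- as.data.frame(meta[meta_cols], stringsAsFactors = FALSE)
  if (nrow(out) == 0) out <- data.frame(row.names = 1)
  out$accepted <- reason == "none"
  out$reason <- reason
  rownames(out) <- NULL
  out
}

#' Summarize rejections over a set of QC results
#'
#' @param results data.frame of stacked [assess_trial()] rows.
#' @return list with `counts` (named vector per reason), `n_total`,
#'   `n_rejected` and `fraction_rejected`.
#' @export
summarize_rejections <- function(results) {
  assert_that(is.data.frame(results) && nrow(results) > 0,
              "results must be a nonempty data.frame", "stepinit_empty_qc")
  reasons <- c("a_no_go_response", "b_wrong_limb", "c_rt_out_of_range",
               "d_baseline_motion")
  counts <- vapply(reasons, function(r) sum(results$reason == r), 0L)
  n_rej <- sum(!results$accepted)
  stopifnot(sum(counts) == n_rej)
  list(counts = counts, n_total = nrow(results), n_rejected = n_rej,
       fraction_rejected = n_rej / nrow(results))
}
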