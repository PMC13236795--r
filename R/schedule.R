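#' Default face stimulus set
#'
#' The experiment uses 10 face identities (5 men, 5 women), each available
#' in four expressions (neutral, fearful, angry, happy). Identities are
#' opaque labels; images are out of scope.
#'
#' @return A data.frame with columns `face_id` and `gender`.
#' @export
default_face_set <- function() {
  data.frame(
    face_id = c(sprintf("M%02d", 1:5), sprintf("F%02d", 1:5)),
    gender = rep(c("male", "female"), each = 5),
    stringsAsFactors = FALSE
  )
}

validate_face_set <- function(face_set) {
  assert_that(is.data.frame(face_set) &&
                all(c("face_id", "gender") %in% names(face_set)),
              "face_set must be a data.frame with columns face_id, gender",
              "stepinit_bad_face_set")
  assert_that(!anyDuplicated(face_set$face_id),
              "face identities must be unique", "stepinit_bad_face_set")
  n_m <- sum(face_set$gender == "male")
  n_f <- sum(face_set$gender == "female")
  assert_that(n_m == 5 && n_f == 5 && nrow(face_set) == 10,
              "face_set must hold exactly 5 male and 5 female identities",
              "stepinit_bad_face_set")
  invisible(face_set)
}

#' Expressions used in the experiment
#' @keywords internal
EMOTIONS <- c("fearful", "angry", "happy")

# Per-condition trial composition. Returns an unordered data.frame of
# trials (face_id, gender, expression, trial_type).
condition_trial_set <- function(condition, group, face_set) {
  validate_face_set(face_set)
  if (condition == "neutral_vs_emotional") {
    assert_that(group == "all",
                "group must be 'all' in the neutral_vs_emotional condition",
                "stepinit_group_condition_mismatch")
    go <- expand.grid(face_id = face_set$face_id, expression = EMOTIONS,
                      stringsAsFactors = FALSE)
    go$trial_type <- "go"
    nogo <- data.frame(face_id = face_set$face_id, expression = "neutral",
                       trial_type = "no_go", stringsAsFactors = FALSE)
    trials <- rbind(go, nogo)
  } else if (condition == "face_gender") {
    assert_that(group %in% c("go_men", "go_women"),
                "group must be 'go_men' or 'go_women' in the face_gender condition",
                "stepinit_group_condition_mismatch")
    go_gender <- if (group == "go_men") "male" else "female"
    nogo_gender <- setdiff(c("male", "female"), go_gender)
    go_ids <- sort(face_set$face_id[face_set$gender == go_gender])
    nogo_ids <- sort(face_set$face_id[face_set$gender == nogo_gender])
    # each go identity x 3 expressions, presented twice (30 go trials)
    go <- expand.grid(face_id = go_ids, expression = EMOTIONS,
                      rep = 1:2, stringsAsFactors = FALSE)[, 1:2]
    go$trial_type <- "go"
    # no-go: 3 identities carry all three expressions, one extra angry trial
    # from a fourth identity; identities chosen in lowest-identifier order.
    nogo <- rbind(
      expand.grid(face_id = nogo_ids[1:3], expression = EMOTIONS,
                  stringsAsFactors = FALSE),
      data.frame(face_id = nogo_ids[4], expression = "angry",
                 stringsAsFactors = FALSE)
    )
    nogo$trial_type <- "no_go"
    trials <- rbind(go, nogo)
  } else {
    stop_stepinit(sprintf("unknown condition '%s'", condition),
                  "stepinit_bad_condition")
  }
  trials$gender <- face_set$gender[match(trials$face_id, face_set$face_id)]
  trials[, c("face_id", "gender", "expression", "trial_type")]
}

#' Build the randomized trial schedule for one condition
#'
#' Constructs the go/no-go trial list for one participant and one
#' condition (30 go + 10 no-go trials) and places it in a seeded random
#' presentation order. In the neutral-vs-emotional condition the 10
#' identities appear in the three emotional expressions (go) and in the
#' neutral expression (no-go). In the face-gender condition the five
#' identities of the go gender appear in the three emotional expressions
#' twice each (go), and four identities of the other gender provide the
#' 10 no-go trials (three with all three expressions plus one extra angry
#' trial).
#'
#' @param condition `"neutral_vs_emotional"` or `"face_gender"`.
#' @param group `"all"` (required for neutral_vs_emotional) or
#'   `"go_men"` / `"go_women"` (face_gender).
#' @param face_set data.frame as from [default_face_set()].
#' @param seed integer seed for the presentation order.
#' @param participant_id identifier copied into every row.
#' @param timing list with elements `fixation_s`, `face_s`, `iti_s`
#'   (defaults 2, 1, 3). The face appears `fixation_s` seconds into each
#'   trial.
#' @return A data.frame (one row per trial) with columns `participant_id`,
#'   `condition`, `group`, `presentation_index`, `face_id`, `gender`,
#'   `expression`, `trial_type`, `face_onset_s`, sorted by
#'   `presentation_index`.
#' @export
build_condition_schedule <- function(condition, group,
                                     face_set = default_face_set(),
                                     seed = 1L,
                                     participant_id = 1L,
                                     timing = list(fixation_s = 2, face_s = 1,
                                                   iti_s = 3)) {
  trials <- condition_trial_set(condition, group, face_set)
  n <- nrow(trials)
  ord <- with_seed(seed, sample.int(n))
  trials <- trials[ord, , drop = FALSE]
  trials$presentation_index <- seq_len(n)
  trials$participant_id <- participant_id
  trials$condition <- condition
  trials$group <- group
  trials$face_onset_s <- timing$fixation_s %||% 2
  rownames(trials) <- NULL
  trials[, c("participant_id", "condition", "group", "presentation_index",
             "face_id", "gender", "expression", "trial_type", "face_onset_s")]
}

#' Build the full experiment schedule
#'
#' Assigns participants to the go-men / go-women instruction groups
#' (exactly half each, seeded), draws a per-participant condition order,
#' and builds both per-condition schedules for every participant.
#'
#' @param n_participants even number of participants (24 in the study).
#' @param seed master integer seed; participant-level sub-seeds are derived
#'   deterministically from it.
#' @param face_set data.frame as from [default_face_set()].
#' @return A data.frame of all trials with the columns of
#'   [build_condition_schedule()] plus `block` (1 or 2, the position of the
#'   condition in the participant's session).
#' @export
build_experiment <- function(n_participants = 24, seed = 1L,
                             face_set = default_face_set()) {
  assert_that(n_participants >= 2 && n_participants %% 2 == 0,
              "n_participants must be an even number >= 2",
              "stepinit_odd_participants")
  validate_face_set(face_set)
  go_men_ids <- with_seed(seed,
                          sort(sample.int(n_participants, n_participants / 2)))
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    grp <- if (p %in% go_men_ids) "go_men" else "go_women"
    p_seed <- derive_seed(seed, p)
    conds <- with_seed(p_seed,
                       sample(c("neutral_vs_emotional", "face_gender")))
    blocks <- lapply(seq_along(conds), function(b) {
      sched <- build_condition_schedule(
        condition = conds[b],
        group = if (conds[b] == "neutral_vs_emotional") "all" else grp,
        face_set = face_set,
        seed = derive_seed(p_seed, b),
        participant_id = p
      )
      sched$block <- b
      sched
    })
    out[[p]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a schedule as a tab-separated table
#'
#' @param schedule data.frame from [build_experiment()] or
#'   [build_condition_schedule()].
#' @param path file path.
#' @return `read_schedule` returns the schedule data.frame.
#' @export
write_schedule <- function(schedule, path) {
  write.table(schedule, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
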