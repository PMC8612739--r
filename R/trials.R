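# Trial-table schema, validation, I/O, outcome coding and filtering.

trial_cols <- c("participant_id", "group", "age_months", "block", "posture",
                "condition", "tactile_side", "auditory_side",
                "response_modality", "response_side", "rt_s", "valid")

#' Validate a trial table
#'
#' Checks every row of a trial table against the schema invariants: factor
#' levels, consistency of the stimulated sides with the condition, the
#' linkage between null responses and missing reaction times, and the
#' response window (reaction times must lie in (0, 8] seconds, the 8 s
#' post-stimulus observation window).
#'
#' @param trials A data frame with the trial-table columns (see
#'   [read_trials()] for the schema).
#' @return The input as a tibble, invisibly, if valid; otherwise an error
#'   listing the offending row numbers.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_cols, names(trials))
  if (length(missing)) {
    abort(paste0("Trial table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  trials <- as_tibble(trials)
  bad <- list()
  flag <- function(cond, label) {
    rows <- which(cond)
    if (length(rows)) bad[[label]] <<- rows
  }
  flag(!trials$group %in% at_groups, "group not in {SVI, S}")
  flag(!trials$posture %in% at_postures, "posture not in {uncrossed, crossed}")
  flag(!trials$condition %in% at_conditions, "unknown condition")
  flag(!trials$block %in% 1:6, "block outside 1-6")
  flag(!is.numeric(trials$age_months) | trials$age_months < 0,
       "negative age_months")
  flag(!schedule_sides_consistent(trials),
       "stimulated sides inconsistent with condition")
  is_null_resp <- trials$response_modality == "null"
  flag(is_null_resp != (trials$response_side == "null") |
         is_null_resp != is.na(trials$rt_s),
       "null response must have null side and absent rt_s")
  flag(!is_null_resp &
         !trials$response_modality %in% at_modalities,
       "unknown response_modality")
  flag(!is_null_resp & !trials$response_side %in% at_sides,
       "unknown response_side")
  flag(!is.na(trials$rt_s) & (trials$rt_s <= 0 | trials$rt_s > 8),
       "rt_s outside (0, 8] s")
  if (length(bad)) {
    msgs <- purrr::imap_chr(bad, function(rows, label) {
      sprintf("%s (rows %s)", label,
              paste(head(rows, 10), collapse = ", "))
    })
    abort(c("Trial table failed validation:", msgs))
  }
  invisible(trials)
}

#' Read a trial table from delimited text
#'
#' Reads a comma-delimited UTF-8 trial table with the header
#' `participant_id,group,age_months,block,posture,condition,tactile_side,`
#' `auditory_side,response_modality,response_side,rt_s,valid` (an empty
#' `rt_s` field encodes an absent reaction time) and validates every row.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of trials.
#' @export
read_trials <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, trial_cols)) {
    abort(c("Trial file header does not match the documented schema.",
            paste0("expected: ", paste(trial_cols, collapse = ",")),
            paste0("found:    ", paste(hdr, collapse = ","))))
  }
  trials <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      age_months = readr::col_integer(),
      block = readr::col_integer(),
      posture = readr::col_character(),
      condition = readr::col_character(),
      tactile_side = readr::col_character(),
      auditory_side = readr::col_character(),
      response_modality = readr::col_character(),
      response_side = readr::col_character(),
      rt_s = readr::col_double(),
      valid = readr::col_logical()
    )
  )
  validate_trials(trials)
  trials
}

#' Write a trial table to delimited text
#'
#' Inverse of [read_trials()]: absent reaction times are written as empty
#' fields.
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[trial_cols], path, na = "")
  invisible(path)
}

#' Code the binary orienting outcome
#'
#' Adds the binary outcome columns used by the mixed models:
#' `correct_side` is 1 when the response was made with or toward the
#' stimulated limb and 0 when it targeted the unstimulated limb; it is
#' undefined (`NA`) for null responses and for audiotactile-incongruent
#' trials, where both hands are stimulated. For incongruent trials
#' `toward_auditory` codes 1 when the response targeted the auditory
#' stimulus location and 0 when it targeted the tactile one.
#'
#' @param trials A validated trial tibble.
#' @return The tibble with `correct_side` and `toward_auditory` columns.
#' @export
add_response_outcome <- function(trials) {
  stim_side <- ifelse(trials$condition == "auditory_only",
                      trials$auditory_side, trials$tactile_side)
  responded <- trials$response_side %in% at_sides
  mutate(
    as_tibble(trials),
    correct_side = dplyr::case_when(
      !responded ~ NA_integer_,
      condition == "at_incongruent" ~ NA_integer_,
      TRUE ~ as.integer(.data$response_side == stim_side)
    ),
    toward_auditory = dplyr::case_when(
      !responded ~ NA_integer_,
      condition != "at_incongruent" ~ NA_integer_,
      TRUE ~ as.integer(.data$response_side == .data$auditory_side)
    )
  )
}

#' Filter trials for analysis
#'
#' Removes trials marked invalid, null-response trials, and (optionally)
#' responses with reaction times longer than `rt_cutoff_s` seconds. The
#' cutoff is strict: a response at exactly the cutoff is retained. Counts
#' removed at each step, per group, are attached as the `"removed"`
#' attribute for trial accounting.
#'
#' @param trials A validated trial tibble.
#' @param rt_cutoff_s Reaction-time cutoff in seconds, or `NULL` for no
#'   cutoff. The study's sensitivity analyses used 4 s.
#' @return The filtered tibble, with a `"removed"` attribute holding a
#'   per-group tibble of `n_invalid`, `n_null` and `n_over_cutoff`.
#' @export
filter_trials <- function(trials, rt_cutoff_s = NULL) {
  trials <- as_tibble(trials)
  keep_valid <- trials$valid
  keep_resp <- trials$response_modality != "null"
  keep_rt <- if (is.null(rt_cutoff_s)) rep(TRUE, nrow(trials)) else
    (is.na(trials$rt_s) | trials$rt_s <= rt_cutoff_s)
  removed <- tibble(
    group = trials$group,
    invalid = !keep_valid,
    null = keep_valid & !keep_resp,
    over = keep_valid & keep_resp & !keep_rt
  ) %>%
    group_by(.data$group) %>%
    summarise(n_invalid = sum(.data$invalid), n_null = sum(.data$null),
              n_over_cutoff = sum(.data$over), .groups = "drop")
  out <- trials[keep_valid & keep_resp & keep_rt, ]
  attr(out, "removed") <- removed
  out
}
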