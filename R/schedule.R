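# Session schedule generation under the published design constraints.
#
# One session comprises 6 blocks: blocks 1-3 with hands uncrossed, 4-6
# crossed. Auditory-only, audiotactile-congruent and audiotactile-incongruent
# trials are interleaved in blocks 1, 2, 4 and 5; tactile-only trials are
# presented separately in blocks 3 and 6. Each condition occurs 12 times
# (6 per posture), 48 trials in all, and the same hand is never stimulated
# with the same sensory cue (auditory/tactile) on more than 2 consecutive
# trials.

#' Generate a pseudorandom session schedule
#'
#' Builds the fixed trial order for one session by constrained
#' pseudorandomization: block-wise permutations are drawn and rejected until
#' the run-length constraint is satisfied. The same schedule is used for
#' every participant of a simulated study (the original design kept the
#' order constant across participants).
#'
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param max_attempts Maximum permutations tried per block before failing.
#' @return A tibble with one row per trial and columns `trial`, `block`
#'   (1-6), `posture`, `condition`, `tactile_side`, `auditory_side`.
#'   The seed is stored in the `"seed"` attribute.
#' @examples
#' sched <- make_schedule(seed = 1)
#' dplyr::count(sched, condition)
#' @export
make_schedule <- function(seed = 1L, max_attempts = 10000L) {
  with_local_seed(seed, {
    out <- NULL
    for (post in at_postures) {
      first_block <- if (post == "uncrossed") 1L else 4L
      carry <- if (is.null(out)) NULL else utils::tail(out, 2)
      mixed <- schedule_mixed_blocks(first_block, post, max_attempts, carry)
      out <- bind_rows(out, mixed)
      tact <- schedule_tactile_block(first_block + 2L, post, max_attempts,
                                     carry = utils::tail(out, 2))
      out <- bind_rows(out, tact)
    }
    out <- mutate(out, trial = row_number(), .before = 1)
  })
  stopifnot(nrow(out) == 48L)
  attr(out, "seed") <- as.integer(seed)
  out
}

# The 18-trial pool for one posture's interleaved blocks: 6 auditory-only,
# 6 congruent, 6 incongruent, each side-balanced.
mixed_pool <- function(posture) {
  tibble(
    posture = posture,
    condition = rep(c("auditory_only", "at_congruent", "at_incongruent"), each = 6),
    side = rep(rep(at_sides, each = 3), times = 3)
  ) %>%
    mutate(
      tactile_side = dplyr::case_when(
        condition == "auditory_only" ~ "none",
        condition == "at_congruent" ~ side,
        condition == "at_incongruent" ~ ifelse(side == "left", "right", "left")
      ),
      auditory_side = ifelse(condition == "tactile_only", "none", side)
    ) %>%
    select(-"side")
}

schedule_mixed_blocks <- function(first_block, posture, max_attempts,
                                  carry = NULL) {
  pool <- mixed_pool(posture)
  if (!is.null(carry)) carry <- carry[names(pool)]
  for (i in seq_len(max_attempts)) {
    cand <- pool[sample.int(nrow(pool)), ]
    if (max_stimulus_run(bind_rows(carry, cand)) <= 2L) {
      cand$block <- rep(c(first_block, first_block + 1L), each = 9L)
      return(select(cand, "block", "posture", "condition",
                    "tactile_side", "auditory_side"))
    }
  }
  abort("Could not satisfy the run-length constraint for the interleaved blocks.")
}

schedule_tactile_block <- function(block, posture, max_attempts, carry = NULL) {
  pool <- tibble(
    posture = posture, condition = "tactile_only",
    tactile_side = rep(at_sides, each = 3), auditory_side = "none"
  )
  for (i in seq_len(max_attempts)) {
    cand <- pool[sample.int(nrow(pool)), ]
    if (max_stimulus_run(bind_rows(carry, cand)) <= 2L) {
      cand$block <- block
      return(select(cand, "block", "posture", "condition",
                    "tactile_side", "auditory_side"))
    }
  }
  abort("Could not satisfy the run-length constraint for the tactile block.")
}

#' Longest same-hand same-cue run in a stimulus sequence
#'
#' Scans a schedule (or trial table) and returns the length of the longest
#' run of consecutive trials on which the same hand is stimulated with the
#' same sensory cue (auditory or tactile).
#'
#' @param schedule A data frame with `tactile_side` and `auditory_side`.
#' @return Integer maximum run length.
#' @export
max_stimulus_run <- function(schedule) {
  run_len <- function(sides) {
    r <- rle(as.character(sides))
    max(c(0L, r$lengths[r$values %in% at_sides]))
  }
  max(run_len(schedule$tactile_side), run_len(schedule$auditory_side))
}

#' Check a session schedule against the design constraints
#'
#' Verifies block structure (6 blocks, uncrossed then crossed), confinement
#' of tactile-only trials to blocks 3 and 6, the per-condition and
#' per-posture counts (12 per condition, 6 per posture, 48 trials), and the
#' run-length constraint.
#'
#' @param schedule A schedule tibble as from [make_schedule()].
#' @return Invisibly `TRUE`; otherwise an error naming the violated
#'   constraint.
#' @export
validate_schedule <- function(schedule) {
  fail <- function(msg) abort(paste0("Invalid schedule: ", msg))
  if (nrow(schedule) != 48L) fail("must have exactly 48 trials.")
  if (!setequal(unique(schedule$block), 1:6)) fail("must use blocks 1-6.")
  post <- ifelse(schedule$block <= 3, "uncrossed", "crossed")
  if (!all(schedule$posture == post)) {
    fail("blocks 1-3 must be uncrossed and 4-6 crossed.")
  }
  tact_blocks <- unique(schedule$block[schedule$condition == "tactile_only"])
  if (!setequal(tact_blocks, c(3L, 6L))) {
    fail("tactile-only trials must appear in blocks 3 and 6 only.")
  }
  counts <- dplyr::count(schedule, .data$condition, .data$posture)
  if (nrow(counts) != 8L || !all(counts$n == 6L)) {
    fail("each condition must occur 6 times per posture.")
  }
  if (max_stimulus_run(schedule) > 2L) {
    fail("same hand stimulated with the same cue on more than 2 consecutive trials.")
  }
  if (!all(schedule_sides_consistent(schedule))) {
    fail("stimulated sides are inconsistent with the condition.")
  }
  invisible(TRUE)
}

# row-wise check that the condition determines which side columns are non-none
schedule_sides_consistent <- function(df) {
  (
    ifelse(df$condition == "tactile_only",
           df$tactile_side %in% at_sides & df$auditory_side == "none",
    ifelse(df$condition == "auditory_only",
           df$auditory_side %in% at_sides & df$tactile_side == "none",
    ifelse(df$condition == "at_congruent",
           df$tactile_side %in% at_sides & df$auditory_side == df$tactile_side,
           df$tactile_side %in% at_sides & df$auditory_side %in% at_sides &
             df$tactile_side != df$auditory_side)))
  )
}
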