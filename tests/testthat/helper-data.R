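# Shared fixture builders: everything is generated in code at test time.

# A minimal hand-written trial table covering all conditions.
tiny_trials <- function() {
  tibble::tibble(
    participant_id = rep(c("S01", "V01"), each = 4),
    group = rep(c("S", "SVI"), each = 4),
    age_months = rep(c(12L, 24L), each = 4),
    block = rep(c(1L, 1L, 3L, 4L), 2),
    posture = rep(c("uncrossed", "uncrossed", "uncrossed", "crossed"), 2),
    condition = rep(c("auditory_only", "at_congruent", "tactile_only",
                      "at_incongruent"), 2),
    tactile_side = rep(c("none", "left", "right", "left"), 2),
    auditory_side = rep(c("left", "left", "none", "right"), 2),
    response_modality = rep(c("eye_head", "arm_hand", "arm_hand", "null"), 2),
    response_side = rep(c("left", "left", "left", "null"), 2),
    rt_s = rep(c(1.2, 0.9, 2.1, NA), 2),
    valid = TRUE
  )
}

# Hand-built trials with a prescribed per-cell outcome pattern: `cells` is a
# tibble with group, posture, age_months, n, n_correct for a single-condition
# design (used for closed-form logit oracles).
trials_from_counts <- function(cells, condition = "auditory_only") {
  cond <- condition
  purrr::pmap_dfr(cells, function(group, posture, age_months, n, n_correct) {
    correct <- rep(c(1L, 0L), c(n_correct, n - n_correct))
    side <- ifelse(correct == 1, "left", "right")
    tibble::tibble(
      participant_id = paste0(group, "_", posture, "_", age_months, "_",
                              seq_len(n)),
      group = group, age_months = age_months,
      block = if (posture == "uncrossed") 1L else 4L,
      posture = posture, condition = cond,
      tactile_side = if (cond == "tactile_only") "left" else "none",
      auditory_side = if (cond == "auditory_only") "left" else "none",
      response_modality = "arm_hand", response_side = side,
      rt_s = 1.5, valid = TRUE
    )
  })
}

# Small simulated dataset shared by several tests.
small_sim <- function(seed = 7, ...) {
  simulate_dataset(sim_config(n_per_group = 5L, seed = seed, ...))
}

# Independent inverse-step-CDF oracle: exhaustive scan over sorted values.
scan_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  for (v in xs) {
    if (sum(xs <= v) / n >= q - 1e-12) return(v)
  }
  xs[n]
}
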