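# Race-model redundancy-gain analysis.
#
# The race-model inequality bounds the bimodal reaction-time CDF by the sum
# of the two unisensory CDFs: P(RT_AT <= t) <= F_A(t) + F_T(t). Gains are
# measured in the reaction-time (horizontal) domain at the nine deciles of
# the CDFs, within participant first, then aggregated across participants.

at_deciles <- seq(0.1, 0.9, by = 0.1)

#' Empirical reaction-time quantiles (inverse step-CDF)
#'
#' Type-1 quantiles of the empirical CDF `F(t) = #{rt <= t} / n`: the
#' quantile at probability `q` is the smallest observed reaction time with
#' `F(rt) >= q`. This estimator inverts a step function, consistent with
#' how the race-model bound (itself a step function) is inverted.
#'
#' @param rts Numeric vector of reaction times (seconds), at least one.
#' @param probs Probabilities in (0, 1), sorted.
#' @param type `"step"` (default) for the inverse step-CDF estimator used
#'   throughout the gain analysis; `"interpolated"` for the conventional
#'   linearly interpolated estimator, provided for exploratory comparison
#'   only (it is not consistent with inverting the step-function bound).
#' @return Numeric vector of quantiles, one per probability.
#' @export
rt_quantile <- function(rts, probs = at_deciles,
                        type = c("step", "interpolated")) {
  type <- match.arg(type)
  if (length(rts) == 0) abort("Empty reaction-time list (missing cell).")
  stopifnot(all(probs > 0 & probs < 1), !is.unsorted(probs))
  if (type == "interpolated") {
    return(quantile(rts, probs, type = 7, names = FALSE))
  }
  xs <- sort(rts)
  n <- length(xs)
  # smallest order statistic whose step-CDF value reaches the target; the
  # small slack keeps decile grids like 3/10 from tipping over a step edge
  idx <- pmax(1L, ceiling(n * probs - 1e-9))
  xs[idx]
}

#' Quantiles of the race-model bound
#'
#' Evaluates the race-model bound `G(t) = min(1, F_A(t) + F_T(t))` on the
#' pooled support of the two unisensory reaction-time samples and inverts
#' it the same way as [rt_quantile()]: the bound quantile at `q` is the
#' smallest pooled reaction time with `G(rt) >= q`. Capping at 1 cannot
#' affect any decile at or below 0.9.
#'
#' @param rt_a,rt_t Unisensory (auditory-only, tactile-only) reaction
#'   times in seconds; both non-empty.
#' @param probs Probabilities in (0, 1), sorted.
#' @return Numeric vector of bound quantiles.
#' @export
race_bound_quantiles <- function(rt_a, rt_t, probs = at_deciles) {
  if (length(rt_a) == 0 || length(rt_t) == 0) {
    abort("Both unisensory reaction-time lists must be non-empty (missing cell).")
  }
  stopifnot(all(probs > 0 & probs < 1), !is.unsorted(probs))
  ts <- sort(unique(c(rt_a, rt_t)))
  g <- pmin(1, stats::ecdf(rt_a)(ts) + stats::ecdf(rt_t)(ts))
  vapply(probs, function(q) ts[which(g >= q - 1e-9)[1]], numeric(1))
}

#' Per-participant decile profiles of the reaction-time CDFs
#'
#' For each participant and posture, computes the decile quantiles of the
#' reaction times of responses made to the stimulated hand in the
#' auditory-only (`A`), tactile-only (`T`) and audiotactile-congruent
#' (`AT`) conditions, plus the race-model bound (`race_bound`) derived
#' from that participant's `A` and `T` samples. Cells with no analyzable
#' reaction times are omitted and listed in the `"missing_cells"`
#' attribute.
#'
#' @param trials A validated trial tibble.
#' @param probs Probabilities in (0, 1); default the nine deciles.
#' @return A long tibble with `participant_id`, `group`, `posture`,
#'   `condition` (`A`, `T`, `AT`, `race_bound`), `prob`, `rt`.
#' @export
participant_quantiles <- function(trials, probs = at_deciles) {
  cond_map <- c(auditory_only = "A", tactile_only = "T", at_congruent = "AT")
  df <- trials %>%
    add_response_outcome() %>%
    filter(.data$valid, .data$condition %in% names(cond_map),
           .data$correct_side %in% 1L, !is.na(.data$rt_s)) %>%
    mutate(condition = unname(cond_map[.data$condition]))
  cells <- df %>%
    group_by(.data$participant_id, .data$group, .data$posture,
             .data$condition) %>%
    summarise(rts = list(.data$rt_s), .groups = "drop")
  profs <- cells %>%
    mutate(q = purrr::map(.data$rts, rt_quantile, probs = probs)) %>%
    select(-"rts") %>%
    tidyr::unnest_longer("q", values_to = "rt") %>%
    mutate(prob = rep(probs, times = nrow(cells)))
  bounds <- tidyr::pivot_wider(cells, names_from = "condition",
                               values_from = "rts")
  if (all(c("A", "T") %in% names(bounds))) {
    bounds <- bounds %>%
      filter(!purrr::map_lgl(.data$A, is.null),
             !purrr::map_lgl(.data$T, is.null))
    if (nrow(bounds) > 0) {
      n_cells <- nrow(bounds)
      bounds <- bounds %>%
        mutate(q = purrr::map2(.data$A, .data$T, race_bound_quantiles,
                               probs = probs)) %>%
        select("participant_id", "group", "posture", "q") %>%
        mutate(condition = "race_bound") %>%
        tidyr::unnest_longer("q", values_to = "rt") %>%
        mutate(prob = rep(probs, times = n_cells))
      profs <- bind_rows(profs, bounds)
    }
  }
  full <- tidyr::crossing(
    distinct(trials, .data$participant_id, .data$group),
    posture = at_postures, condition = c("A", "T", "AT")
  )
  have <- distinct(profs, .data$participant_id, .data$posture, .data$condition)
  missing <- dplyr::anti_join(
    full, have, by = c("participant_id", "posture", "condition"))
  out <- select(profs, "participant_id", "group", "posture", "condition",
                "prob", "rt") %>%
    arrange(.data$participant_id, .data$posture, .data$condition, .data$prob)
  attr(out, "missing_cells") <- missing
  out
}

#' Redundancy gains against the race-model bound
#'
#' Per participant, posture and decile, the multisensory gain is the
#' race-bound quantile minus the audiotactile quantile (positive when the
#' bimodal responses beat the bound, i.e. a race-model violation).
#' Participants missing any of the `A`, `T` or `AT` cells for a posture
#' are dropped listwise from that posture (logged in the attribute).
#' Group-level tests per posture and decile are one-sample one-tailed
#' t tests of the mean gain against zero (H1: gain > 0) and two-tailed
#' Welch t tests between groups; both families are Bonferroni-corrected
#' for the nine deciles.
#'
#' @param x A trial tibble, or a profile tibble from
#'   [participant_quantiles()].
#' @param probs Probabilities (deciles by default); the Bonferroni family
#'   size is their number.
#' @return An object of class `"race_gain"`: a list with `gains`
#'   (per-participant), `tests` (per group x posture x decile) and
#'   `group_tests` (per posture x decile).
#' @export
redundancy_gain <- function(x, probs = at_deciles) {
  profiles <- if ("prob" %in% names(x)) x else participant_quantiles(x, probs)
  m <- length(probs)
  wide <- profiles %>%
    filter(.data$condition %in% c("AT", "race_bound")) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "rt") %>%
    filter(!is.na(.data$AT), !is.na(.data$race_bound)) %>%
    mutate(gain = .data$race_bound - .data$AT)
  complete <- wide %>%
    dplyr::count(.data$participant_id, .data$group, .data$posture) %>%
    filter(.data$n == m)
  gains <- dplyr::semi_join(
    wide, complete, by = c("participant_id", "group", "posture")) %>%
    select("participant_id", "group", "posture", "prob", "gain")
  tests <- gains %>%
    group_by(.data$group, .data$posture, .data$prob) %>%
    summarise(
      n = dplyr::n(), mean_gain_s = mean(.data$gain),
      se = sd(.data$gain) / sqrt(dplyr::n()), .groups = "drop"
    ) %>%
    mutate(
      t = .data$mean_gain_s / .data$se,
      df = .data$n - 1,
      p = pt(.data$t, .data$df, lower.tail = FALSE),
      p_adj = pmin(1, m * .data$p)
    )
  tests$t[tests$n < 2] <- NA_real_
  group_tests <- gains %>%
    group_by(.data$posture, .data$prob) %>%
    summarise(welch_gain_test(.data$gain, .data$group), .groups = "drop") %>%
    mutate(p_adj = pmin(1, m * .data$p))
  dropped <- dplyr::anti_join(
    distinct(wide, .data$participant_id, .data$group, .data$posture),
    complete, by = c("participant_id", "group", "posture"))
  structure(
    list(gains = gains, tests = tests, group_tests = group_tests,
         probs = probs, dropped = dropped),
    class = "race_gain"
  )
}

# Welch two-sample comparison of per-participant gains, S minus SVI.
welch_gain_test <- function(gain, group) {
  s <- gain[group == "S"]
  v <- gain[group == "SVI"]
  if (length(s) < 2 || length(v) < 2) {
    return(tibble(estimate = mean(s) - mean(v), t = NA_real_,
                  df = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(s, v, var.equal = FALSE)
  tibble(estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
}

#' @export
print.race_gain <- function(x, ...) {
  cat("<race_gain>", nrow(x$gains) / length(x$probs),
      "participant x posture cells,", length(x$probs), "deciles\n")
  sig <- sum(x$tests$p_adj < 0.05, na.rm = TRUE)
  cat("  gain tests with adjusted p < 0.05:", sig, "of", nrow(x$tests), "\n")
  invisible(x)
}

#' @method tidy race_gain
#' @export
tidy.race_gain <- function(x, ...) x$tests

#' @method glance race_gain
#' @export
glance.race_gain <- function(x, ...) {
  tibble(
    n_cells = nrow(distinct(x$gains, .data$participant_id, .data$posture)),
    n_dropped = nrow(x$dropped),
    n_sig_gain = sum(x$tests$p_adj < 0.05, na.rm = TRUE),
    n_sig_group = sum(x$group_tests$p_adj < 0.05, na.rm = TRUE)
  )
}
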