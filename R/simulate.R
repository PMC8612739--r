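# Synthetic-data generator: a two-group crossed-hands session emulator with
# a logistic orienting-direction model (participant random intercepts) and a
# two-channel race architecture for reaction times.

#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults that emulate the
#' study conditions: two groups (sighted `S`, severely visually impaired
#' `SVI`) of 10 infants, the 48-trial crossed-hands schedule, ~5% null
#' responses, and infant-scale reaction times of roughly 1-4 s.
#'
#' The orienting direction of each non-null response is drawn from a
#' logistic model whose linear predictor is `beta` applied to sum-coded
#' group (`S` = +1/2, `SVI` = -1/2), posture (`uncrossed` = +1/2,
#' `crossed` = -1/2), centered age, and per-condition offsets, plus a
#' participant random intercept with standard deviation `sigma_u`.
#' Reaction times come from a race between a per-group auditory and tactile
#' channel, each shifted-lognormal: `t0 + exp(Normal(meanlog, sdlog))`.
#' Congruent bimodal trials take the minimum of the two channels minus
#' `violation_v` seconds (the race-model violation magnitude; 0 gives an
#' independent race that satisfies the race-model bound). On incongruent
#' trials the responded-to side is the tactile one with probability
#' `tactile_pref` (vectorized by group), and the reaction time is the
#' winning channel's draw.
#'
#' @param n_per_group Participants per group.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param age_range_months Integer age range sampled uniformly.
#' @param beta Named numeric vector of fixed effects on the log-odds scale.
#'   Recognised names: `intercept`, `group`, `posture`, `age`,
#'   `group_posture`, `cond_auditory`, `cond_congruent` (tactile-only is
#'   the reference); unnamed effects default to 0.
#' @param sigma_u SD of the participant random intercept (log-odds).
#' @param channel_params Named list `list(S = , SVI = )`, each a list with
#'   `auditory` and `tactile` numeric vectors `c(t0, meanlog, sdlog)`.
#' @param violation_v Seconds subtracted from the winning channel on
#'   congruent bimodal trials; `>= 0`.
#' @param tactile_pref Probability the tactile side wins an incongruent
#'   trial; scalar or named per group. The default gives the sighted group
#'   an auditory preference and the visually impaired group a tactile one.
#' @param p_null Probability of a null (no-orienting) response.
#' @param modality_probs Probabilities of `arm_hand`, `eye_head` and `both`
#'   response modalities given a non-null response.
#' @param rater_disagree Probability the simulated second rater flips the
#'   response side of a non-null trial.
#' @param rater_rt_sd SD (s) of the second rater's reaction-time jitter.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = 10L,
                       seed = 1L,
                       age_range_months = c(5L, 35L),
                       beta = c(intercept = 1.2, group = 0, posture = 0.4,
                                age = 0, group_posture = 0.6,
                                cond_auditory = 0, cond_congruent = 0.6),
                       sigma_u = 0.8,
                       channel_params = default_channel_params(),
                       violation_v = 0.2,
                       tactile_pref = c(S = 0.35, SVI = 0.65),
                       p_null = 0.05,
                       modality_probs = c(arm_hand = 0.72, eye_head = 0.22,
                                          both = 0.06),
                       rater_disagree = 0.03,
                       rater_rt_sd = 0.04) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    age_range_months = as.integer(age_range_months), beta = beta,
    sigma_u = sigma_u, channel_params = channel_params,
    violation_v = violation_v, tactile_pref = tactile_pref,
    p_null = p_null, modality_probs = modality_probs,
    rater_disagree = rater_disagree, rater_rt_sd = rater_rt_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_channel_params <- function() {
  one <- list(auditory = c(t0 = 0.4, meanlog = 0.2, sdlog = 0.5),
              tactile = c(t0 = 0.4, meanlog = 0.35, sdlog = 0.5))
  list(S = one, SVI = one)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 1) abort("`n_per_group` must be at least 1.")
  assert_prob(cfg$p_null, "p_null")
  assert_prob(cfg$tactile_pref, "tactile_pref")
  assert_prob(cfg$rater_disagree, "rater_disagree")
  if (cfg$sigma_u < 0) abort("`sigma_u` must be non-negative.")
  if (cfg$violation_v < 0) abort("`violation_v` must be non-negative.")
  for (g in at_groups) {
    cp <- cfg$channel_params[[g]]
    if (is.null(cp$auditory) || is.null(cp$tactile)) {
      abort(sprintf("`channel_params$%s` must have auditory and tactile entries.", g))
    }
    for (ch in c("auditory", "tactile")) {
      if (cp[[ch]][["sdlog"]] <= 0) abort("channel sdlog must be positive.")
    }
  }
  if (diff(cfg$age_range_months) < 0) abort("`age_range_months` must be increasing.")
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [sim_config()];
#' absent keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$beta <- unlist(vals$beta)
  vals$tactile_pref <- unlist(vals$tactile_pref)
  vals$modality_probs <- unlist(vals$modality_probs)
  if (!is.null(vals$channel_params)) {
    vals$channel_params <- purrr::map(vals$channel_params,
                                      function(g) purrr::map(g, unlist))
  }
  do.call(sim_config, vals)
}

beta_at <- function(beta, name) {
  if (name %in% names(beta)) unname(beta[[name]]) else 0
}

# Draw one RT per row from the shifted-lognormal channel of each row's group.
draw_channel <- function(group, channel, cfg) {
  p <- purrr::map(cfg$channel_params[group], function(g) g[[channel]])
  t0 <- purrr::map_dbl(p, "t0")
  ml <- purrr::map_dbl(p, "meanlog")
  sl <- purrr::map_dbl(p, "sdlog")
  t0 + exp(rnorm(length(group), ml, sl))
}

#' Simulate a full two-group study
#'
#' Generates one session schedule (shared by all participants, as in the
#' original design) and simulates every participant's coded trials from the
#' logistic orienting-direction model and the two-channel race architecture
#' described in [sim_config()]. Reaction times exceeding the 8 s response
#' window become null responses.
#'
#' @param config A [sim_config()] object.
#' @return A trial tibble (schema of [read_trials()], plus a `trial`
#'   column), deterministic given `config$seed`. The configuration and seed
#'   are stored in the `"sim_config"` attribute.
#' @examples
#' trials <- simulate_dataset(sim_config(seed = 1))
#' dplyr::count(trials, group, condition)
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 2)
  sched <- make_schedule(seeds[1])
  out <- with_local_seed(seeds[2], {
    participants <- tibble(
      participant_id = c(sprintf("S%02d", seq_len(config$n_per_group)),
                         sprintf("V%02d", seq_len(config$n_per_group))),
      group = rep(c("S", "SVI"), each = config$n_per_group),
      age_months = sample(seq(config$age_range_months[1],
                              config$age_range_months[2]),
                          2 * config$n_per_group, replace = TRUE),
      u = rnorm(2 * config$n_per_group, 0, config$sigma_u)
    )
    df <- tidyr::crossing(participants, sched) %>%
      arrange(.data$participant_id, .data$trial)
    df <- simulate_responses(df, config)
    select(df, "participant_id", "group", "age_months", "trial", "block",
           "posture", "condition", "tactile_side", "auditory_side",
           "response_modality", "response_side", "rt_s", "valid")
  })
  attr(out, "sim_config") <- config
  validate_trials(out)
  out
}

simulate_responses <- function(df, cfg) {
  n <- nrow(df)
  beta <- cfg$beta
  age_c <- df$age_months - mean(range(cfg$age_range_months))
  g <- ifelse(df$group == "S", 0.5, -0.5)
  p <- ifelse(df$posture == "uncrossed", 0.5, -0.5)
  cond_off <- dplyr::case_when(
    df$condition == "auditory_only" ~ beta_at(beta, "cond_auditory"),
    df$condition == "at_congruent" ~ beta_at(beta, "cond_congruent"),
    TRUE ~ 0
  )
  eta <- beta_at(beta, "intercept") + beta_at(beta, "group") * g +
    beta_at(beta, "posture") * p + beta_at(beta, "age") * age_c +
    beta_at(beta, "group_posture") * g * p + cond_off + df$u
  correct <- rbinom(n, 1, plogis(eta))

  rt_aud <- draw_channel(df$group, "auditory", cfg)
  rt_tac <- draw_channel(df$group, "tactile", cfg)
  pref <- cfg$tactile_pref
  pref_row <- if (length(pref) == 1) rep(unname(pref), n) else
    unname(pref[df$group])
  tac_wins <- rbinom(n, 1, pref_row) == 1

  stim_side <- ifelse(df$condition == "auditory_only",
                      df$auditory_side, df$tactile_side)
  other <- function(s) ifelse(s == "left", "right", "left")
  side <- character(n)
  rt <- numeric(n)
  uni_aud <- df$condition == "auditory_only"
  uni_tac <- df$condition == "tactile_only"
  cong <- df$condition == "at_congruent"
  incg <- df$condition == "at_incongruent"
  rt[uni_aud] <- rt_aud[uni_aud]
  rt[uni_tac] <- rt_tac[uni_tac]
  rt[cong] <- pmax(pmin(rt_aud[cong], rt_tac[cong]) - cfg$violation_v, 0.05)
  rt[incg] <- ifelse(tac_wins[incg], rt_tac[incg], rt_aud[incg])
  side[!incg] <- ifelse(correct[!incg] == 1, stim_side[!incg],
                        other(stim_side[!incg]))
  side[incg] <- ifelse(tac_wins[incg], df$tactile_side[incg],
                       df$auditory_side[incg])

  modality <- sample(names(cfg$modality_probs), n, replace = TRUE,
                     prob = cfg$modality_probs)
  is_null <- rbinom(n, 1, cfg$p_null) == 1 | rt > 8
  df$response_modality <- ifelse(is_null, "null", modality)
  df$response_side <- ifelse(is_null, "null", side)
  df$rt_s <- ifelse(is_null, NA_real_, rt)
  df$valid <- TRUE
  df
}

#' Simulate two raters coding the same trials
#'
#' Rater 1 reproduces the true coded responses; rater 2 flips the response
#' side of non-null trials with probability `rater_disagree` and jitters
#' reaction times with Normal noise of SD `rater_rt_sd`. Both raters'
#' reaction times are quantized to the 1/25 s video frame grid.
#'
#' @param trials A trial tibble, e.g. from [simulate_dataset()].
#' @param config A [sim_config()]; only the rater fields are used.
#' @return A rating tibble: the trial-design columns plus
#'   `response_side_r1`, `response_modality_r1`, `rt_s_r1` and the `_r2`
#'   counterparts.
#' @export
simulate_raters <- function(trials, config = sim_config()) {
  if (nrow(trials) == 0) abort("`trials` must be non-empty.")
  with_local_seed(derive_seeds(config$seed, 3)[3], {
    n <- nrow(trials)
    flip <- rbinom(n, 1, config$rater_disagree) == 1 &
      trials$response_side %in% at_sides
    side2 <- ifelse(flip,
                    ifelse(trials$response_side == "left", "right", "left"),
                    trials$response_side)
    rt1 <- quantize_frames(trials$rt_s)
    rt2 <- quantize_frames(trials$rt_s + rnorm(n, 0, config$rater_rt_sd))
    tibble(
      trials[c("participant_id", "group", "age_months", "block", "posture",
               "condition", "tactile_side", "auditory_side")],
      trial = if ("trial" %in% names(trials)) trials$trial else seq_len(n),
      response_side_r1 = trials$response_side,
      response_modality_r1 = trials$response_modality,
      rt_s_r1 = rt1,
      response_side_r2 = side2,
      response_modality_r2 = trials$response_modality,
      rt_s_r2 = rt2
    )
  })
}
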