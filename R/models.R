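# Random-intercept mixed models for orienting direction (logistic GLMM) and
# reaction time (LMM), with Type III Wald chi-square tables and
# Bonferroni-corrected marginal-mean contrasts.

#' Specify one of the study's mixed-model analyses
#'
#' Builds the model specification for the four analyses: auditory
#' localization (auditory-only trials), tactile localization (tactile-only
#' trials), multisensory gain (tactile-only, auditory-only and
#' audiotactile-congruent trials) and crossmodal conflict (tactile-only,
#' auditory-only and audiotactile-incongruent trials). All models use the
#' fully crossed fixed effects of group, posture, (condition,) and centered
#' age in months, with a participant random intercept and sum-to-zero
#' factor coding (required for Type III tests).
#'
#' For the direction models the binary outcome codes 1 for a response with
#' or toward the stimulated limb; in the crossmodal-conflict analysis the
#' incongruent trials instead code 1 for a response toward the auditory
#' stimulus location. For the reaction-time models only responses to the
#' stimulated limb enter, except in the incongruent condition where the
#' first response counts whichever stimulus it targeted.
#'
#' @param analysis One of `"auditory_localization"`,
#'   `"tactile_localization"`, `"multisensory_gain"`,
#'   `"crossmodal_conflict"`.
#' @param response `"direction"` (binary orienting direction, GLMM) or
#'   `"rt"` (reaction time in seconds, LMM).
#' @param hand_arm_only If `TRUE`, restrict to arm/hand responses (the
#'   tactile sensitivity analysis).
#' @return An object of class `"at_model_spec"`.
#' @export
at_model_spec <- function(analysis = c("auditory_localization",
                                       "tactile_localization",
                                       "multisensory_gain",
                                       "crossmodal_conflict"),
                          response = c("direction", "rt"),
                          hand_arm_only = FALSE) {
  analysis <- match.arg(analysis)
  response <- match.arg(response)
  conditions <- switch(analysis,
    auditory_localization = "auditory_only",
    tactile_localization = "tactile_only",
    multisensory_gain = c("tactile_only", "auditory_only", "at_congruent"),
    crossmodal_conflict = c("tactile_only", "auditory_only", "at_incongruent")
  )
  structure(
    list(analysis = analysis, response = response, conditions = conditions,
         include_condition = length(conditions) > 1,
         hand_arm_only = hand_arm_only),
    class = "at_model_spec"
  )
}

#' @export
print.at_model_spec <- function(x, ...) {
  cat("<at_model_spec>", x$analysis, "|", x$response, "\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble the model frame for a specification
#'
#' Filters trials to the specified conditions and response rules, codes the
#' outcome, centers age at its grand mean, and applies sum-to-zero
#' contrasts to all factors.
#'
#' @param trials A validated trial tibble (null responses are dropped
#'   here; pre-filter with [filter_trials()] to apply a reaction-time
#'   cutoff).
#' @param spec An [at_model_spec()].
#' @return A tibble with columns `y`, `participant_id`, `group`, `posture`,
#'   (`condition`,) `age_c`.
#' @export
prepare_model_data <- function(trials, spec) {
  df <- trials %>%
    add_response_outcome() %>%
    filter(.data$condition %in% spec$conditions,
           .data$response_modality != "null",
           .data$valid)
  if (spec$hand_arm_only) df <- filter(df, .data$response_modality == "arm_hand")
  incong <- df$condition == "at_incongruent"
  if (spec$response == "direction") {
    df$y <- ifelse(incong, df$toward_auditory, df$correct_side)
  } else {
    keep <- ifelse(incong, TRUE, df$correct_side == 1) & !is.na(df$rt_s)
    df <- df[keep, ]
    df$y <- df$rt_s
  }
  df <- df[!is.na(df$y), ]
  if (nrow(df) == 0) abort("No analyzable trials for this specification.")
  df$group <- factor(df$group, at_groups)
  df$posture <- factor(df$posture, at_postures)
  df$age_c <- df$age_months - mean(df$age_months)
  stats::contrasts(df$group) <- stats::contr.sum(2)
  stats::contrasts(df$posture) <- stats::contr.sum(2)
  out <- select(df, "y", "participant_id", "group", "posture",
                dplyr::any_of("condition"), "age_c")
  if (spec$include_condition) {
    out$condition <- factor(out$condition, spec$conditions)
    stats::contrasts(out$condition) <- stats::contr.sum(length(spec$conditions))
  } else {
    out$condition <- NULL
  }
  out
}

fixed_formula_rhs <- function(spec) {
  if (spec$include_condition) "group * posture * condition * age_c"
  else "group * posture * age_c"
}

new_at_fit <- function(fit, spec, data, class2) {
  beta <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  X <- model.matrix(if (inherits(fit, "merMod"))
    lme4::nobars(stats::formula(fit)) else stats::formula(fit), data)
  sigma_u <- if (inherits(fit, "merMod")) {
    vc <- lme4::VarCorr(fit)
    attr(vc$participant_id, "stddev")[[1]]
  } else 0
  structure(
    list(
      fit = fit, spec = spec, data = data,
      beta = beta, vcov = V,
      assign = attr(X, "assign"),
      term_labels = attr(terms(stats::as.formula(
        paste("y ~", fixed_formula_rhs(spec))), data = data), "term.labels"),
      sigma_u = unname(sigma_u),
      sigma_resid = if (class2 == "at_lmm") sigma(fit) else NA_real_,
      loglik = as.numeric(stats::logLik(fit)),
      converged = fit_converged(fit),
      n_obs = nrow(data),
      n_participants = dplyr::n_distinct(data$participant_id)
    ),
    class = c(class2, "at_fit")
  )
}

fit_converged <- function(fit) {
  if (inherits(fit, "merMod")) {
    length(fit@optinfo$conv$lme4) == 0 &&
      (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  } else {
    isTRUE(fit$converged)
  }
}

#' Fit the random-intercept logistic GLMM of orienting direction
#'
#' Maximizes the marginal likelihood of a logistic model with a participant
#' random intercept, integrating the intercept out by adaptive
#' Gauss-Hermite quadrature with `n_quad` nodes (`n_quad = 1` is the
#' Laplace approximation, the default of the underlying `lme4::glmer`).
#' With `random = FALSE` the random intercept is constrained to zero and an
#' ordinary logistic regression is fitted (useful for degenerate-limit
#' checks).
#'
#' @param trials A trial tibble.
#' @param spec An [at_model_spec()] with `response = "direction"`.
#' @param n_quad Number of quadrature nodes (1 = Laplace).
#' @param random Include the participant random intercept?
#' @param control A [lme4::glmerControl()] object; the default computes
#'   exact observed-information derivatives for the coefficient covariance.
#' @return An object of class `"at_glmm"` with elements `beta`, `vcov`
#'   (from the observed information), `sigma_u`, `loglik`, `converged`,
#'   `n_obs`, `n_participants` and the underlying fit.
#' @export
fit_glmm <- function(trials, spec, n_quad = 1L, random = TRUE,
                     control = lme4::glmerControl(calc.derivs = TRUE)) {
  stopifnot(spec$response == "direction")
  df <- prepare_model_data(trials, spec)
  if (random && dplyr::n_distinct(df$participant_id) < 2) {
    abort("Need at least 2 participants to estimate a random intercept.")
  }
  if (all(df$y == df$y[1])) {
    warn(c("Outcome is constant: complete separation.",
           i = "Estimates are unreliable; consider a penalized fit."))
  }
  rhs <- fixed_formula_rhs(spec)
  if (random) {
    fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | participant_id)"))
    fit <- suppressMessages(lme4::glmer(
      fml, data = df, family = stats::binomial(),
      nAGQ = n_quad, control = control
    ))
  } else {
    fml <- stats::as.formula(paste("y ~", rhs))
    fit <- stats::glm(fml, data = df, family = stats::binomial())
  }
  new_at_fit(fit, spec, df, "at_glmm")
}

#' Fit the random-intercept LMM of reaction times
#'
#' Fits a linear mixed model with a participant random intercept by REML
#' (default, matching the underlying `lme4::lmer` default) or ML.
#'
#' @param trials A trial tibble.
#' @param spec An [at_model_spec()] with `response = "rt"`.
#' @param method `"REML"` or `"ML"`.
#' @return An object of class `"at_lmm"` (see [fit_glmm()]), with the
#'   additional element `sigma_resid`.
#' @export
fit_lmm <- function(trials, spec, method = c("REML", "ML")) {
  stopifnot(spec$response == "rt")
  method <- match.arg(method)
  df <- prepare_model_data(trials, spec)
  if (dplyr::n_distinct(df$participant_id) < 2) {
    abort("Need at least 2 participants to estimate a random intercept.")
  }
  per <- dplyr::count(df, .data$participant_id)
  if (max(per$n) == 1) {
    abort(c("Variance components are not identified:",
            "every participant contributes a single observation, so the",
            "random-intercept and residual variances cannot be separated."))
  }
  fml <- stats::as.formula(paste("y ~", fixed_formula_rhs(spec),
                                 "+ (1 | participant_id)"))
  fit <- lme4::lmer(fml, data = df, REML = method == "REML")
  new_at_fit(fit, spec, df, "at_lmm")
}

#' @export
print.at_fit <- function(x, ...) {
  cat(sprintf("<%s> %s | %s\n", class(x)[1], x$spec$analysis, x$spec$response))
  cat(sprintf("  n_obs = %d, n_participants = %d, sigma_u = %.3f%s\n",
              x$n_obs, x$n_participants, x$sigma_u,
              if (!is.na(x$sigma_resid))
                sprintf(", sigma_resid = %.3f", x$sigma_resid) else ""))
  if (!x$converged) cat("  (fit did not converge cleanly)\n")
  invisible(x)
}

#' @method tidy at_fit
#' @export
tidy.at_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$beta / se
  tibble(
    term = names(x$beta), estimate = unname(x$beta), std.error = unname(se),
    statistic = unname(stat), p.value = unname(2 * pnorm(-abs(stat)))
  )
}

#' @method glance at_fit
#' @export
glance.at_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_participants = x$n_participants,
    sigma_u = x$sigma_u, sigma_resid = x$sigma_resid,
    logLik = x$loglik, converged = x$converged
  )
}

#' Type III Wald chi-square table
#'
#' For each model term, tests the term's coefficient block against zero
#' with the Wald statistic `b' V^-1 b` (`b` the block of estimates, `V`
#' their covariance), on as many degrees of freedom as the block has
#' columns. Valid under the sum-to-zero contrast coding that
#' [prepare_model_data()] applies.
#'
#' @param fit An `"at_glmm"` or `"at_lmm"` fit.
#' @return A tibble with columns `term`, `chi2`, `df`, `p`.
#' @export
wald_type3 <- function(fit) {
  stopifnot(inherits(fit, "at_fit"))
  labels <- fit$term_labels
  purrr::map_dfr(seq_along(labels), function(i) {
    idx <- which(fit$assign == i)
    b <- fit$beta[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) {
      abort(sprintf("Covariance block for term `%s` is singular (aliased).",
                    labels[i]))
    }
    chi2 <- drop(t(b) %*% Vi %*% b)
    tibble(term = labels[i], chi2 = chi2, df = length(idx),
           p = pchisq(chi2, length(idx), lower.tail = FALSE))
  })
}

#' Estimated marginal means and Bonferroni-corrected contrasts
#'
#' Computes estimated marginal means on the linear-predictor scale
#' (averaging over the sum-coded levels of the other factors), forms
#' pairwise contrasts of `compare` within each cell of `by`, and applies a
#' Bonferroni correction with an explicit family size: the adjusted p value
#' is `min(1, correction_n * p)`. The study's comparison families were
#' n = 2 for two-way interactions and n = 6 or 12 for three-way ones.
#' Effect sizes are standardized differences using the model sigma and
#' error degrees of freedom.
#'
#' @param fit An `"at_glmm"` or `"at_lmm"` fit.
#' @param compare Factor whose levels are compared pairwise.
#' @param by Optional conditioning factor(s).
#' @param correction_n Bonferroni family size; defaults to the total
#'   number of contrasts produced.
#' @return A tibble with the contrast label, conditioning columns,
#'   `estimate`, `se`, `statistic`, `p_value`, `p_adj` and `effect_size`.
#' @export
emm_contrasts <- function(fit, compare, by = NULL, correction_n = NULL) {
  stopifnot(inherits(fit, "at_fit"))
  vars <- c(compare, by)
  known <- c("group", "posture", "condition", "age_c")
  bad <- setdiff(vars, intersect(known, names(fit$data)))
  if (length(bad)) {
    abort(paste0("Unknown factor(s): ", paste(bad, collapse = ", ")))
  }
  emm <- emmeans::emmeans(fit$fit, specs = vars, data = fit$data,
                          lmer.df = "asymptotic")
  ctr <- emmeans::contrast(emm, method = "pairwise", by = by, adjust = "none")
  tab <- as_tibble(summary(ctr))
  names(tab)[names(tab) == "SE"] <- "se"
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(tab))[1]
  p_col <- intersect(c("p.value"), names(tab))[1]
  correction_n <- correction_n %||% nrow(tab)
  eff <- tryCatch({
    es <- emmeans::eff_size(
      emm, sigma = total_sigma(fit),
      edf = stats::df.residual(fit$fit), method = "pairwise", by = by
    )
    as_tibble(summary(es))$effect.size
  }, error = function(e) rep(NA_real_, nrow(tab)))
  if (length(eff) != nrow(tab)) eff <- rep(NA_real_, nrow(tab))
  tab %>%
    mutate(
      statistic = .data[[stat_col]],
      p_value = .data[[p_col]],
      p_adj = pmin(1, correction_n * .data[[p_col]]),
      effect_size = eff
    ) %>%
    select(dplyr::any_of(c("contrast", by)), "estimate", "se", "statistic",
           "p_value", "p_adj", "effect_size")
}

# Total model SD used to standardize contrasts: residual and random-intercept
# variation for the LMM; random intercept plus the standard logistic residual
# variance (pi^2/3) on the log-odds scale for the GLMM.
total_sigma <- function(fit) {
  if (inherits(fit, "at_lmm")) sqrt(fit$sigma_resid^2 + fit$sigma_u^2)
  else sqrt(fit$sigma_u^2 + pi^2 / 3)
}
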