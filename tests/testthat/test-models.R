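# Mixed models: degenerate-limit oracles, Type III Wald tests, marginal-mean
# contrasts.

# counts 8/10 vs 2/10 replicated in each posture x age cell so the saturated
# logit is exact: the group log-odds ratio is log(16).
closed_form_trials <- function() {
  cells <- tidyr::crossing(
    group = c("S", "SVI"),
    posture = c("uncrossed", "crossed"),
    age_months = c(12L, 24L)
  )
  cells$n <- 5L
  cells$n_correct <- ifelse(cells$group == "S", 4L, 1L)
  trials_from_counts(cells)
}

test_that("with the random intercept constrained to zero, the fit reproduces the closed-form 2x2 logit", {
  fit <- fit_glmm(closed_form_trials(), at_model_spec("auditory_localization"),
                  random = FALSE)
  # sum-to-zero coding over levels (SVI, S): the S - SVI log-odds ratio is
  # minus twice the first-level coefficient
  lor <- -2 * fit$beta[["group1"]]
  expect_equal(lor, log(16), tolerance = 1e-8)
  expect_equal(log(16), 2.772589, tolerance = 1e-6)
})

test_that("GLMM at sigma_u = 0 matches an independent Newton-Raphson logistic oracle", {
  cfg <- sim_config(n_per_group = 15L, seed = 31, sigma_u = 0,
                    beta = c(intercept = 0.8, group = 0.5, posture = 0.4,
                             group_posture = 0.6),
                    p_null = 0)
  trials <- simulate_dataset(cfg)
  spec <- at_model_spec("tactile_localization")
  fit <- fit_glmm(trials, spec, random = TRUE)
  expect_lt(fit$sigma_u, 0.05)

  df <- prepare_model_data(trials, spec)
  X <- model.matrix(~ group * posture * age_c, df)
  y <- df$y
  b <- rep(0, ncol(X))
  for (i in 1:50) { # Newton-Raphson on the logistic log-likelihood
    mu <- plogis(drop(X %*% b))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  expect_equal(unname(fit$beta), unname(b), tolerance = 1e-3)
})

test_that("a constant outcome triggers the separation warning path", {
  trials <- closed_form_trials()
  trials$response_side <- "left" # every response toward the stimulated hand
  expect_warning(
    fit_glmm(trials, at_model_spec("auditory_localization"), random = FALSE),
    "separation"
  )
})

test_that("LMM collapses to OLS when participants are exchangeable", {
  cfg <- sim_config(n_per_group = 10L, seed = 41, sigma_u = 0, p_null = 0)
  trials <- simulate_dataset(cfg)
  spec <- at_model_spec("auditory_localization", "rt")
  fit <- fit_lmm(trials, spec)
  df <- prepare_model_data(trials, spec)
  ols <- stats::lm(y ~ group * posture * age_c, df)
  if (fit$sigma_u < 1e-6) {
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  } else {
    # boundary not reached exactly; estimates still agree closely
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-2)
  }
})

test_that("balanced one-way variance components match the ANOVA method-of-moments oracle", {
  # balanced between (group) x within (posture) design with constant age, so
  # the covariance structure is the classic one-way-within-participants layout
  set.seed(17)
  n_part <- 6L
  n_per <- 5L # trials per posture cell
  trials <- purrr::map_dfr(1:(2 * n_part), function(i) {
    g <- if (i <= n_part) "S" else "SVI"
    u <- rnorm(1, 0, 0.5)
    tidyr::crossing(posture = c("uncrossed", "crossed"), rep = 1:n_per) |>
      dplyr::mutate(
        participant_id = sprintf("P%02d", i), group = g, age_months = 12L,
        block = ifelse(posture == "uncrossed", 1L, 4L),
        condition = "auditory_only", tactile_side = "none",
        auditory_side = "left", response_modality = "arm_hand",
        response_side = "left",
        rt_s = pmin(pmax(2 + u + rnorm(dplyr::n(), 0, 0.3), 0.1), 8),
        valid = TRUE
      ) |>
      dplyr::select(-rep)
  })
  spec <- at_model_spec("auditory_localization", "rt")
  fit <- suppressMessages(suppressWarnings(fit_lmm(trials, spec)))
  # oracle: expected mean squares from the balanced ANOVA decomposition
  av <- summary(stats::aov(rt_s ~ group * posture +
                             Error(participant_id), data = trials))
  ms_between <- av[["Error: participant_id"]][[1]]["Residuals", "Mean Sq"]
  ms_within <- av[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  k <- 2 * n_per # observations per participant
  expect_equal(fit$sigma_resid^2, ms_within, tolerance = 1e-5)
  expect_equal(fit$sigma_u^2, (ms_between - ms_within) / k, tolerance = 1e-5)
})

test_that("LMM recovers known parameters within three standard errors", {
  cfg <- sim_config(n_per_group = 15L, seed = 55, p_null = 0)
  trials <- simulate_dataset(cfg)
  spec <- at_model_spec("auditory_localization", "rt")
  fit <- fit_lmm(trials, spec)
  # auditory channel: t0 + exp(N(meanlog, sdlog)) has a known mean
  p <- cfg$channel_params$S$auditory
  mu_true <- p[["t0"]] + exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta[["(Intercept)"]] - mu_true),
            3 * se[["(Intercept)"]] + 0.05)
  # group and posture have no true RT effect in this configuration
  expect_lt(abs(fit$beta[["group1"]]), 4 * se[["group1"]])
})

test_that("one observation per participant is flagged as non-identified", {
  trials <- closed_form_trials() # unique participant per row
  expect_error(fit_lmm(trials, at_model_spec("auditory_localization", "rt")),
               "not identified")
})

test_that("single-df Wald chi-square equals the squared z ratio", {
  fit <- fit_glmm(closed_form_trials(), at_model_spec("auditory_localization"),
                  random = FALSE)
  w <- wald_type3(fit)
  one_df <- w[w$df == 1, ]
  expect_gt(nrow(one_df), 0)
  # every 1-df chi2 equals (estimate/SE)^2 for the matching coefficient
  for (i in seq_len(nrow(one_df))) {
    lbl <- one_df$term[i]
    j <- which(fit$assign == match(lbl, fit$term_labels))
    expect_length(j, 1)
    expect_equal(one_df$chi2[i],
                 (fit$beta[[j]] / sqrt(fit$vcov[j, j]))^2,
                 tolerance = 1e-10)
  }
})

test_that("Type III Wald table matches car::Anova on a mixed fit", {
  skip_if_not_installed("car")
  cfg <- sim_config(n_per_group = 8L, seed = 61)
  trials <- simulate_dataset(cfg)
  fit <- fit_glmm(trials, at_model_spec("tactile_localization"))
  ours <- wald_type3(fit)
  ref <- car::Anova(fit$fit, type = 3)
  ref <- ref[rownames(ref) != "(Intercept)", ]
  expect_equal(ours$chi2, unname(ref$Chisq), tolerance = 1e-6)
  expect_equal(ours$df, unname(ref$Df))
  expect_equal(ours$p, unname(ref$`Pr(>Chisq)`), tolerance = 1e-6)
})

test_that("Wald p values are uniform under the null", {
  set.seed(71)
  pvals <- replicate(500, {
    cells <- tidyr::crossing(group = c("S", "SVI"),
                             posture = c("uncrossed", "crossed"),
                             age_months = c(10L, 20L))
    cells$n <- 25L
    cells$n_correct <- rbinom(nrow(cells), 25, 0.5)
    trials <- trials_from_counts(cells)
    fit <- fit_glmm(trials, at_model_spec("auditory_localization"),
                    random = FALSE)
    w <- wald_type3(fit)
    w$p[w$term == "group"]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("quadrature refinement changes estimates by shrinking increments", {
  cfg <- sim_config(n_per_group = 8L, seed = 81)
  trials <- simulate_dataset(cfg)
  spec <- at_model_spec("tactile_localization")
  b1 <- fit_glmm(trials, spec, n_quad = 1)$beta
  b5 <- fit_glmm(trials, spec, n_quad = 5)$beta
  b21 <- fit_glmm(trials, spec, n_quad = 21)$beta
  step1 <- sqrt(sum((b5 - b1)^2))
  step2 <- sqrt(sum((b21 - b5)^2))
  expect_lte(step2, step1 + 1e-8)
})

test_that("marginal-mean contrasts reduce to coefficient differences and honor Bonferroni", {
  fit <- fit_glmm(closed_form_trials(), at_model_spec("auditory_localization"),
                  random = FALSE)
  ctr <- emm_contrasts(fit, compare = "group", correction_n = 2)
  # sum coding over (SVI, S): the SVI - S marginal contrast is twice the
  # first-level coefficient
  expect_equal(ctr$estimate, 2 * fit$beta[["group1"]], tolerance = 1e-8)
  expect_equal(ctr$p_adj, pmin(1, 2 * ctr$p_value))
  expect_error(emm_contrasts(fit, compare = "flavour"), "Unknown factor")
})

test_that("marginal means equal a direct cell-averaging oracle on balanced data", {
  cells <- tidyr::crossing(group = c("S", "SVI"),
                           posture = c("uncrossed", "crossed"),
                           age_months = c(10L, 30L))
  cells$n <- 10L
  cells$n_correct <- c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 3L)
  trials <- trials_from_counts(cells)
  fit <- fit_glmm(trials, at_model_spec("auditory_localization"),
                  random = FALSE)
  ctr <- emm_contrasts(fit, compare = "posture", by = "group",
                       correction_n = 2)
  # oracle: cell means of the linear predictor at centered age 0
  df <- prepare_model_data(trials, at_model_spec("auditory_localization"))
  grid <- tidyr::crossing(group = factor(c("S", "SVI"), levels(df$group)),
                          posture = factor(c("uncrossed", "crossed"),
                                           levels(df$posture)),
                          age_c = 0)
  stats::contrasts(grid$group) <- stats::contr.sum(2)
  stats::contrasts(grid$posture) <- stats::contr.sum(2)
  eta <- drop(model.matrix(~ group * posture * age_c, grid) %*% fit$beta)
  for (g in c("S", "SVI")) {
    oracle <- eta[grid$group == g & grid$posture == "uncrossed"] -
      eta[grid$group == g & grid$posture == "crossed"]
    expect_equal(ctr$estimate[ctr$group == g], unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("the GLMM log-likelihood at the optimum dominates the truth", {
  cfg <- sim_config(n_per_group = 10L, seed = 91, sigma_u = 0.8,
                    beta = c(intercept = 1.0, group = 0.4, posture = 0.4,
                             group_posture = 0.6),
                    p_null = 0)
  trials <- simulate_dataset(cfg)
  spec <- at_model_spec("tactile_localization")
  fit <- fit_glmm(trials, spec)
  df <- prepare_model_data(trials, spec)
  dfun <- lme4::glmer(y ~ group * posture * age_c + (1 | participant_id),
                      data = df, family = stats::binomial(),
                      devFunOnly = TRUE)
  # model-scale truth: sum coding halves the +-1/2-coded generator effects
  beta_true <- c(1.0, 0.4 / 2, 0.4 / 2, 0, 0.6 / 4, 0, 0, 0)
  dev_true <- dfun(c(cfg$sigma_u, beta_true))
  expect_gte(dev_true, -2 * fit$loglik - 1e-6)
})

test_that("tidy and glance expose coefficients and fit metadata", {
  fit <- fit_glmm(small_sim(), at_model_spec("tactile_localization"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 10L)
  expect_gte(gl$sigma_u, 0)
})
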