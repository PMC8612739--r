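test_that("type-1 quantiles invert the step CDF", {
  expect_equal(rt_quantile(2, probs = c(0.1, 0.5, 0.9)), c(2, 2, 2))
  expect_equal(rt_quantile(1:5, probs = 0.5), 3)
  # 20 uniform draws, all nine deciles, against the exhaustive scan oracle
  set.seed(8)
  x <- runif(20, 0.5, 4)
  got <- rt_quantile(x)
  oracle <- vapply(seq(0.1, 0.9, 0.1), function(q) scan_quantile(x, q),
                   numeric(1))
  expect_equal(got, oracle)
})

test_that("race-bound quantiles match hand evaluation of the summed step CDFs", {
  # G(2) = F_A(2) + F_T(2) = 0.5 + 0 = 0.5, so the median bound is 2
  expect_equal(race_bound_quantiles(c(2, 4), c(3, 5), probs = 0.5), 2)
  # when one channel never fires early, low deciles equal a doubled-mass F_A
  rt_a <- c(1, 1.5, 2, 2.5)
  rt_t <- c(3, 3.5, 4, 4.5) # all >= max(rt_a)
  got <- race_bound_quantiles(rt_a, rt_t, probs = c(0.1, 0.25, 0.5))
  pooled <- sort(c(rt_a, rt_t))
  oracle <- vapply(c(0.1, 0.25, 0.5), function(q) {
    g <- vapply(pooled, function(t) min(1, mean(rt_a <= t) + mean(rt_t <= t)),
                numeric(1))
    pooled[which(g >= q - 1e-12)[1]]
  }, numeric(1))
  expect_equal(got, oracle)
  # identical lists: G = 2F, so bound quantile at q is the type-1 quantile at q/2
  x <- c(0.8, 1.1, 1.7, 2.2, 3.0, 3.3)
  for (q in c(0.2, 0.5, 0.8)) {
    expect_equal(race_bound_quantiles(x, x, probs = q), scan_quantile(x, q / 2))
  }
})

test_that("the bound dominates both unisensory quantile profiles", {
  set.seed(15)
  for (rep in 1:20) {
    a <- 0.4 + rexp(sample(5:30, 1), 0.8)
    b <- 0.4 + rexp(sample(5:30, 1), 0.6)
    qa <- rt_quantile(a)
    qb <- rt_quantile(b)
    qg <- race_bound_quantiles(a, b)
    expect_true(all(qg <= pmin(qa, qb) + 1e-12))
    expect_true(!is.unsorted(qg)) # monotone in the decile
  }
})

test_that("empty cells signal and are logged instead of fabricated", {
  expect_error(rt_quantile(numeric(0)), "missing cell")
  expect_error(race_bound_quantiles(numeric(0), 1:3), "non-empty")
  trials <- small_sim()
  # remove one participant's congruent trials in one posture
  drop <- trials$participant_id == "S01" & trials$posture == "crossed" &
    trials$condition == "at_congruent"
  profs <- participant_quantiles(trials[!drop, ])
  miss <- attr(profs, "missing_cells")
  expect_true(any(miss$participant_id == "S01" & miss$posture == "crossed" &
                    miss$condition == "AT"))
  rg <- redundancy_gain(trials[!drop, ])
  expect_true(any(rg$dropped$participant_id == "S01" &
                    rg$dropped$posture == "crossed") ||
                !"S01" %in% rg$gains$participant_id[
                  rg$gains$posture == "crossed"])
})

test_that("profiles are computed within participant before aggregation", {
  trials <- small_sim()
  profs <- participant_quantiles(trials)
  rg <- redundancy_gain(profs)
  # transposed aggregation: mean over participants of per-participant deciles
  manual <- profs |>
    dplyr::filter(condition %in% c("AT", "race_bound")) |>
    tidyr::pivot_wider(names_from = condition, values_from = rt) |>
    dplyr::filter(!is.na(AT), !is.na(race_bound))
  manual <- manual |>
    dplyr::semi_join(
      dplyr::filter(dplyr::count(manual, participant_id, posture), n == 9),
      by = c("participant_id", "posture")
    ) |>
    dplyr::group_by(group, posture, prob) |>
    dplyr::summarise(m = mean(race_bound - AT), .groups = "drop")
  joined <- dplyr::left_join(rg$tests, manual, by = c("group", "posture", "prob"))
  expect_equal(joined$mean_gain_s, joined$m)
})

test_that("zero gains produce no rejections", {
  # audiotactile quantiles exactly at the bound for every participant
  probs <- seq(0.1, 0.9, 0.1)
  profs <- tidyr::crossing(
    participant_id = sprintf("P%02d", 1:8),
    posture = c("uncrossed", "crossed"),
    condition = c("AT", "race_bound"),
    prob = probs
  ) |>
    dplyr::mutate(group = ifelse(participant_id <= "P04", "S", "SVI"),
                  rt = 1 + prob) # identical for AT and the bound
  rg <- redundancy_gain(profs)
  expect_true(all(rg$gains$gain == 0))
  expect_true(all(is.na(rg$tests$t) | !is.finite(rg$tests$t) |
                    rg$tests$p_adj == 1))
})

test_that("Welch group comparisons have fractional df bounded by n1 + n2 - 2", {
  trials <- simulate_dataset(sim_config(seed = 23))
  rg <- redundancy_gain(trials)
  gt <- rg$group_tests[!is.na(rg$group_tests$df), ]
  expect_gt(nrow(gt), 0)
  ns <- rg$tests |>
    dplyr::group_by(posture, prob) |>
    dplyr::summarise(n_tot = sum(n), .groups = "drop")
  joined <- dplyr::left_join(gt, ns, by = c("posture", "prob"))
  expect_true(all(joined$df <= joined$n_tot - 2 + 1e-9))
  expect_true(any(abs(joined$df - round(joined$df)) > 1e-6)) # genuinely fractional
})

test_that("a strong violation produces significant central-decile gains", {
  trials <- simulate_dataset(sim_config(seed = 29, violation_v = 0.5))
  rg <- redundancy_gain(trials)
  central <- rg$tests[rg$tests$prob == 0.5, ]
  expect_true(all(central$mean_gain_s > 0))
  # with 6 trials per condition cell the per-cell test is not always
  # significant after Bonferroni; most cells are
  expect_gte(sum(central$p_adj < 0.05), 3)
})

test_that("gain tables and plots are exposed tidily", {
  rg <- redundancy_gain(simulate_dataset(sim_config(seed = 3)))
  expect_s3_class(tidy(rg), "tbl_df")
  expect_true(all(c("mean_gain_s", "se", "t", "df", "p_adj") %in%
                    names(tidy(rg))))
  gl <- glance(rg)
  expect_true(gl$n_cells > 0)
  p <- ggplot2::autoplot(rg)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_rt_cdf(participant_quantiles(
    simulate_dataset(sim_config(seed = 3)))), "ggplot")
})

test_that("the interpolated quantile flag matches the conventional estimator", {
  expect_equal(rt_quantile(1:5, probs = 0.5, type = "interpolated"), 3)
  expect_equal(rt_quantile(c(1, 2), probs = 0.5, type = "interpolated"), 1.5)
  # the default step estimator is unchanged by the flag's existence
  expect_equal(rt_quantile(c(1, 2), probs = 0.5), 1)
})
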