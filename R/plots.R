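# Figure-style visualisations: mean reaction-time CDFs and decile gains.

#' Mean reaction-time CDF curves
#'
#' Plots, per posture and group, the across-participant mean reaction time
#' at each decile for the auditory-only, tactile-only and
#' audiotactile-congruent conditions and the race-model bound — the curve
#' view of the redundancy-gain analysis.
#'
#' @param profiles A profile tibble from [participant_quantiles()] (a trial
#'   tibble is also accepted).
#' @return A ggplot object.
#' @export
plot_rt_cdf <- function(profiles) {
  if (!"prob" %in% names(profiles)) profiles <- participant_quantiles(profiles)
  mean_cdf <- profiles %>%
    group_by(.data$group, .data$posture, .data$condition, .data$prob) %>%
    summarise(rt = mean(.data$rt), .groups = "drop")
  ggplot2::ggplot(mean_cdf,
                  ggplot2::aes(x = .data$rt, y = .data$prob,
                               colour = .data$condition,
                               linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~posture) +
    ggplot2::labs(x = "reaction time (s)", y = "cumulative probability",
                  colour = "condition", linetype = "group") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.race_gain
#' @export
plot_race_gain <- function(object, ...) autoplot.race_gain(object, ...)

#' Plot redundancy gains by decile
#'
#' Bar plot of the mean multisensory gain (race-bound quantile minus
#' audiotactile quantile, seconds) per decile, group and posture, with
#' standard-error bars; asterisks mark deciles whose one-tailed
#' Bonferroni-adjusted gain test is significant at 0.05.
#'
#' @param object A `"race_gain"` object from [redundancy_gain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot race_gain
#' @export
autoplot.race_gain <- function(object, ...) {
  tests <- mutate(object$tests, sig = !is.na(.data$p_adj) & .data$p_adj < 0.05)
  ggplot2::ggplot(tests,
                  ggplot2::aes(x = factor(.data$prob), y = .data$mean_gain_s,
                               fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_gain_s - .data$se,
                   ymax = .data$mean_gain_s + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3) +
    ggplot2::geom_text(
      data = filter(tests, .data$sig),
      ggplot2::aes(label = "*",
                   y = .data$mean_gain_s + .data$se + 0.02),
      position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~posture) +
    ggplot2::labs(x = "decile of the reaction-time CDF",
                  y = "multisensory gain (s)", fill = "group") +
    ggplot2::theme_minimal()
}
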