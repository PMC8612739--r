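# Inter-observer reliability: Cohen's kappa, weighted kappa and
# reaction-time agreement between the two raters.

#' Cross-tabulate two raters' nominal codes
#'
#' @param r1,r2 Equal-length vectors of category labels.
#' @param levels Optional common label set (order matters for weighted
#'   kappa); defaults to the union of observed labels.
#' @return A square contingency matrix of rater-1 by rater-2 counts.
#' @export
agreement_table <- function(r1, r2, levels = NULL) {
  if (length(r1) != length(r2)) abort("`r1` and `r2` must be paired.")
  levels <- levels %||% sort(union(unique(r1), unique(r2)))
  unclass(table(factor(r1, levels), factor(r2, levels)))
}

# Agreement-weight formulation shared by unweighted and weighted kappa.
# w is a k x k agreement-weight matrix (1 on the diagonal); kappa is
# (po_w - pe_w) / (1 - pe_w) and the CI uses the large-sample
# (Fleiss-Cohen) asymptotic variance.
kappa_from_weights <- function(tab, w, conf_level, weighted, scheme) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) abort("Agreement table must be square.")
  n <- sum(tab)
  if (n < 2) abort("Agreement table must hold at least 2 ratings.")
  p <- tab / n
  pi. <- rowSums(p)
  p.j <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi., p.j))
  if (abs(1 - pe) < 1e-12) {
    abort("Kappa is undefined: chance agreement is 1 (degenerate marginals).")
  }
  kappa <- (po - pe) / (1 - pe)
  wbar_i <- as.vector(w %*% p.j)   # row-wise expected weight
  wbar_j <- as.vector(pi. %*% w)   # column-wise expected weight
  dev <- w * (1 - pe) - outer(wbar_i, wbar_j, "+") * (1 - po)
  v <- (sum(p * dev^2) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(
    kappa = kappa, se = se,
    ci_low = max(-1, min(kappa, kappa - z * se)),
    ci_high = min(1, max(kappa, kappa + z * se)),
    weighted = weighted, weight_scheme = scheme, n = n
  )
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two raters
#' of nominal codes, with a 95% (by default) confidence interval from the
#' large-sample asymptotic standard error, truncated to `[-1, 1]`.
#'
#' @param table A square contingency matrix (see [agreement_table()]).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `kappa`, `se`, `ci_low`, `ci_high`,
#'   `weighted`, `weight_scheme`, `n`.
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))
#' @export
cohen_kappa <- function(table, conf_level = 0.95) {
  k <- nrow(as.matrix(table))
  kappa_from_weights(table, diag(k), conf_level,
                     weighted = FALSE, scheme = "none")
}

#' Weighted kappa for ordered categories
#'
#' Weighted agreement with disagreement penalties proportional to the
#' category distance: `|i - j| / (k - 1)` (linear) or its square
#' (quadratic). With two categories both schemes reduce to the unweighted
#' kappa.
#'
#' @inheritParams cohen_kappa
#' @param scheme `"linear"` or `"quadratic"` distance weights.
#' @return A one-row tibble as for [cohen_kappa()].
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic"),
                           conf_level = 0.95) {
  scheme <- match.arg(scheme)
  k <- nrow(as.matrix(table))
  if (k < 2) abort("Weighted kappa needs at least 2 ordered categories.")
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (scheme == "linear") 1 - d else 1 - d^2
  kappa_from_weights(table, w, conf_level, weighted = TRUE, scheme = scheme)
}

#' Agreement between two raters' reaction times
#'
#' Pearson correlation (Fisher-z confidence interval) and mean signed
#' difference `rt1 - rt2` (normal-approximation confidence interval)
#' between paired reaction-time ratings. Pairs where either rating is
#' absent are dropped.
#'
#' @param rt1,rt2 Paired reaction times in seconds.
#' @param conf_level Confidence level.
#' @return A one-row tibble: `n`, `pearson_r`, `r_ci_low`, `r_ci_high`,
#'   `mean_signed_diff_s`, `diff_ci_low`, `diff_ci_high`.
#' @export
rt_agreement <- function(rt1, rt2, conf_level = 0.95) {
  if (length(rt1) != length(rt2)) abort("`rt1` and `rt2` must be paired.")
  ok <- !is.na(rt1) & !is.na(rt2)
  rt1 <- rt1[ok]
  rt2 <- rt2[ok]
  n <- length(rt1)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(rt1) == 0 || sd(rt2) == 0) {
    abort("Correlation undefined: a rater's reaction times have zero variance.")
  }
  r <- cor(rt1, rt2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  fz <- atanh(r) + c(-1, 1) * z / sqrt(n - 3)
  d <- rt1 - rt2
  dci <- mean(d) + c(-1, 1) * z * sd(d) / sqrt(n)
  tibble(
    n = n, pearson_r = r,
    r_ci_low = tanh(fz[1]), r_ci_high = tanh(fz[2]),
    mean_signed_diff_s = mean(d),
    diff_ci_low = dci[1], diff_ci_high = dci[2]
  )
}

#' Read a square agreement table from delimited text
#'
#' Reads a comma-delimited square count table whose first column holds the
#' category labels and whose remaining columns (named by the same labels)
#' hold rater-1 by rater-2 counts.
#'
#' @param path CSV file path.
#' @return A square contingency matrix suitable for [cohen_kappa()].
#' @export
read_agreement_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1])
  if (nrow(m) != ncol(m) || !identical(colnames(m), labels)) {
    abort("Agreement table file must be square with matching row/column labels.")
  }
  rownames(m) <- labels
  storage.mode(m) <- "double"
  m
}

#' Write reliability results as JSON
#'
#' @param reliability A list as returned by [rating_reliability()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reliability_json <- function(reliability, path) {
  jsonlite::write_json(
    list(kappa = reliability$kappa, rt = reliability$rt),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' Reliability summary for a dual-rating table
#'
#' Convenience wrapper computing, from a rating table, the unweighted and
#' weighted kappas for response side (left/right/null) and response
#' modality (arm-hand/eye-head/both/null), plus reaction-time agreement on
#' trials both raters coded as responses.
#'
#' @param pairs A rating tibble (see [simulate_raters()]).
#' @return A tibble with one row per statistic.
#' @export
rating_reliability <- function(pairs) {
  side_lv <- c("left", "right", "null")
  mod_lv <- c(at_modalities, "null")
  side_tab <- agreement_table(pairs$response_side_r1,
                              pairs$response_side_r2, side_lv)
  mod_tab <- agreement_table(pairs$response_modality_r1,
                             pairs$response_modality_r2, mod_lv)
  kappas <- bind_rows(
    mutate(cohen_kappa(side_tab), variable = "response_side"),
    mutate(weighted_kappa(side_tab), variable = "response_side"),
    mutate(cohen_kappa(mod_tab), variable = "response_modality"),
    mutate(weighted_kappa(mod_tab), variable = "response_modality")
  )
  rt <- rt_agreement(pairs$rt_s_r1, pairs$rt_s_r2)
  list(kappa = select(kappas, "variable", dplyr::everything()),
       rt = rt)
}
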