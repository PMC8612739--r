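# Dual-rater reconciliation: trials where the raters agree (or reached post
# hoc agreement) keep a reconciled record; residual disagreements on side or
# modality are designated null trials and drop out of analysis.

rating_suffix_cols <- function(suffix) {
  paste0(c("response_side", "response_modality", "rt_s"), suffix)
}

#' Reconcile the codes of two raters
#'
#' Aligns the two raters' codes trial by trial. Trials on which the raters
#' agree on both response side and response modality are kept with a
#' reconciled record whose reaction time is the mean of the two raters'
#' reaction times, quantized to the 1/25 s video frame grid. Trials with a
#' residual disagreement on side or modality are designated null and
#' thereby excluded from downstream analysis. Reconciliation never invents
#' a response: a trial that either rater coded null stays null.
#'
#' @param pairs A rating tibble as from [simulate_raters()] (trial-design
#'   columns plus `_r1`/`_r2` coding columns).
#' @return A trial tibble with reconciled `response_side`,
#'   `response_modality` and `rt_s`, plus an `agreement` logical column.
#'   The `"reconciliation"` attribute holds a one-row summary tibble with
#'   `n_trials`, `n_agreed`, `n_disagreed` and `n_null`.
#' @export
reconcile_ratings <- function(pairs) {
  need <- c(rating_suffix_cols("_r1"), rating_suffix_cols("_r2"))
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    abort(paste0("Rating table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(pairs$response_side_r1) || anyNA(pairs$response_side_r2)) {
    abort("Both raters must have coded every trial (mismatched trial sets).")
  }
  agree <- pairs$response_side_r1 == pairs$response_side_r2 &
    pairs$response_modality_r1 == pairs$response_modality_r2
  is_null <- agree & pairs$response_side_r1 == "null"
  keep_resp <- agree & !is_null
  out <- pairs %>%
    mutate(
      agreement = agree,
      response_side = ifelse(keep_resp, .data$response_side_r1, "null"),
      response_modality = ifelse(keep_resp, .data$response_modality_r1, "null"),
      rt_s = ifelse(keep_resp,
                    quantize_frames((.data$rt_s_r1 + .data$rt_s_r2) / 2),
                    NA_real_),
      valid = TRUE
    ) %>%
    select(-dplyr::all_of(need))
  attr(out, "reconciliation") <- tibble(
    n_trials = nrow(pairs),
    n_agreed = sum(keep_resp),
    n_disagreed = sum(!agree),
    n_null = sum(is_null)
  )
  out
}

#' Read / write rating tables
#'
#' Rating tables use the trial schema with `_r1`/`_r2` suffixes on the
#' response columns; absent reaction times are empty fields.
#'
#' @param path File path.
#' @return `read_ratings()` returns the rating tibble; `write_ratings()`
#'   returns `path` invisibly.
#' @export
read_ratings <- function(path) {
  pairs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(rating_suffix_cols("_r1"), rating_suffix_cols("_r2"))
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    abort(paste0("Rating file is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  pairs
}

#' @rdname read_ratings
#' @param pairs A rating tibble.
#' @export
write_ratings <- function(pairs, path) {
  readr::write_csv(pairs, path, na = "")
  invisible(path)
}
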