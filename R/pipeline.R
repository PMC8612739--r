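# End-to-end orchestration: load or simulate -> reconcile -> filter ->
# mixed models -> race model -> reliability -> report.

at_analyses <- c("auditory_localization", "tactile_localization",
                 "multisensory_gain", "crossmodal_conflict",
                 "race_model", "reliability")

#' Configuration for a full pipeline run
#'
#' @param input A trial tibble, a path to a trial CSV (schema of
#'   [read_trials()]), or `NULL` to simulate a dataset from `sim`.
#' @param sim A [sim_config()] used when `input` is `NULL`; its seed is
#'   overridden by `seed`.
#' @param ratings Optional rating tibble or CSV path for the reliability
#'   stage; simulated automatically when `input` is `NULL`.
#' @param analyses Subset of the six analyses to run.
#' @param rt_cutoff_s Reaction-time cutoff in seconds (`NULL` = none; the
#'   sensitivity mode uses 4).
#' @param hand_arm_only Restrict the tactile-localization models to
#'   arm/hand responses.
#' @param n_quad Quadrature nodes for the logistic mixed models.
#' @param seed Master seed for simulation.
#' @return A list with class `"analysis_config"`.
#' @export
analysis_config <- function(input = NULL, sim = sim_config(),
                            ratings = NULL, analyses = at_analyses,
                            rt_cutoff_s = NULL, hand_arm_only = FALSE,
                            n_quad = 1L, seed = 1L) {
  analyses <- match.arg(analyses, at_analyses, several.ok = TRUE)
  if (length(analyses) == 0) abort("Select at least one analysis.")
  structure(
    list(input = input, sim = sim, ratings = ratings, analyses = analyses,
         rt_cutoff_s = rt_cutoff_s, hand_arm_only = hand_arm_only,
         n_quad = as.integer(n_quad), seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; a `sim` key holds
#' [sim_config()] fields. `input` and `ratings` may be file paths.
#'
#' @param path YAML file path.
#' @return An `"analysis_config"`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sim)) {
    vals$sim$beta <- unlist(vals$sim$beta)
    vals$sim$tactile_pref <- unlist(vals$sim$tactile_pref)
    vals$sim$modality_probs <- unlist(vals$sim$modality_probs)
    vals$sim <- do.call(sim_config, vals$sim)
  }
  do.call(analysis_config, vals)
}

model_analyses <- c("auditory_localization", "tactile_localization",
                    "multisensory_gain", "crossmodal_conflict")

# Comparison families mirroring the published post hoc structure: for the
# two-way group x posture interaction, pairwise contrasts of each factor
# within the other (n = 2 each); with condition in the model, contrasts
# within the cells of the other two factors (n = 6) and condition contrasts
# within group x posture cells (n = 12).
contrast_families <- function(spec) {
  if (spec$include_condition) {
    list(
      list(compare = "posture", by = c("group", "condition"), n = 6L),
      list(compare = "group", by = c("condition", "posture"), n = 6L),
      list(compare = "condition", by = c("posture", "group"), n = 12L)
    )
  } else {
    list(
      list(compare = "posture", by = "group", n = 2L),
      list(compare = "group", by = "posture", n = 2L)
    )
  }
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order: input acquisition
#' (load or simulate), rater reconciliation, trial accounting, filtering,
#' the four mixed-model analyses (each a logistic GLMM of orienting
#' direction and an LMM of reaction time, with Type III Wald tables and
#' Bonferroni-corrected marginal-mean contrasts), the race-model
#' redundancy-gain analysis, and inter-observer reliability. Stages that
#' cannot run on the available data (e.g. empty cells) are recorded as
#' skipped entries rather than failures. The run is deterministic given
#' the configuration and seed.
#'
#' @param config An [analysis_config()].
#' @param quiet Suppress stage-level progress messages.
#' @return An object of class `"at_report"`: a list with elements
#'   `trials`, `accounting`, `reliability`, `models` (per analysis: Wald
#'   tables and contrasts), `race`, `skipped` and `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(analysis_config(seed = 42), quiet = TRUE)
#' rep$models$tactile_localization$glmm_wald
#' }
#' @export
run_pipeline <- function(config = analysis_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  skipped <- list()
  skip <- function(stage, e) {
    skipped[[stage]] <<- conditionMessage(e)
    say("  [skipped] %s: %s", stage, conditionMessage(e))
    NULL
  }

  # --- input -------------------------------------------------------------
  simulated <- is.null(config$input)
  ratings <- config$ratings
  if (simulated) {
    sim <- config$sim
    sim$seed <- config$seed
    trials <- simulate_dataset(sim)
    say("simulated %d trials (%d participants, seed %d)", nrow(trials),
        dplyr::n_distinct(trials$participant_id), config$seed)
    if ("reliability" %in% config$analyses && is.null(ratings)) {
      ratings <- simulate_raters(trials, sim)
      trials <- reconcile_ratings(ratings)
      rec <- attr(trials, "reconciliation")
      say("reconciled ratings: %d agreed, %d disagreement-excluded",
          rec$n_agreed, rec$n_disagreed)
    }
  } else if (is.character(config$input)) {
    trials <- read_trials(config$input)
    say("read %d trials from %s", nrow(trials), config$input)
  } else {
    trials <- validate_trials(config$input)
  }
  if (is.character(ratings)) ratings <- read_ratings(ratings)

  # --- reliability -------------------------------------------------------
  reliability <- NULL
  if ("reliability" %in% config$analyses) {
    reliability <- if (is.null(ratings)) {
      skip("reliability", simpleError("no ratings available"))
    } else {
      tryCatch(rating_reliability(ratings),
               error = function(e) skip("reliability", e))
    }
  }

  # --- accounting and filtering ------------------------------------------
  accounting <- trial_accounting(trials)
  analyzed <- filter_trials(trials, config$rt_cutoff_s)
  rem <- attr(analyzed, "removed")
  say("filtering: %d of %d trials analyzable (%d null, %d over cutoff)",
      nrow(analyzed), nrow(trials), sum(rem$n_null), sum(rem$n_over_cutoff))

  # --- mixed models ------------------------------------------------------
  models <- list()
  for (analysis in intersect(config$analyses, model_analyses)) {
    hao <- config$hand_arm_only && analysis == "tactile_localization"
    entry <- tryCatch({
      dspec <- at_model_spec(analysis, "direction", hand_arm_only = hao)
      rspec <- at_model_spec(analysis, "rt", hand_arm_only = hao)
      gfit <- fit_glmm(analyzed, dspec, n_quad = config$n_quad)
      lfit <- fit_lmm(analyzed, rspec)
      fams <- contrast_families(dspec)
      contrasts <- purrr::map_dfr(fams, function(f) {
        mutate(emm_contrasts(lfit, f$compare, f$by, correction_n = f$n),
               compare = f$compare, .before = 1)
      })
      say("%s: GLMM (n=%d) and LMM (n=%d) fitted", analysis,
          gfit$n_obs, lfit$n_obs)
      list(glmm = gfit, lmm = lfit,
           glmm_wald = wald_type3(gfit), lmm_wald = wald_type3(lfit),
           contrasts = contrasts)
    }, error = function(e) skip(analysis, e))
    models[[analysis]] <- entry
  }

  # --- race model --------------------------------------------------------
  race <- NULL
  if ("race_model" %in% config$analyses) {
    race <- tryCatch({
      rg <- redundancy_gain(analyzed)
      say("race model: %d complete participant x posture cells",
          nrow(distinct(rg$gains, .data$participant_id, .data$posture)))
      rg
    }, error = function(e) skip("race_model", e))
  }

  structure(
    list(trials = trials, analyzed = analyzed, accounting = accounting,
         reliability = reliability, models = models, race = race,
         skipped = skipped, config = config),
    class = "at_report"
  )
}

#' @export
print.at_report <- function(x, ...) {
  cat("<at_report>\n")
  cat("  trials:", nrow(x$trials), "| analyzable:", nrow(x$analyzed), "\n")
  cat("  model analyses:", paste(names(x$models), collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trial accounting per group
#'
#' Summarises, per group, the per-participant numbers of completed trials
#' (marked valid), contributed trials (with an orienting response), null
#' trials, and the percentage of responses by modality, and compares the
#' per-participant counts between groups with Welch t tests (no variance
#' homogeneity assumed).
#'
#' @param trials A validated trial tibble (before filtering).
#' @return A list of class `"trial_accounting"`: `by_participant`,
#'   `by_group` summary and `tests` (Welch comparisons).
#' @export
trial_accounting <- function(trials) {
  per <- trials %>%
    group_by(.data$participant_id, .data$group) %>%
    summarise(
      completed = sum(.data$valid),
      contributed = sum(.data$valid & .data$response_modality != "null"),
      null = sum(.data$valid & .data$response_modality == "null"),
      arm_hand = sum(.data$valid & .data$response_modality == "arm_hand"),
      eye_head = sum(.data$valid & .data$response_modality == "eye_head"),
      both = sum(.data$valid & .data$response_modality == "both"),
      .groups = "drop"
    ) %>%
    mutate(
      pct_arm_hand = 100 * .data$arm_hand / .data$contributed,
      pct_eye_head = 100 * .data$eye_head / .data$contributed,
      pct_both = 100 * .data$both / .data$contributed,
      pct_null = 100 * .data$null / .data$completed
    )
  by_group <- per %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      mean_completed = mean(.data$completed), sd_completed = sd(.data$completed),
      mean_contributed = mean(.data$contributed),
      sd_contributed = sd(.data$contributed),
      mean_pct_arm_hand = mean(.data$pct_arm_hand),
      se_pct_arm_hand = sd(.data$pct_arm_hand) / sqrt(dplyr::n()),
      mean_pct_eye_head = mean(.data$pct_eye_head),
      mean_pct_both = mean(.data$pct_both),
      mean_pct_null = mean(.data$pct_null),
      .groups = "drop"
    )
  tests <- purrr::map_dfr(
    c("completed", "contributed", "arm_hand", "eye_head", "both"),
    function(v) {
      s <- per[[v]][per$group == "S"]
      sv <- per[[v]][per$group == "SVI"]
      if (length(s) < 2 || length(sv) < 2 ||
          (sd(s) == 0 && sd(sv) == 0)) {
        return(tibble(measure = v, t = 0, df = NA_real_, p = NA_real_))
      }
      tt <- stats::t.test(s, sv, var.equal = FALSE)
      tibble(measure = v, t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value)
    })
  structure(list(by_participant = per, by_group = by_group, tests = tests),
            class = "trial_accounting")
}

#' @export
print.trial_accounting <- function(x, ...) {
  cat("<trial_accounting>\n")
  print(x$by_group)
  invisible(x)
}

#' @method tidy trial_accounting
#' @export
tidy.trial_accounting <- function(x, ...) x$by_group

#' Write the report tables to a directory
#'
#' Exports the Wald tables, contrast tables, race-gain tables, reliability
#' summary, trial accounting and a machine-readable run manifest as
#' TSV/JSON files. Outputs are byte-identical across runs with the same
#' configuration and seed.
#'
#' @param report An `"at_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")))
  }
  for (analysis in names(report$models)) {
    m <- report$models[[analysis]]
    if (is.null(m)) next
    tsv(mutate(m$glmm_wald, model = "glmm", .before = 1) %>%
          bind_rows(mutate(m$lmm_wald, model = "lmm", .before = 1)),
        paste0("wald_", analysis))
    tsv(m$contrasts, paste0("contrasts_", analysis))
  }
  if (!is.null(report$race)) {
    tsv(report$race$tests, "race_gains")
    tsv(report$race$group_tests, "race_group_comparisons")
  }
  tsv(report$accounting$by_group, "trial_accounting")
  tsv(report$accounting$tests, "trial_accounting_tests")
  if (!is.null(report$reliability)) {
    write_reliability_json(report$reliability,
                           file.path(dir, "reliability.json"))
  }
  manifest <- list(
    package = "audiotactile",
    version = as.character(utils::packageVersion("audiotactile")),
    seed = report$config$seed,
    analyses = report$config$analyses,
    rt_cutoff_s = report$config$rt_cutoff_s,
    config_hash = rlang::hash(report$config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
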