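#' Read a pipeline run configuration
#'
#' A YAML (or JSON) file with optional blocks: `sim` (fields of
#' [sim_config()]), `outcomes` (subset of the two outcome names),
#' `learners`, `thresholds`, `pair_cap`, `grid` (`"default"` or
#' `"compact"`), and `seed`. Missing fields take the defaults.
#'
#' @param path Path to the config file; `NULL` gives all defaults.
#' @param seed Optional seed overriding the file's.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    sim = do.call(sim_config, raw$sim %||% list()),
    outcomes = raw$outcomes %||% c("migraine_vs_rest", "headache_vs_none"),
    learners = raw$learners %||% LEARNERS,
    thresholds = raw$thresholds %||% c(0.25, 0.5, 0.75),
    pair_cap = raw$pair_cap %||% 200,
    grid = raw$grid %||% "default",
    seed = as.integer(seed %||% raw$seed %||% raw$sim$seed %||% 1L)
  )
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end forecasting pipeline
#'
#' Orchestrates the whole analysis on a simulated cohort (or on supplied
#' minute/diary tables): simulate, attach next-day labels, exclude
#' out-of-bed minutes, diagnose missingness, featurize 5-minute intervals
#' (imputing any gaps), fit the group-level mixed models, run the nested
#' per-participant cross-validation for each eligible (participant,
#' outcome) pair, and evaluate threshold metrics. All stage outputs are
#' written as CSVs under `out_dir`; identical config and seed give
#' byte-identical outputs.
#'
#' @param config A `run_config` (or path to one; see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param minutes,diary Optional observed tables; when `NULL` a cohort is
#'   simulated from `config$sim`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `nightly_predictions`,
#'   `participant_metrics`, `threshold_metrics`, `eligibility`,
#'   `group_lmm`, `missingness`, and the output paths.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = tempfile("run"),
                         minutes = NULL, diary = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))

  if (is.null(minutes)) {
    say("simulating cohort (%d participants x %d nights)",
        config$sim$n_participants, config$sim$nights_per_participant)
    cohort <- simulate_cohort(config$sim)
    minutes <- cohort$minutes; diary <- cohort$diary
  }
  write_minutes(minutes, file.path(out_dir, "minutes.csv"))
  write_diary(diary, file.path(out_dir, "diary.csv"))

  labeled <- attach_labels(minutes, diary)
  sleep <- night_sleep_metrics(labeled$minutes)
  miss <- missingness_association(labeled)
  say("missingness verdict: %s", miss$verdict)

  nightly <- nightly_metrics(labeled)
  lmm <- fit_group_lmm(nightly)
  readr::write_csv(lmm$results, file.path(out_dir, "group_lmm.csv"))
  readr::write_csv(lmm$summary, file.path(out_dir, "group_summary.csv"))

  inbed <- exclude_out_of_bed(labeled$minutes)
  intervals <- interval_features(inbed, sleep)
  if (anyNA(intervals[feature_columns(intervals)])) {
    say("imputing missing interval cells")
    intervals <- impute_mice(intervals, seed = derive_seed(config$seed, "mice"))
  }
  readr::write_csv(intervals, file.path(out_dir, "intervals.csv"))

  grids <- if (identical(config$grid, "compact")) compact_grids()
           else default_grids()
  nights <- distinct(intervals, .data$participant_id, .data$night_index,
                     .data$label)
  results <- list(); elig_all <- list()
  for (oc_name in config$outcomes) {
    oc <- outcome_def(oc_name)
    elig <- eligible(nights, oc)
    elig_all[[oc_name]] <- elig
    for (pid in elig$participant_id[elig$eligible]) {
      say("nested CV: participant %s, outcome %s", pid, oc_name)
      res <- run_participant(intervals[intervals$participant_id == pid, ],
                             oc, learners = config$learners,
                             seed = config$seed, grids = grids,
                             pair_cap = config$pair_cap)
      results[[paste(pid, oc_name)]] <- res
    }
  }

  preds <- bind_rows(purrr::map(results, "predictions"))
  metrics <- bind_rows(purrr::map(results, "metrics"))
  eligibility <- bind_rows(elig_all)
  thr <- purrr::map_dfr(results, function(r) {
    best_preds <- r$predictions %>% filter(.data$learner == r$best)
    purrr::map_dfr(config$thresholds, ~ threshold_metrics(best_preds, .x)) %>%
      mutate(participant_id = r$participant_id, outcome = r$outcome$name,
             learner = r$best)
  })

  readr::write_csv(preds, file.path(out_dir, "nightly_predictions.csv"))
  readr::write_csv(metrics, file.path(out_dir, "participant_metrics.csv"))
  readr::write_csv(thr, file.path(out_dir, "threshold_metrics.csv"))
  readr::write_csv(eligibility, file.path(out_dir, "eligibility.csv"))

  invisible(list(nightly_predictions = preds, participant_metrics = metrics,
                 threshold_metrics = thr, eligibility = eligibility,
                 group_lmm = lmm, missingness = miss, results = results,
                 out_dir = out_dir))
}
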