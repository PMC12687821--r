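#' Calibration studies for the forecasting framework
#'
#' These functions run the package's own end-to-end checks on synthetic
#' cohorts: a null-control study (no planted effects; cross-validated AUROC
#' should be centred near chance), a signal-recovery study (strong planted
#' pre-migraine effects should be detected by the nested framework, ranked
#' first by SHAP, and localized by the temporal GAM), and a family-wise
#' error study for the group-level mixed models. They are what the test
#' suite and the reproduction script execute; night lengths are kept short
#' where the nightly interval count is irrelevant to the property under
#' study, so the studies run at desk scale.
#'
#' @name calibration
NULL

# study conditions: null cohorts at the study's label structure
# (36 nights, prevalence 0.30) with short nights
null_study_config <- function(seed, n_participants = 1, nights = 36) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = 0.3, p_nonmigraine = 0,
             baseline_night_minutes = c(mean = 150, sd = 20),
             baseline_awake_minutes = c(mean = 20, sd = 6),
             seed = seed)
}

# strong planted pre-migraine effects: 1.5 uS EDA bump at 135 min, one-hour
# sleep deficit, -5/+5 PRV early-drop/late-rise
planted_study_config <- function(seed, n_participants = 1, nights = 30) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = 0.3, p_nonmigraine = 0,
             baseline_night_minutes = c(mean = 240, sd = 30),
             baseline_awake_minutes = c(mean = 30, sd = 10),
             effect_eda_peak_amp = 1.5, effect_sleep_shift = -60,
             effect_prv_early_drop = -5, effect_prv_late_rise = 5,
             seed = seed)
}

# planted effects on full-length nights covering the 420-min GAM horizon
gam_study_config <- function(seed, n_participants = 2, nights = 40) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = 0.4, p_nonmigraine = 0,
             baseline_night_minutes = c(mean = 500, sd = 40),
             effect_eda_peak_amp = 1.0, effect_prv_early_drop = -5,
             effect_prv_late_rise = 5, seed = seed)
}

sim_to_intervals <- function(config) {
  cohort <- simulate_cohort(config)
  lab <- attach_labels(cohort$minutes, cohort$diary)
  sleep <- night_sleep_metrics(lab$minutes)
  iv <- interval_features(exclude_out_of_bed(lab$minutes), sleep)
  if (anyNA(iv[feature_columns(iv)]))
    iv <- impute_mice(iv, seed = config$seed)
  iv
}

#' @rdname calibration
#' @param n_participants Number of simulated null participants.
#' @param nights Nights per participant.
#' @param seed Integer seed.
#' @param grids,pair_cap Passed to [run_participant()].
#' @return `study_null_auroc()`: per-(participant, learner) metrics tibble;
#'   ineligible draws are skipped.
#' @export
study_null_auroc <- function(n_participants = 20, nights = 36, seed = 1L,
                             grids = compact_grids(), pair_cap = 6) {
  oc <- outcome_def("migraine_vs_rest")
  purrr::map_dfr(seq_len(n_participants), function(i) {
    cfg <- null_study_config(derive_seed(seed, "null", i), nights = nights)
    iv <- suppressMessages(sim_to_intervals(cfg))
    nights_tbl <- distinct(iv, .data$participant_id, .data$night_index,
                           .data$label)
    if (!eligible(nights_tbl, oc)$eligible[1]) return(tibble())
    res <- run_participant(iv, oc, seed = derive_seed(seed, "run", i),
                           grids = grids, pair_cap = pair_cap)
    mutate(res$metrics, replicate = i)
  })
}

#' @rdname calibration
#' @param n_seeds Number of replicate planted-effect participants.
#' @return `study_signal_recovery()`: one row per seed with the best
#'   learner, its cross-validated AUROC, the top-ranked SHAP feature on the
#'   final refit, and whether that feature derives from a planted signal
#'   (sleep duration, EDA or PRV).
#' @export
study_signal_recovery <- function(n_seeds = 20, nights = 30, seed = 1L,
                                  grids = compact_grids(), pair_cap = 6) {
  oc <- outcome_def("migraine_vs_rest")
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg <- planted_study_config(derive_seed(seed, "planted", i),
                                nights = nights)
    iv <- suppressMessages(sim_to_intervals(cfg))
    nights_tbl <- distinct(iv, .data$participant_id, .data$night_index,
                           .data$label)
    if (!eligible(nights_tbl, oc)$eligible[1]) return(tibble())
    res <- run_participant(iv, oc, seed = derive_seed(seed, "run", i),
                           grids = grids, pair_cap = pair_cap)

    # explanatory SHAP on the per-participant final refit (all nights)
    tuned <- tune_learner(iv, oc, res$best, grids[[res$best]],
                          pair_cap = pair_cap,
                          seed = derive_seed(seed, "shap", i))
    fitted <- fit_final(iv, oc, res$best, tuned$params,
                        seed = derive_seed(seed, "shap", i))
    sh <- shap_summary(fitted, iv)
    top <- sh$ranking$feature[1]
    tibble(replicate = i, best_learner = res$best,
           best_auroc = max(res$metrics$auroc), top_feature = top,
           top_planted = grepl("^(time_asleep|time_in_bed|eda|prv)", top))
  })
}

#' @rdname calibration
#' @return `study_gam_localization()`: the minute (after sleep onset) of the
#'   largest migraine-vs-none difference of the smoothed EDA curves.
#' @export
study_gam_localization <- function(seed = 1L) {
  cohort <- simulate_cohort(gam_study_config(derive_seed(seed, "gam")))
  lab <- attach_labels(cohort$minutes, cohort$diary)
  g <- fit_temporal_gam(lab$minutes, "eda")
  ct <- g$contrasts
  ct$peak_minute[ct$group_a == "migraine" & ct$group_b == "none"]
}

#' @rdname calibration
#' @param n_cohorts Number of replicate null cohorts.
#' @param alpha Significance level.
#' @return `study_fwer()`: the fraction of null cohorts in which any
#'   Holm-corrected metric p-value falls below `alpha`.
#' @export
study_fwer <- function(n_cohorts = 100, seed = 1L, alpha = 0.05) {
  hits <- vapply(seq_len(n_cohorts), function(i) {
    cfg <- sim_config(n_participants = 4, nights_per_participant = 20,
                      p_migraine = 0.25, p_nonmigraine = 0.15,
                      baseline_night_minutes = c(mean = 150, sd = 20),
                      baseline_awake_minutes = c(mean = 20, sd = 6),
                      seed = derive_seed(seed, "fwer", i))
    cohort <- simulate_cohort(cfg)
    lab <- attach_labels(cohort$minutes, cohort$diary)
    lmm <- suppressWarnings(fit_group_lmm(nightly_metrics(lab)))
    any(lmm$results$p_adj < alpha, na.rm = TRUE)
  }, logical(1))
  mean(hits)
}

#' Wear-efficiency summary of the reference cohort
#'
#' Recomputes per-participant data-collection efficiency
#' (analyzable nights / total nights worn) from the published reference
#' wear-time counts shipped with the package, and summarises the cohort
#' mean and standard deviation in percent.
#'
#' @param path CSV of per-participant counts; defaults to the shipped file.
#' @return A list: per-participant `efficiency` tibble, `mean_pct`,
#'   `sd_pct`.
#' @export
wear_efficiency_summary <- function(path = system.file(
  "extdata", "reference_wear_counts.csv", package = "nocturne")) {
  counts <- readr::read_csv(path, show_col_types = FALSE)
  eff <- mutate(counts,
                efficiency = .data$analyzable_nights / .data$total_nights)
  list(efficiency = eff,
       mean_pct = 100 * mean(eff$efficiency),
       sd_pct = 100 * sd(eff$efficiency))
}

#' Consistency check of published threshold-metric rows
#'
#' Rebuilds each published threshold row's confusion matrix from its printed
#' sensitivity, specificity and day counts via [confusion_from_summary()]
#' and rederives accuracy and precision for comparison with the printed
#' values.
#'
#' @param path CSV of published rows; defaults to the shipped file.
#' @return The rows with recomputed `tp`, `fp`, `tn`, `fn`,
#'   `accuracy_recomputed_pct` and `precision_recomputed_pct`.
#' @export
threshold_reference_check <- function(path = system.file(
  "extdata", "reference_threshold_rows.csv", package = "nocturne")) {
  rows <- readr::read_csv(path, show_col_types = FALSE)
  recon <- purrr::pmap_dfr(rows, function(...) {
    r <- list(...)
    cm <- confusion_from_summary(r$sensitivity_pct / 100,
                                 r$specificity_pct / 100,
                                 r$positive_days,
                                 r$total_days - r$positive_days)
    tibble(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
           accuracy_recomputed_pct = 100 * cm$accuracy,
           precision_recomputed_pct = 100 * cm$precision,
           consistent = cm$consistent)
  })
  bind_cols(rows, recon)
}
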