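oc <- outcome_def("migraine_vs_rest")

test_that("SHAP attributions satisfy local accuracy for every learner", {
  iv <- cohort_intervals(strong_effect_config(seed = 6, nights = 16))
  rows <- iv[1:40, ]
  for (spec in list(list("elastic_net", list(alpha = 0.5, lambda = 0.05)),
                    list("random_forest", list(mtry_frac = 1 / 3,
                                               min_leaf = 5,
                                               num_trees = 50)),
                    list("gbm", list(nrounds = 40, max_depth = 2,
                                     eta = 0.1)))) {
    model <- fit_final(iv, oc, spec[[1]], spec[[2]], seed = 4)
    sh <- shap_summary(model, rows)
    xs <- as.matrix(apply_scaler(model$scaler, rows)[model$features])
    margin <- nocturne:::predict_margin(model$model, xs)
    expect_lt(max(abs(sh$margin - margin)), 1e-6)
    # normalized feature values span [0, 1]
    expect_gte(min(sh$attributions$value_scaled, na.rm = TRUE), 0)
    expect_lte(max(sh$attributions$value_scaled, na.rm = TRUE), 1)
  }
})

test_that("the retention filter behaves and an infinite filter empties the set", {
  iv <- cohort_intervals(strong_effect_config(seed = 6, nights = 16))
  model <- fit_final(iv, oc, "gbm", list(nrounds = 40, max_depth = 2,
                                         eta = 0.1), seed = 4)
  sh <- shap_summary(model, iv, filter = 0.25)
  expect_true(all(sh$ranking$max_abs_phi[sh$ranking$retained] >= 0.25))
  empty <- shap_summary(model, iv, filter = Inf)
  expect_equal(sum(empty$ranking$retained), 0)
  expect_error(shap_summary(model, iv[, 1:5]), "feature column")
})

test_that("SHAP ranks the planted sleep-duration effect first", {
  cfg <- sim_config(n_participants = 1, nights_per_participant = 24,
                    p_migraine = 0.35, p_nonmigraine = 0,
                    baseline_night_minutes = c(mean = 240, sd = 25),
                    effect_sleep_shift = -70, seed = 15)
  iv <- cohort_intervals(cfg)
  model <- fit_final(iv, oc, "gbm", list(nrounds = 60, max_depth = 2,
                                         eta = 0.1), seed = 2)
  sh <- shap_summary(model, iv)
  top <- sh$ranking$feature[1]
  expect_match(top, "^time_(asleep|in_bed)")
  # shorter sleep pushes migraine risk up: negative direction
  expect_equal(sh$ranking$direction[1], -1)
})

test_that("temporal GAM recovers the planted EDA peak and PRV shape", {
  coh <- simulate_cohort(gam_effect_config(seed = 8))
  lab <- attach_labels(coh$minutes, coh$diary)

  g_eda <- fit_temporal_gam(lab$minutes, "eda")
  ct <- g_eda$contrasts
  expect_equal(ct$group_a, "migraine"); expect_equal(ct$group_b, "none")
  expect_gte(ct$peak_minute, 120)
  expect_lte(ct$peak_minute, 150)

  g_prv <- fit_temporal_gam(lab$minutes, "prv")
  cur <- tidy(g_prv) %>%
    tidyr::pivot_wider(id_cols = "minute", names_from = "group",
                       values_from = "estimate") %>%
    dplyr::mutate(diff = migraine - none)
  expect_true(all(cur$diff[cur$minute <= 100] < 0))
  expect_true(all(cur$diff[cur$minute >= 170] > 0))
})

test_that("GAM curves carry CI bands, overlap under the null, and respect groups", {
  coh <- simulate_cohort(gam_effect_config(seed = 12))
  null_cfg <- gam_effect_config(seed = 12)
  null_cfg$effect_eda_peak_amp <- 0
  null_cfg$effect_prv_early_drop <- 0
  null_cfg$effect_prv_late_rise <- 0
  coh0 <- simulate_cohort(null_cfg)
  lab0 <- attach_labels(coh0$minutes, coh0$diary)
  g0 <- fit_temporal_gam(lab0$minutes, "prv")
  wide <- tidy(g0) %>%
    tidyr::pivot_wider(id_cols = "minute", names_from = "group",
                       values_from = c("ci_lo", "ci_hi"))
  overlap <- with(wide, pmin(ci_hi_migraine, ci_hi_none) >=
                          pmax(ci_lo_migraine, ci_lo_none))
  expect_gt(mean(overlap), 0.95)
  cur <- tidy(g0)
  expect_true(all(cur$ci_lo <= cur$estimate & cur$estimate <= cur$ci_hi))
  expect_equal(sort(unique(cur$minute)), 0:420)
})

test_that("doubling the smoothing penalty never increases wiggliness", {
  coh <- simulate_cohort(gam_effect_config(seed = 9, n_participants = 1,
                                           nights = 30))
  lab <- attach_labels(coh$minutes, coh$diary)
  g <- fit_temporal_gam(lab$minutes, "eda")
  for (grp in names(g$fits)) {
    f <- g$fits[[grp]]
    f2 <- mgcv::gam(formula(f), data = f$model, sp = 2 * f$sp)
    expect_lte(sum(f2$edf), sum(f$edf) + 1e-8)
  }
})

test_that("groups with too few nights are skipped with a message", {
  coh <- simulate_cohort(gam_effect_config(seed = 3))
  lab <- attach_labels(coh$minutes, coh$diary)
  m <- lab$minutes
  # keep only two migraine nights
  mig_nights <- dplyr::distinct(m[m$label == "migraine", ],
                                participant_id, night_index)
  drop <- mig_nights[-(1:2), ]
  m2 <- dplyr::anti_join(m, drop, by = c("participant_id", "night_index"))
  expect_error(expect_message(fit_temporal_gam(m2, "prv"), "skipped"),
               ">= 2 outcome groups")
})
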