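oc_mig <- outcome_def("migraine_vs_rest")
oc_ha <- outcome_def("headache_vs_none")

test_that("outcome definitions pin the positive label sets", {
  expect_equal(oc_mig$positives, "migraine")
  expect_setequal(oc_ha$positives, c("migraine", "non_migraine"))
})

test_that("eligibility requires two nights of each class", {
  nights <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), c(5, 4, 4)),
    night_index = c(1:5, 1:4, 1:4),
    label = c("migraine", "migraine", "none", "none", "none",
              "migraine", "none", "none", "none",
              "none", "none", "none", "none"))
  e <- eligible(nights, oc_mig)
  expect_true(e$eligible[e$participant_id == "A"])
  expect_false(e$eligible[e$participant_id == "B"])   # 1 positive
  expect_match(e$reason[e$participant_id == "B"], "positive")
  expect_false(e$eligible[e$participant_id == "C"])   # 0 positives
})

test_that("outer folds cover each night exactly once, disjointly", {
  folds <- enumerate_l1no(1:9)
  expect_equal(nrow(folds), 9)
  expect_setequal(folds$test_night, 1:9)
  for (k in seq_len(nrow(folds))) {
    expect_false(folds$test_night[k] %in% folds$training[[k]])
    expect_setequal(c(folds$test_night[k], folds$training[[k]]), 1:9)
  }
})

test_that("inner pairs enumerate the full product and cap deterministically", {
  nights <- tibble::tibble(night_index = 1:8,
                           label = rep(c("migraine", "none"), c(3, 5)))
  pairs <- enumerate_l2no(nights, oc_mig)
  expect_equal(nrow(pairs), 15)
  expect_true(all(pairs$pos_night %in% 1:3))
  expect_true(all(pairs$neg_night %in% 4:8))
  expect_equal(nrow(dplyr::distinct(pairs)), 15)

  big <- tibble::tibble(night_index = 1:40,
                        label = rep(c("migraine", "none"), each = 20))
  capped <- enumerate_l2no(big, oc_mig, cap = 50, seed = 9)
  expect_equal(nrow(capped), 50)
  expect_equal(nrow(dplyr::distinct(capped)), 50)
  expect_identical(capped, enumerate_l2no(big, oc_mig, cap = 50, seed = 9))

  onesided <- tibble::tibble(night_index = 1:4, label = rep("none", 4))
  expect_error(enumerate_l2no(onesided, oc_mig),
               class = "nocturne_fold_error")
})

test_that("nightly aggregation averages interval probabilities with a CI", {
  iv <- cohort_intervals(short_night_config(n_participants = 1, nights = 8,
                                            seed = 5))
  model <- fit_final(iv, oc_mig, "elastic_net",
                     list(alpha = 0.5, lambda = 0.1), seed = 1)
  night <- iv[iv$night_index == 2, ]
  pred <- predict_night(model, night)
  # p_hat equals the arithmetic mean of the interval probabilities
  xs <- as.matrix(apply_scaler(model$scaler, night)[feature_columns_tst(night)])
  probs <- as.numeric(predict(model$model$fit, xs, s = 0.1,
                              type = "response"))
  expect_equal(pred$p_hat, mean(probs), tolerance = 1e-10)
  expect_true(pred$ci_lo <= pred$p_hat && pred$p_hat <= pred$ci_hi)
  # order invariance
  pred2 <- predict_night(model, night[sample.int(nrow(night)), ])
  expect_equal(pred2$p_hat, pred$p_hat, tolerance = 1e-12)
  # zero rows -> skipped with a message
  expect_message(empty <- predict_night(model, night[0, ]), "skipped")
  expect_equal(nrow(empty), 0)
})

test_that("tuning scores concordance, prefers simpler ties, is near 1 on strong effects", {
  # very large planted effect: nights separate almost perfectly
  big <- sim_config(n_participants = 1, nights_per_participant = 20,
                    p_migraine = 0.3, p_nonmigraine = 0,
                    baseline_night_minutes = c(mean = 240, sd = 30),
                    baseline_awake_minutes = c(mean = 30, sd = 10),
                    effect_eda_peak_amp = 2.5, effect_sleep_shift = -120,
                    seed = 2)
  iv <- cohort_intervals(big)
  grid <- tibble::tibble(alpha = 0.5, lambda = c(0.1, 0.01))
  tuned <- tune_learner(iv, oc_mig, "elastic_net", grid, pair_cap = 10,
                        seed = 3)
  expect_gte(tuned$score, 0.9)
  expect_true(all(tuned$scores$score >= 0 & tuned$scores$score <= 1))

  # a single grid point is returned unconditionally
  single <- tune_learner(iv, oc_mig, "gbm",
                         tibble::tibble(nrounds = 30, max_depth = 2,
                                        eta = 0.1))
  expect_equal(single$params$nrounds, 30)
  expect_error(tune_learner(iv, oc_mig, "gbm", tibble::tibble()), "empty")
})

test_that("run_participant is deterministic and recovers a strong planted effect", {
  iv <- cohort_intervals(strong_effect_config(seed = 4, nights = 20))
  res1 <- run_participant(iv, oc_mig, seed = 11, grids = compact_grids(),
                          pair_cap = 6)
  res2 <- run_participant(iv, oc_mig, seed = 11, grids = compact_grids(),
                          pair_cap = 6)
  expect_identical(res1$metrics, res2$metrics)
  expect_identical(res1$predictions, res2$predictions)
  expect_equal(nrow(res1$predictions), 20 * 3)  # every night x learner
  expect_gte(max(res1$metrics$auroc), 0.75)

  # permuting labels destroys the signal
  ivp <- iv
  perm <- withr::with_seed(7, {
    nights <- dplyr::distinct(iv, night_index, label)
    setNames(sample(nights$label), nights$night_index)
  })
  ivp$label <- unname(perm[as.character(ivp$night_index)])
  resp <- run_participant(ivp, oc_mig, seed = 11, grids = compact_grids(),
                          pair_cap = 6)
  expect_gt(max(res1$metrics$auroc) - max(resp$metrics$auroc), 0.1)
})

test_that("nightly AUROC equals pairwise concordance over night pairs", {
  iv <- cohort_intervals(short_night_config(n_participants = 1, nights = 12,
                                            seed = 19))
  res <- run_participant(iv, oc_mig, learners = "elastic_net", seed = 2,
                         grids = list(elastic_net = tibble::tibble(
                           alpha = 0.5, lambda = 0.05)))
  pr <- res$predictions
  pos <- pr$p_hat[pr$positive]; neg <- pr$p_hat[!pr$positive]
  brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(res$metrics$auroc, brute, tolerance = 1e-12)
})

test_that("the held-out night cannot influence training artifacts", {
  iv <- cohort_intervals(short_night_config(n_participants = 1, nights = 10,
                                            seed = 23))
  test_night <- 3
  train <- iv[iv$night_index != test_night, ]

  run_fold <- function(intervals) {
    train_f <- intervals[intervals$night_index != test_night, ]
    tuned <- tune_learner(train_f, oc_mig, "elastic_net",
                          tibble::tibble(alpha = 0.5, lambda = c(0.1, 0.01)),
                          pair_cap = 5, seed = 31)
    fitted <- fit_final(train_f, oc_mig, "elastic_net", tuned$params,
                        seed = 31)
    list(params = tuned$params, scaler = fitted$scaler,
         beta = as.numeric(coef(fitted$model$fit, s = tuned$params$lambda)))
  }
  base <- run_fold(iv)
  mutated <- iv
  sel <- mutated$night_index == test_night
  mutated[sel, feature_columns_tst(mutated)] <-
    mutated[sel, feature_columns_tst(mutated)] + 50
  after <- run_fold(mutated)
  expect_identical(base$params, after$params)
  expect_identical(base$scaler, after$scaler)
  expect_identical(base$beta, after$beta)
})

test_that("ineligible participants are refused with context", {
  iv <- cohort_intervals(short_night_config(n_participants = 1, nights = 8,
                                            seed = 3))
  iv$label <- "none"
  expect_error(run_participant(iv, oc_mig),
               class = "nocturne_eligibility_error")
})
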