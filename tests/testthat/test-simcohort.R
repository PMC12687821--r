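test_that("simulation is deterministic under seed and varies across seeds", {
  cfg <- short_night_config(n_participants = 1, nights = 6, seed = 7)
  a <- simulate_participant(cfg, "A")
  b <- simulate_participant(cfg, "A")
  expect_identical(a, b)

  cfg2 <- short_night_config(n_participants = 1, nights = 6, seed = 8)
  c <- simulate_participant(cfg2, "A")
  n <- min(nrow(a$minutes), nrow(c$minutes))
  expect_gt(max(abs(head(a$minutes$eda_us, n) - head(c$minutes$eda_us, n)),
                na.rm = TRUE), 0)

  # participants within a cohort are independent blocks with distinct seeds
  coh <- simulate_cohort(short_night_config(n_participants = 2, nights = 6,
                                            seed = 7))
  p1 <- coh$minutes[coh$minutes$participant_id == "P01", ]
  p2 <- coh$minutes[coh$minutes$participant_id == "P02", ]
  n2 <- min(nrow(p1), nrow(p2))
  expect_gt(max(abs(head(p1$eda_us, n2) - head(p2$eda_us, n2)),
                na.rm = TRUE), 0)
})

test_that("simulated nights satisfy the structural invariants", {
  cfg <- short_night_config(n_participants = 2, nights = 8, seed = 3)
  coh <- simulate_cohort(cfg)
  m <- coh$minutes
  expect_true(all(m$eda_us >= 0, na.rm = TRUE))
  expect_true(all(m$state %in% c("asleep", "awake_in_bed", "out_of_bed")))
  by_night <- split(m$minute_index, paste(m$participant_id, m$night_index))
  expect_true(all(vapply(by_night, function(x) all(diff(x) > 0), logical(1))))
  expect_equal(nrow(coh$diary), 2 * 8)
  expect_true(all(coh$diary$label %in% c("none", "non_migraine", "migraine")))
  # default cohort size targets the ~315-night scale of a 10 x ~36 study
  expect_equal(sim_config()$n_participants * sim_config()$nights_per_participant,
               360)
})

test_that("a null cohort's physiology is exchangeable across labels", {
  cfg <- short_night_config(n_participants = 3, nights = 30, seed = 21)
  coh <- simulate_cohort(cfg)
  lab <- attach_labels(coh$minutes, coh$diary)
  nm <- nightly_metrics(lab)
  ks <- suppressWarnings(stats::ks.test(nm$eda[nm$label == "migraine"],
                                        nm$eda[nm$label == "none"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted EDA bump localizes to the 120-150 min window", {
  # oracle: brute-force mean-difference curve over minutes since sleep onset,
  # smoothed with a 15-min moving average
  cfg <- sim_config(n_participants = 1, nights_per_participant = 200,
                    p_migraine = 0.5, p_nonmigraine = 0,
                    baseline_night_minutes = c(mean = 360, sd = 30),
                    effect_eda_peak_amp = 1.0, effect_eda_peak_time = 135,
                    seed = 13)
  sp <- simulate_participant(cfg, "X")
  lab <- attach_labels(sp$minutes, sp$diary)
  m <- lab$minutes %>%
    dplyr::group_by(night_index) %>%
    dplyr::mutate(t = minute_index -
                    minute_index[match("asleep", state)]) %>%
    dplyr::ungroup() %>%
    dplyr::filter(t >= 0, t <= 300)
  curve <- m %>%
    dplyr::group_by(t, is_mig = label == "migraine") %>%
    dplyr::summarise(eda = mean(eda_us), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = is_mig, values_from = eda) %>%
    dplyr::arrange(t) %>%
    dplyr::mutate(diff = `TRUE` - `FALSE`,
                  sm = as.numeric(stats::filter(diff, rep(1 / 15, 15))))
  peak <- curve$t[which.max(curve$sm)]
  expect_gte(peak, 120)
  expect_lte(peak, 150)
})

test_that("default cohort marginals match the targeted wear-study scale", {
  coh <- simulate_cohort(sim_config(n_participants = 6,
                                    nights_per_participant = 20, seed = 42))
  lab <- attach_labels(coh$minutes, coh$diary)
  nm <- nightly_metrics(lab)
  # median time in bed within +/-10% of 504 min; median nightly EDA in the
  # 0.1-1.0 uS interquartile band
  expect_gt(median(nm$time_in_bed), 504 * 0.9)
  expect_lt(median(nm$time_in_bed), 504 * 1.1)
  expect_gt(median(nm$eda), 0.1)
  expect_lt(median(nm$eda), 1.0)
  expect_gt(median(nm$time_asleep), 397.8)
  expect_lt(median(nm$time_asleep), 498.0)
})

test_that("missingness injection is calibrated MCAR and rate 0 is identity", {
  cfg <- short_night_config(n_participants = 1, nights = 12, seed = 5)
  sp <- simulate_participant(cfg, "A")
  expect_identical(inject_missingness(sp$minutes, 0), sp$minutes)

  dropped <- inject_missingness(sp$minutes, 0.2, seed = 11)
  expect_equal(nrow(dropped), nrow(sp$minutes))
  frac <- mean(!dropped$observed)
  se <- sqrt(0.2 * 0.8 / nrow(sp$minutes))
  expect_lt(abs(frac - 0.2), 3 * se)
  expect_true(all(is.na(dropped$eda_us[!dropped$observed])))
  expect_error(inject_missingness(sp$minutes, 1.2), class = "nocturne_config_error")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(p_migraine = 0.7, p_nonmigraine = 0.5),
               class = "nocturne_config_error")
  expect_error(sim_config(nights_per_participant = 3),
               class = "nocturne_config_error")
  expect_error(sim_config(ar_coef = 1), class = "nocturne_config_error")
  expect_error(sim_config(baseline_night_minutes = c(mean = 500, sd = -1)),
               class = "nocturne_config_error")
})
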