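# Shared cohort builders for the test suite.
#
# Short-night configs keep the per-night interval count small so the nested
# cross-validation runs at test scale; the label structure (36 nights,
# prevalence ~0.3) matches the study conditions the framework targets.

short_night_config <- function(n_participants = 2, nights = 36, seed = 1,
                               p_migraine = 0.3, p_nonmigraine = 0, ...) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = p_migraine, p_nonmigraine = p_nonmigraine,
             baseline_night_minutes = c(mean = 150, sd = 20),
             baseline_awake_minutes = c(mean = 20, sd = 6),
             seed = seed, ...)
}

# Strong planted pre-migraine effects: an EDA bump well above minute noise,
# a one-hour sleep-duration deficit, and a PRV early-drop/late-rise.
# Chosen once as the "strong amplitude" regime; medium-length nights so the
# 135-min EDA peak fits inside every night.
strong_effect_config <- function(seed = 1, n_participants = 1, nights = 30,
                                 ...) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = 0.3, p_nonmigraine = 0,
             baseline_night_minutes = c(mean = 240, sd = 30),
             baseline_awake_minutes = c(mean = 30, sd = 10),
             effect_eda_peak_amp = 1.5, effect_sleep_shift = -60,
             effect_prv_early_drop = -5, effect_prv_late_rise = 5,
             seed = seed, ...)
}

# Full-length nights (cover the 420-min GAM horizon) with planted effects.
gam_effect_config <- function(seed = 1, n_participants = 2, nights = 40) {
  sim_config(n_participants = n_participants, nights_per_participant = nights,
             p_migraine = 0.4, p_nonmigraine = 0,
             baseline_night_minutes = c(mean = 500, sd = 40),
             effect_eda_peak_amp = 1.0, effect_prv_early_drop = -5,
             effect_prv_late_rise = 5, seed = seed)
}

# simulate -> label -> featurize in one step; returns the interval table
cohort_intervals <- function(config) {
  cohort <- simulate_cohort(config)
  lab <- attach_labels(cohort$minutes, cohort$diary)
  sleep <- night_sleep_metrics(lab$minutes)
  iv <- interval_features(exclude_out_of_bed(lab$minutes), sleep)
  if (anyNA(iv[feature_columns_tst(iv)]))
    iv <- impute_mice(iv, seed = config$seed)
  iv
}

feature_columns_tst <- function(df) intersect(feature_names(), names(df))

# deterministic hand-built night for arithmetic checks
toy_night <- function(n_asleep = 420, n_awake = 50, n_oob = 10,
                      pid = "T1", night = 1L) {
  n <- n_asleep + n_awake + n_oob
  tibble::tibble(
    participant_id = pid,
    night_index = night,
    night_date = as.Date("2024-02-01") + night,
    minute_index = seq_len(n) - 1L,
    eda_us = 0.4,
    pulse_rate_bpm = 70,
    prv = 25,
    resp_rate_bpm = 16,
    temp_c = 34.5,
    state = c(rep("awake_in_bed", ceiling(n_awake / 2)),
              rep("asleep", n_asleep),
              rep("out_of_bed", n_oob),
              rep("awake_in_bed", floor(n_awake / 2))),
    observed = TRUE
  )
}
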