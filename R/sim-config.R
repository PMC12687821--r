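#' Simulation configuration for a synthetic wearable cohort
#'
#' Builds and validates the parameter set that drives [simulate_cohort()].
#' Defaults reproduce the statistical structure of a small adult migraine
#' cohort wearing a wrist device overnight for about five weeks: roughly 315
#' nights across 10 participants, nightly time in bed centred near 504
#' minutes, right-skewed electrodermal activity with a median around
#' 0.3 uS, and next-day diary labels drawn with migraine and non-migraine
#' headache prevalences of about 25% and 17%.
#'
#' All `effect_*` knobs default to zero (a null cohort). Setting them plants
#' pre-headache signatures on the relevant nights:
#'
#' * `effect_eda_peak_amp` adds a smooth Gaussian bump (sd 35 min) of the
#'   given amplitude (uS) to EDA on nights preceding a migraine day, centred
#'   `effect_eda_peak_time` minutes after sleep onset (default 135 min, the
#'   centre of the 120--150 min window where pre-migraine EDA peaks are
#'   typically reported).
#' * `effect_prv_early_drop` / `effect_prv_late_rise` shift pulse-rate
#'   variability by the given signed amounts before/after
#'   `effect_prv_changepoint` minutes of sleep on pre-migraine nights.
#' * `effect_sleep_shift` adds the given number of minutes to time in bed
#'   (and hence time asleep) on nights preceding any headache day.
#'
#' @param n_participants Number of simulated participants.
#' @param nights_per_participant Nights recorded per participant (>= 4).
#' @param p_migraine,p_nonmigraine Per-day probabilities of a migraine /
#'   non-migraine headache label; must sum to at most 1.
#' @param baseline_night_minutes Length-2 numeric `c(mean, sd)` of nightly
#'   time in bed, minutes.
#' @param baseline_awake_minutes Length-2 numeric `c(mean, sd)` of nightly
#'   awake-in-bed minutes.
#' @param signal_baselines Data frame with columns `signal`, `mean`,
#'   `sd_participant`, `sd_night`, `sd_minute`. EDA rows are interpreted on
#'   the natural-log scale (the trace is exponentiated, giving the right
#'   skew seen in wrist EDA); all other signals are Gaussian on their native
#'   scale. `default_signal_baselines()` gives the defaults.
#' @param effect_eda_peak_amp Amplitude (uS) of the pre-migraine EDA bump.
#' @param effect_eda_peak_time Bump centre, minutes after sleep onset.
#' @param effect_prv_early_drop,effect_prv_late_rise Signed PRV shifts (ms)
#'   before/after the changepoint on pre-migraine nights.
#' @param effect_prv_changepoint Changepoint, minutes after sleep onset.
#' @param effect_sleep_shift Minutes added to time in bed before headache
#'   days (negative values shorten sleep).
#' @param ar_coef Lag-1 autocorrelation of minute-level noise, in `[0, 1)`.
#' @param missing_rate Fraction of minutes dropped completely at random.
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 2, nights_per_participant = 6, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_participants = 10,
                       nights_per_participant = 36,
                       p_migraine = 0.25,
                       p_nonmigraine = 0.17,
                       baseline_night_minutes = c(mean = 505, sd = 55),
                       baseline_awake_minutes = c(mean = 56, sd = 18),
                       signal_baselines = default_signal_baselines(),
                       effect_eda_peak_amp = 0,
                       effect_eda_peak_time = 135,
                       effect_prv_early_drop = 0,
                       effect_prv_late_rise = 0,
                       effect_prv_changepoint = 150,
                       effect_sleep_shift = 0,
                       ar_coef = 0.7,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    nights_per_participant = as.integer(nights_per_participant),
    p_migraine = p_migraine,
    p_nonmigraine = p_nonmigraine,
    baseline_night_minutes = baseline_night_minutes,
    baseline_awake_minutes = baseline_awake_minutes,
    signal_baselines = as_tibble(signal_baselines),
    effect_eda_peak_amp = effect_eda_peak_amp,
    effect_eda_peak_time = effect_eda_peak_time,
    effect_prv_early_drop = effect_prv_early_drop,
    effect_prv_late_rise = effect_prv_late_rise,
    effect_prv_changepoint = effect_prv_changepoint,
    effect_sleep_shift = effect_sleep_shift,
    ar_coef = ar_coef,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default per-signal baseline parameters
#'
#' Means and variance components (between-participant, between-night,
#' within-night minute noise) for the five physiological signals. EDA is
#' parameterised on the log scale; the defaults put the cohort median of
#' nightly median EDA near 0.3 uS with interquartile range roughly
#' 0.1--1.0 uS, pulse rate near 70 bpm, PRV near 27 ms, respiratory rate
#' near 16.4 breaths/min and wrist temperature near 34.5 C.
#'
#' @return A tibble with one row per signal.
#' @export
default_signal_baselines <- function() {
  tibble(
    signal        = c("eda", "pulse_rate", "prv", "resp_rate", "temperature"),
    mean          = c(-1.20, 70.5, 26.5, 16.5, 34.45),
    sd_participant = c(1.45, 6.0, 9.0, 0.9, 0.55),
    sd_night      = c(0.80, 4.0, 8.0, 0.7, 0.50),
    sd_minute     = c(0.50, 3.0, 6.0, 0.5, 0.30)
  )
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "nocturne_config_error")
  probs <- c(cfg$p_migraine, cfg$p_nonmigraine)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    bad("p_migraine and p_nonmigraine must be probabilities in [0, 1]")
  if (cfg$p_migraine + cfg$p_nonmigraine > 1)
    bad("p_migraine + p_nonmigraine must not exceed 1")
  if (cfg$nights_per_participant < 4)
    bad("nights_per_participant must be at least 4")
  if (cfg$n_participants < 1) bad("n_participants must be at least 1")
  sds <- c(cfg$baseline_night_minutes[2], cfg$baseline_awake_minutes[2],
           cfg$signal_baselines$sd_participant,
           cfg$signal_baselines$sd_night, cfg$signal_baselines$sd_minute)
  if (any(sds < 0)) bad("all standard deviations must be >= 0")
  if (cfg$ar_coef < 0 || cfg$ar_coef >= 1)
    bad("ar_coef must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad("missing_rate must lie in [0, 1)")
  need <- c("signal", "mean", "sd_participant", "sd_night", "sd_minute")
  assert_columns(cfg$signal_baselines, need, "signal_baselines")
  missing_sig <- setdiff(names(PHYSIO_SIGNALS), cfg$signal_baselines$signal)
  if (length(missing_sig) > 0)
    bad(paste("signal_baselines lacks rows for:",
              paste(missing_sig, collapse = ", ")))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants x %d nights, p(migraine)=%.2f p(non-migraine)=%.2f\n",
              x$n_participants, x$nights_per_participant,
              x$p_migraine, x$p_nonmigraine))
  cat(sprintf("  effects: eda_peak %.2f uS @ %d min, prv %+.1f/%+.1f @ %d min, sleep %+d min\n",
              x$effect_eda_peak_amp, round(x$effect_eda_peak_time),
              x$effect_prv_early_drop, x$effect_prv_late_rise,
              round(x$effect_prv_changepoint), round(x$effect_sleep_shift)))
  cat(sprintf("  ar_coef %.2f, missing_rate %.2f, seed %d\n",
              x$ar_coef, x$missing_rate, x$seed))
  invisible(x)
}
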