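#' Simulate one participant's nights of minute-level wearable data
#'
#' Draws `nights_per_participant` nights for a single participant under the
#' generative model described in [sim_config()]: per-participant random
#' baselines for every signal, per-night random effects, AR(1) minute noise,
#' a state sequence (asleep / awake in bed / out of bed) built from drawn
#' time-in-bed and awake budgets, and i.i.d. next-day diary labels. Effect
#' knobs plant pre-headache signatures on the corresponding nights.
#' Output is deterministic given `(config, participant_id)`.
#'
#' @param config A [sim_config()] object.
#' @param participant_id Character or integer id for the participant.
#' @return A list with tibbles `minutes` (schema of [read_minutes()]) and
#'   `diary` (schema of [read_diary()]).
#' @export
simulate_participant <- function(config, participant_id) {
  config <- validate_sim_config(config)
  pid <- as.character(participant_id)
  withr::with_seed(derive_seed(config$seed, "participant", pid), {
    bl <- config$signal_baselines
    p_intercept <- setNames(rnorm(nrow(bl), 0, bl$sd_participant), bl$signal)

    labels <- sample(LABEL_LEVELS, config$nights_per_participant,
                     replace = TRUE,
                     prob = c(1 - config$p_migraine - config$p_nonmigraine,
                              config$p_nonmigraine, config$p_migraine))
    nights <- purrr::map(seq_len(config$nights_per_participant), function(i) {
      simulate_night_minutes(config, pid, i, labels[i], p_intercept)
    })
    minutes <- bind_rows(nights)
  })
  if (config$missing_rate > 0) {
    minutes <- inject_missingness(minutes, config$missing_rate,
                                  seed = derive_seed(config$seed, "missing", pid))
  }
  diary <- minutes %>%
    distinct(.data$participant_id, .data$night_index, .data$night_date) %>%
    mutate(label = labels[.data$night_index]) %>%
    select(participant_id = "participant_id", calendar_day = "night_date",
           label = "label")
  list(minutes = minutes, diary = diary)
}

# One night's minute records. The night "belongs" to the morning it ends on;
# night_date is that morning and equals the diary day carrying its label.
simulate_night_minutes <- function(config, pid, night_index, label,
                                   p_intercept) {
  tib_mu <- config$baseline_night_minutes[[1]]
  tib_sd <- config$baseline_night_minutes[[2]]
  awk_mu <- config$baseline_awake_minutes[[1]]
  awk_sd <- config$baseline_awake_minutes[[2]]

  tib <- round(rnorm(1, tib_mu, tib_sd))
  if (label != "none") tib <- tib + round(config$effect_sleep_shift)
  tib <- max(tib, 120)
  awake <- round(rnorm(1, awk_mu, awk_sd))
  awake <- min(max(awake, 10), floor(tib * 0.4))

  states <- build_state_sequence(tib, awake)
  n <- length(states)
  minute_index <- seq_len(n) - 1L

  onset <- match("asleep", states)
  t_sleep <- minute_index - minute_index[onset]

  bl <- config$signal_baselines
  sig <- function(name) {
    row <- bl[bl$signal == name, ]
    row$mean + p_intercept[[name]] + rnorm(1, 0, row$sd_night) +
      ar1_noise(n, row$sd_minute, config$ar_coef)
  }

  eda <- exp(sig("eda"))
  prv <- sig("prv")
  if (label == "migraine") {
    if (config$effect_eda_peak_amp != 0) {
      bump <- config$effect_eda_peak_amp *
        exp(-0.5 * ((t_sleep - config$effect_eda_peak_time) / 35)^2)
      eda <- eda + ifelse(t_sleep >= 0, bump, 0)
    }
    prv <- prv + case_when(
      t_sleep < 0 ~ 0,
      t_sleep < config$effect_prv_changepoint ~ config$effect_prv_early_drop,
      TRUE ~ config$effect_prv_late_rise
    )
  }

  tibble(
    participant_id = pid,
    night_index = as.integer(night_index),
    night_date = as.Date("2024-01-01") + night_index,
    minute_index = minute_index,
    eda_us = pmax(eda, 0),
    pulse_rate_bpm = pmax(sig("pulse_rate"), 30),
    prv = pmax(prv, 0),
    resp_rate_bpm = pmax(sig("resp_rate"), 4),
    temp_c = sig("temperature"),
    state = states,
    observed = TRUE
  )
}

# Assemble the per-minute state sequence: a sleep-latency block, the asleep
# core with 1-3 awake interruptions, a morning awake block, and 1-3 inserted
# out-of-bed excursions of 2-10 min (appended, so time in bed is preserved).
build_state_sequence <- function(tib, awake) {
  asleep <- tib - awake
  latency <- max(1L, round(awake * 0.3))
  morning <- max(1L, round(awake * 0.2))
  interrupt <- awake - latency - morning

  core <- rep("asleep", asleep)
  if (interrupt > 0) {
    k <- sample(1:3, 1)
    lens <- tabulate(sample(k, interrupt, replace = TRUE), nbins = k)
    for (len in lens[lens > 0]) {
      at <- sample(seq_len(length(core) - 1L)[-1], 1)
      core <- append(core, rep("awake_in_bed", len), after = at)
    }
  }
  states <- c(rep("awake_in_bed", latency), core, rep("awake_in_bed", morning))

  n_oob <- sample(1:3, 1)
  for (len in sample(2:10, n_oob, replace = TRUE)) {
    at <- sample(seq_along(states), 1)
    states <- append(states, rep("out_of_bed", len), after = at)
  }
  states
}

#' Simulate a whole cohort
#'
#' Applies [simulate_participant()] with per-participant derived seeds, so
#' participants are mutually independent and the whole cohort is reproducible
#' from `config$seed` alone.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `wearable_cohort` with tibbles `minutes` and
#'   `diary`; the config is attached as attribute `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 2,
#'                                      nights_per_participant = 6))
#' dplyr::count(cohort$diary, label)
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  parts <- purrr::map(ids, ~ simulate_participant(config, .x))
  out <- list(minutes = bind_rows(purrr::map(parts, "minutes")),
              diary = bind_rows(purrr::map(parts, "diary")))
  attr(out, "config") <- config
  class(out) <- "wearable_cohort"
  out
}

#' @export
print.wearable_cohort <- function(x, ...) {
  nn <- nrow(distinct(x$minutes, .data$participant_id, .data$night_index))
  cat(sprintf("<wearable_cohort> %d participants, %d nights, %d minute records\n",
              length(unique(x$minutes$participant_id)), nn, nrow(x$minutes)))
  print(count(x$diary, .data$label))
  invisible(x)
}

#' Drop minutes completely at random
#'
#' Flags approximately `rate` of the minute records as unobserved and blanks
#' their physiological values, independently of the night's next-day label
#' (missing completely at random). The record count is preserved.
#'
#' @param minutes A minutes tibble (one or many nights).
#' @param rate Fraction of minutes to drop, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The minutes tibble with `observed` flags updated and dropped
#'   rows' signal values set to `NA`.
#' @export
inject_missingness <- function(minutes, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    abort("rate must lie in [0, 1)", class = "nocturne_config_error")
  if (rate == 0) return(minutes)
  withr::with_seed(derive_seed(seed, "mcar"), {
    drop <- runif(nrow(minutes)) < rate
  })
  minutes %>%
    mutate(observed = .data$observed & !drop,
           across(all_of(unname(PHYSIO_SIGNALS)),
                  ~ if_else(drop, NA_real_, .x)))
}
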