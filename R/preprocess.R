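#' Remove out-of-bed minutes
#'
#' Drops minute records with `state == "out_of_bed"` (physiology recorded
#' while up and moving is confounded by physical activity). Asleep and
#' awake-in-bed minutes are retained. Nights left empty by the exclusion are
#' dropped entirely, with a message. The operation is idempotent.
#'
#' @param minutes Minutes tibble (optionally labeled).
#' @return The filtered minutes tibble.
#' @export
exclude_out_of_bed <- function(minutes) {
  kept <- minutes %>% filter(.data$state != "out_of_bed")
  before <- distinct(minutes, .data$participant_id, .data$night_index)
  after <- distinct(kept, .data$participant_id, .data$night_index)
  dropped <- nrow(before) - nrow(after)
  if (dropped > 0)
    inform(sprintf("exclude_out_of_bed: %d night(s) empty after exclusion, dropped",
                   dropped))
  kept
}

#' Nightly sleep metrics
#'
#' Counts minutes per state for each night: `time_in_bed` (asleep +
#' awake-in-bed), `time_asleep`, `time_awake_in_bed`, and `time_out_of_bed`,
#' all in minutes.
#'
#' @param minutes Minutes tibble (before out-of-bed exclusion, so the
#'   out-of-bed count is visible).
#' @return A tibble with one row per (participant, night).
#' @export
night_sleep_metrics <- function(minutes) {
  minutes %>%
    group_by(.data$participant_id, .data$night_index) %>%
    summarise(
      time_asleep = sum(.data$state == "asleep"),
      time_awake_in_bed = sum(.data$state == "awake_in_bed"),
      time_out_of_bed = sum(.data$state == "out_of_bed"),
      .groups = "drop"
    ) %>%
    mutate(time_in_bed = .data$time_asleep + .data$time_awake_in_bed) %>%
    select("participant_id", "night_index", "time_in_bed", "time_asleep",
           "time_awake_in_bed", "time_out_of_bed")
}

#' Nightly summary table for group-level comparison
#'
#' One row per labeled night: the three sleep-duration metrics plus the
#' nightly median of each physiological signal over observed in-bed minutes.
#' This is the input to [fit_group_lmm()].
#'
#' @param cohort A `cohort_table` from [attach_labels()], or a labeled
#'   minutes tibble.
#' @return A tibble with one row per night and one column per metric.
#' @export
nightly_metrics <- function(cohort) {
  minutes <- if (inherits(cohort, "cohort_table")) cohort$minutes else cohort
  assert_columns(minutes, c("label", "state"), "labeled minutes table")
  sleep <- night_sleep_metrics(minutes)
  med <- minutes %>%
    filter(.data$state != "out_of_bed", .data$observed) %>%
    group_by(.data$participant_id, .data$night_index, .data$label) %>%
    summarise(eda = median(.data$eda_us, na.rm = TRUE),
              pulse_rate = median(.data$pulse_rate_bpm, na.rm = TRUE),
              prv = median(.data$prv, na.rm = TRUE),
              resp_rate = median(.data$resp_rate_bpm, na.rm = TRUE),
              temperature = median(.data$temp_c, na.rm = TRUE),
              .groups = "drop")
  med %>% left_join(sleep, by = c("participant_id", "night_index"))
}

#' Test whether minute-level missingness is associated with next-day label
#'
#' Fits a mixed-effects logistic regression of the per-minute missingness
#' indicator on the night's next-day headache category, with a participant
#' random intercept (fit on the equivalent aggregated binomial form for
#' speed). The global label effect is assessed with a likelihood-ratio test;
#' a p-value at or above `alpha` is read as consistent with missingness
#' completely at random (MCAR).
#'
#' @param cohort A `cohort_table` or labeled minutes tibble with an
#'   `observed` flag.
#' @param alpha Significance level for the verdict.
#' @return A list of class `missingness_report`: per-signal missing
#'   fractions, the label-effect likelihood-ratio statistic and p-value,
#'   per-category coefficients with standard errors, and a `verdict` of
#'   `"MCAR-consistent"` or `"label-associated"`.
#' @export
missingness_association <- function(cohort, alpha = 0.05) {
  minutes <- if (inherits(cohort, "cohort_table")) cohort$minutes else cohort
  assert_columns(minutes, c("label", "observed"), "labeled minutes table")

  frac <- minutes %>%
    summarise(across(all_of(unname(PHYSIO_SIGNALS)), ~ mean(is.na(.x))))
  by_night <- minutes %>%
    group_by(.data$participant_id, .data$night_index, .data$label) %>%
    summarise(n_missing = sum(!.data$observed),
              n_obs = sum(.data$observed), .groups = "drop") %>%
    mutate(label = factor(.data$label, levels = LABEL_LEVELS))

  note <- NULL
  if (sum(by_night$n_missing) == 0) {
    return(structure(list(
      missing_fraction = frac, p_value = NA_real_, statistic = NA_real_,
      coefficients = NULL, verdict = "MCAR-consistent", alpha = alpha,
      note = "no missing minutes; nothing to test"),
      class = "missingness_report"))
  }

  fit_full <- suppressMessages(suppressWarnings(lme4::glmer(
    cbind(n_missing, n_obs) ~ label + (1 | participant_id),
    data = by_night, family = stats::binomial())))
  fit_null <- suppressMessages(suppressWarnings(lme4::glmer(
    cbind(n_missing, n_obs) ~ 1 + (1 | participant_id),
    data = by_night, family = stats::binomial())))
  lrt <- anova(fit_null, fit_full)
  p <- lrt$`Pr(>Chisq)`[2]
  stat <- lrt$Chisq[2]
  cf <- summary(fit_full)$coefficients
  coefs <- tibble(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                  p_value = cf[, 4])

  structure(list(
    missing_fraction = frac, p_value = p, statistic = stat,
    coefficients = coefs,
    verdict = if (is.na(p) || p >= alpha) "MCAR-consistent" else "label-associated",
    alpha = alpha, note = note),
    class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("<missingness_report>\n")
  cat("  per-signal missing fraction:\n")
  print(as.data.frame(x$missing_fraction), row.names = FALSE)
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.na(x$p_value))
    cat(sprintf("  label effect: LR chisq = %.2f, p = %.4f\n",
                x$statistic, x$p_value))
  cat(sprintf("  verdict (alpha = %.2f): %s\n", x$alpha, x$verdict))
  invisible(x)
}

#' @export
tidy.missingness_report <- function(x, ...) {
  if (is.null(x$coefficients)) return(tibble())
  x$coefficients
}
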