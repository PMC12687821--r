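INTERVAL_STATS <- c("median", "min", "max", "sd")

#' Names of the 36 interval feature columns
#'
#' Four summary statistics (median, min, max, sd) of nine per-night signals:
#' the five physiological signals plus the four night-level sleep metrics.
#' @return Character vector of column names, e.g. `eda_max`, `prv_min`.
#' @export
feature_names <- function() {
  signals <- c(names(PHYSIO_SIGNALS), SLEEP_METRICS)
  as.vector(t(outer(signals, INTERVAL_STATS, paste, sep = "_")))
}

feature_columns <- function(df) intersect(feature_names(), names(df))

#' Convert nights into 5-minute interval feature rows
#'
#' Partitions each night's retained minutes (after out-of-bed exclusion)
#' into consecutive non-overlapping 5-minute windows, anchored at the first
#' retained minute; gaps from excluded minutes close up. Per window and
#' physiological signal the median, min, max and sample standard deviation
#' are computed over observed minutes; a window (or signal within a window)
#' with fewer than 3 usable minutes yields `NA` stats, left for
#' [impute_mice()]. A trailing window of 1--2 minutes is dropped. The four
#' night-level sleep metrics are attached to every row of the night as
#' constants (their `median`/`min`/`max` equal the value and `sd` is 0).
#' Nights with fewer than 5 retained minutes produce no rows, with a
#' message.
#'
#' @param minutes Minutes tibble after [exclude_out_of_bed()]; may carry a
#'   `label` column, which passes through untouched.
#' @param sleep_metrics Optional tibble from [night_sleep_metrics()] computed
#'   on the *unexcluded* minutes (so `time_out_of_bed` is visible). If
#'   `NULL` it is computed from `minutes`, where out-of-bed time is 0.
#' @return A tibble with one row per interval: ids, `interval_index`, the 36
#'   feature columns of [feature_names()], and `label` if present.
#' @export
interval_features <- function(minutes, sleep_metrics = NULL) {
  if (is.null(sleep_metrics)) sleep_metrics <- night_sleep_metrics(minutes)
  has_label <- "label" %in% names(minutes)

  wstat <- function(v, f) {
    v <- v[!is.na(v)]
    if (length(v) < 3) NA_real_ else f(v)
  }
  prepped <- minutes %>%
    arrange(.data$participant_id, .data$night_index, .data$minute_index) %>%
    group_by(.data$participant_id, .data$night_index) %>%
    mutate(.win = (row_number() - 1L) %/% 5L,
           .m = n(),
           .keep_night = .data$.m >= 5,
           # trailing window of 1-2 retained minutes is dropped
           .tail = .data$.m - 5L * max(.data$.win),
           .keep_row = .data$.win < max(.data$.win) | .data$.tail >= 3 |
             max(.data$.win) == 0) %>%
    ungroup()
  n_nights <- nrow(distinct(prepped, .data$participant_id, .data$night_index))

  # values are NA when unobserved, so !is.na is the usable-minute mask
  rows <- prepped %>%
    filter(.data$.keep_night, .data$.keep_row) %>%
    group_by(.data$participant_id, .data$night_index, .data$.win) %>%
    summarise(
      eda_median = wstat(.data$eda_us, median),
      eda_min = wstat(.data$eda_us, min),
      eda_max = wstat(.data$eda_us, max),
      eda_sd = wstat(.data$eda_us, sd),
      pulse_rate_median = wstat(.data$pulse_rate_bpm, median),
      pulse_rate_min = wstat(.data$pulse_rate_bpm, min),
      pulse_rate_max = wstat(.data$pulse_rate_bpm, max),
      pulse_rate_sd = wstat(.data$pulse_rate_bpm, sd),
      prv_median = wstat(.data$prv, median),
      prv_min = wstat(.data$prv, min),
      prv_max = wstat(.data$prv, max),
      prv_sd = wstat(.data$prv, sd),
      resp_rate_median = wstat(.data$resp_rate_bpm, median),
      resp_rate_min = wstat(.data$resp_rate_bpm, min),
      resp_rate_max = wstat(.data$resp_rate_bpm, max),
      resp_rate_sd = wstat(.data$resp_rate_bpm, sd),
      temperature_median = wstat(.data$temp_c, median),
      temperature_min = wstat(.data$temp_c, min),
      temperature_max = wstat(.data$temp_c, max),
      temperature_sd = wstat(.data$temp_c, sd),
      label = if (has_label) first(.data$label) else NA_character_,
      .groups = "drop_last"
    ) %>%
    mutate(interval_index = row_number()) %>%
    ungroup() %>%
    select(-".win")
  if (!has_label) rows$label <- NULL

  if (nrow(rows) == 0) {
    inform("interval_features: no night had >= 5 retained minutes")
    return(rows)
  }
  dropped <- n_nights - nrow(distinct(rows, .data$participant_id, .data$night_index))
  if (dropped > 0)
    inform(sprintf("interval_features: %d night(s) with < 5 retained minutes dropped",
                   dropped))

  rows <- rows %>%
    left_join(sleep_metrics, by = c("participant_id", "night_index"))
  for (sm in SLEEP_METRICS) {
    rows[[paste0(sm, "_median")]] <- rows[[sm]]
    rows[[paste0(sm, "_min")]] <- rows[[sm]]
    rows[[paste0(sm, "_max")]] <- rows[[sm]]
    rows[[paste0(sm, "_sd")]] <- 0
  }
  rows <- rows %>% select(-all_of(SLEEP_METRICS))
  keep <- c("participant_id", "night_index", "interval_index",
            feature_names(), if (has_label) "label")
  rows[keep]
}

#' Center-and-scale transform fit on training rows only
#'
#' `fit_scaler()` records per-feature means and standard deviations from the
#' supplied (training) rows; `apply_scaler()` standardises any rows with
#' them. Zero-variance features map to 0 rather than dividing by zero.
#' Fitting inside each training fold (never globally) is what keeps held-out
#' nights from leaking into the transform.
#'
#' @param rows Interval feature tibble (training rows for `fit_scaler`).
#' @return `fit_scaler()`: an object of class `feature_scaler`;
#'   `apply_scaler()`: the rows with feature columns standardised.
#' @export
fit_scaler <- function(rows) {
  feats <- feature_columns(rows)
  if (nrow(rows) == 0) abort("fit_scaler: no training rows")
  x <- as.matrix(rows[feats])
  structure(list(mean = colMeans(x, na.rm = TRUE),
                 sd = apply(x, 2, sd, na.rm = TRUE),
                 features = feats),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler`.
#' @export
apply_scaler <- function(scaler, rows) {
  stopifnot(inherits(scaler, "feature_scaler"))
  for (f in scaler$features) {
    s <- scaler$sd[[f]]
    if (is.na(s) || s == 0) {
      rows[[f]] <- 0
    } else {
      rows[[f]] <- (rows[[f]] - scaler$mean[[f]]) / s
    }
  }
  rows
}
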