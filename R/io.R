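MINUTES_COLS <- c("participant_id", "night_index", "night_date",
                  "minute_index", "eda_us", "pulse_rate_bpm", "prv",
                  "resp_rate_bpm", "temp_c", "state", "observed")
DIARY_COLS <- c("participant_id", "calendar_day", "label")

#' Normalize a headache diary label
#'
#' Maps common spellings (case-insensitive, spaces/hyphens interchangeable
#' with underscores) onto the canonical categories `none`, `non_migraine`,
#' `migraine`. The accepted synonyms are: `none`, `no_headache`,
#' `headache_free` -> `none`; `non_migraine`, `nonmigraine`,
#' `non_migraine_headache`, `headache` -> `non_migraine`; `migraine` ->
#' `migraine`.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels.
#' @export
normalize_label <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  map <- c(none = "none", no_headache = "none", headache_free = "none",
           non_migraine = "non_migraine", nonmigraine = "non_migraine",
           non_migraine_headache = "non_migraine", headache = "non_migraine",
           migraine = "migraine")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf("unparseable label(s): %s; allowed values (any case): %s",
                  paste(bad, collapse = ", "),
                  paste(names(map), collapse = ", ")),
          class = "nocturne_label_error")
  }
  out
}

read_checked <- function(path, mandatory, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, mandatory, what)
  extra <- setdiff(names(df), mandatory)
  if (length(extra) > 0) {
    warn(sprintf("%s: ignoring unknown column(s): %s", what,
                 paste(extra, collapse = ", ")))
    df <- df[mandatory]
  }
  df
}

#' Read / write minute-record and diary tables
#'
#' CSV round-trip for the two on-disk tables. `minutes.csv` holds 1-minute
#' aggregated records keyed by `(participant_id, night_index, minute_index)`
#' with columns `night_date` (ISO-8601, the morning the night ends on),
#' `eda_us`, `pulse_rate_bpm`, `prv`, `resp_rate_bpm`, `temp_c`, `state`
#' (`asleep` / `awake_in_bed` / `out_of_bed`) and logical `observed`.
#' `diary.csv` holds one row per participant-day with a headache `label`,
#' normalized via [normalize_label()]. Unknown columns are dropped with a
#' warning; a missing mandatory column raises a schema error naming it.
#'
#' @param path File path.
#' @return A typed tibble.
#' @name wearable_io
NULL

#' @rdname wearable_io
#' @export
read_minutes <- function(path) {
  df <- read_checked(path, MINUTES_COLS, what = "minutes table")
  df %>%
    mutate(participant_id = as.character(.data$participant_id),
           night_index = as.integer(.data$night_index),
           night_date = as.Date(.data$night_date),
           minute_index = as.integer(.data$minute_index),
           across(all_of(unname(PHYSIO_SIGNALS)), as.numeric),
           state = as.character(.data$state),
           observed = as.logical(.data$observed)) %>%
    check_states() %>%
    arrange(.data$participant_id, .data$night_index, .data$minute_index)
}

check_states <- function(df) {
  ok <- c("asleep", "awake_in_bed", "out_of_bed")
  bad <- setdiff(unique(df$state), ok)
  if (length(bad) > 0)
    abort(sprintf("unknown state value(s): %s; allowed: %s",
                  paste(bad, collapse = ", "), paste(ok, collapse = ", ")),
          class = "nocturne_schema_error")
  df
}

#' @rdname wearable_io
#' @export
read_diary <- function(path) {
  df <- read_checked(path, DIARY_COLS, what = "diary table")
  df <- df %>%
    mutate(participant_id = as.character(.data$participant_id),
           calendar_day = as.Date(.data$calendar_day),
           label = normalize_label(.data$label))
  dup <- df %>% count(.data$participant_id, .data$calendar_day) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(sprintf("duplicate diary entries for %d participant-day(s), e.g. %s %s",
                  nrow(dup), dup$participant_id[1], dup$calendar_day[1]),
          class = "nocturne_schema_error")
  df
}

#' @rdname wearable_io
#' @param minutes,diary Tibbles in the respective schemas.
#' @export
write_minutes <- function(minutes, path) {
  assert_columns(minutes, MINUTES_COLS, "minutes table")
  readr::write_csv(minutes[MINUTES_COLS], path, progress = FALSE)
  invisible(path)
}

#' @rdname wearable_io
#' @export
write_diary <- function(diary, path) {
  assert_columns(diary, DIARY_COLS, "diary table")
  readr::write_csv(diary[DIARY_COLS], path, progress = FALSE)
  invisible(path)
}

#' Attach next-day diary labels to nights
#'
#' Joins each night to the diary entry of the day the participant wakes into:
#' a night is identified with the morning it ends on (`night_date`), and its
#' label is the diary entry whose `calendar_day` equals that date. Nights
#' without a matching diary day are excluded and counted; duplicate diary
#' entries for one day are an error (caught in [read_diary()] for files, and
#' re-checked here).
#'
#' @param minutes Minutes tibble.
#' @param diary Diary tibble with canonical labels.
#' @return A list of class `cohort_table`: `minutes` (labeled, with a
#'   `label` column), `nights` (one row per labeled night), and
#'   `n_unlabeled` (count of excluded nights).
#' @export
attach_labels <- function(minutes, diary) {
  assert_columns(minutes, c("participant_id", "night_index", "night_date"),
                 "minutes table")
  assert_columns(diary, DIARY_COLS, "diary table")
  dup <- diary %>% count(.data$participant_id, .data$calendar_day) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort("duplicate diary entries for one participant-day",
          class = "nocturne_schema_error")

  nights <- minutes %>%
    distinct(.data$participant_id, .data$night_index, .data$night_date) %>%
    left_join(diary, by = c("participant_id", "night_date" = "calendar_day"))
  n_unlabeled <- sum(is.na(nights$label))
  if (n_unlabeled > 0)
    inform(sprintf("attach_labels: %d night(s) without a next-day diary entry excluded",
                   n_unlabeled))
  nights <- nights %>% filter(!is.na(.data$label))
  labeled <- minutes %>%
    dplyr::inner_join(nights %>% select("participant_id", "night_index", "label"),
                      by = c("participant_id", "night_index"))
  structure(list(minutes = labeled, nights = nights,
                 n_unlabeled = n_unlabeled),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d labeled nights (%d unlabeled excluded)\n",
              nrow(x$nights), x$n_unlabeled))
  print(count(x$nights, .data$label))
  invisible(x)
}
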