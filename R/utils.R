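#' Allowed diary labels
#'
#' Next-day diary categories, in severity order.
#' @keywords internal
LABEL_LEVELS <- c("none", "non_migraine", "migraine")

#' Physiological signal column names used across the package
#' @keywords internal
PHYSIO_SIGNALS <- c(eda = "eda_us", pulse_rate = "pulse_rate_bpm",
                    prv = "prv", resp_rate = "resp_rate_bpm",
                    temperature = "temp_c")

#' Sleep-metric names (night-level constants)
#' @keywords internal
SLEEP_METRICS <- c("time_in_bed", "time_asleep", "time_awake_in_bed",
                   "time_out_of_bed")

# Stable 32-bit seed derivation: combines an integer base seed with any
# number of scalar components (ids, fold indices). Uses a small multiplicative
# hash over UTF-8 bytes so identical inputs give identical seeds on any
# platform; result is kept in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste0(as.character(x), collapse = "|"),
                  character(1))
  key <- paste(c(as.character(seed), parts), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629)
}

# AR(1) stationary Gaussian noise of length n with marginal sd `sd` and
# lag-1 coefficient `phi` in [0, 1).
ar1_noise <- function(n, sd, phi) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(0, n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "nocturne_schema_error")
  }
  invisible(df)
}
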