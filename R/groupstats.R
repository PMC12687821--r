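#' Group-level mixed-model comparison of nightly metrics
#'
#' For each nightly metric, fits a linear mixed model with a fixed next-day
#' label effect (three categories) and a participant random intercept, and
#' tests the global 2-df label effect with a likelihood-ratio test against
#' the intercept-only model (both fit by maximum likelihood). P-values are
#' Holm-corrected across the metrics tested. With a single participant the
#' random intercept is dropped and a fixed-effects fit is used.
#'
#' @param nightly_table Tibble from [nightly_metrics()].
#' @param metrics Character vector of metric columns to test; default all
#'   eight nightly metrics.
#' @param alpha Significance level used when printing verdicts.
#' @return An object of class `group_lmm`: a `results` tibble with one row
#'   per metric (LR statistic, raw and Holm-corrected p, per-category means),
#'   a `summary` tibble of per-category median `[IQR]` strings, and the
#'   per-category night counts.
#' @export
fit_group_lmm <- function(nightly_table,
                          metrics = c("time_in_bed", "time_asleep",
                                      "time_awake_in_bed", "eda",
                                      "pulse_rate", "temperature", "prv",
                                      "resp_rate"),
                          alpha = 0.05) {
  assert_columns(nightly_table, c("participant_id", "label", metrics),
                 "nightly table")
  present <- intersect(LABEL_LEVELS, unique(nightly_table$label))
  if (length(present) < 2)
    abort("fit_group_lmm needs at least 2 label categories present")
  if (length(present) < 3)
    warn(sprintf("label category absent cohort-wide: %s; fitting on the rest",
                 paste(setdiff(LABEL_LEVELS, present), collapse = ", ")))
  df <- nightly_table %>%
    mutate(label = factor(.data$label, levels = present))
  multi <- length(unique(df$participant_id)) > 1

  res <- purrr::map_dfr(metrics, function(m) {
    d <- df[!is.na(df[[m]]), ]
    if (multi) {
      full <- suppressMessages(lme4::lmer(
        as.formula(paste(m, "~ label + (1 | participant_id)")),
        data = d, REML = FALSE))
      null <- suppressMessages(lme4::lmer(
        as.formula(paste(m, "~ 1 + (1 | participant_id)")),
        data = d, REML = FALSE))
      a <- anova(null, full)
      stat <- a$Chisq[2]; p <- a$`Pr(>Chisq)`[2]
      fe <- lme4::fixef(full)
    } else {
      full <- lm(as.formula(paste(m, "~ label")), data = d)
      null <- lm(as.formula(paste(m, "~ 1")), data = d)
      a <- anova(null, full, test = "LRT")
      stat <- NA_real_; p <- a$`Pr(>Chi)`[2]
      fe <- coef(full)
    }
    means <- fe[1] + c(0, fe[-1])
    names(means) <- paste0("mean_", present)
    bind_cols(tibble(metric = m, statistic = stat, p_value = p),
              as_tibble(as.list(means)))
  })
  res$p_adj <- p.adjust(res$p_value, method = "holm")

  summ <- df %>%
    tidyr::pivot_longer(all_of(metrics), names_to = "metric") %>%
    group_by(.data$metric, .data$label) %>%
    summarise(cell = sprintf("%.1f [%.1f, %.1f]",
                             median(.data$value, na.rm = TRUE),
                             quantile(.data$value, 0.25, na.rm = TRUE),
                             quantile(.data$value, 0.75, na.rm = TRUE)),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "label", values_from = "cell")

  structure(list(results = res, summary = summ,
                 n_per_category = table(df$label), alpha = alpha),
            class = "group_lmm")
}

#' @export
print.group_lmm <- function(x, ...) {
  cat("<group_lmm> nights per category:",
      paste(names(x$n_per_category), x$n_per_category, sep = "=",
            collapse = ", "), "\n")
  print(as.data.frame(x$results[c("metric", "statistic", "p_value", "p_adj")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.group_lmm <- function(x, ...) x$results

#' @export
glance.group_lmm <- function(x, ...) {
  tibble(n_metrics = nrow(x$results),
         n_significant = sum(x$results$p_adj < x$alpha, na.rm = TRUE),
         min_p_adj = min(x$results$p_adj, na.rm = TRUE))
}

#' Percent difference between two positive means
#'
#' `100 * (mean_a - mean_b) / mean_b`: how much higher (in percent) the
#' first mean is than the second.
#'
#' @param mean_a,mean_b Means; `mean_b` must be positive.
#' @return The percent difference.
#' @examples
#' percent_difference(1.13, 0.75)  # ~50.7
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_b <= 0)) abort("mean_b must be positive")
  100 * (mean_a - mean_b) / mean_b
}
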