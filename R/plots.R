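#' Plot nightly predicted probabilities for one participant
#'
#' Scatter of nightly risk with 95% bands, coloured by the true next-day
#' status, for each learner.
#'
#' @param object A `participant_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.participant_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$night_index, y = .data$p_hat,
                               colour = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             fatten = 2) +
    ggplot2::facet_wrap(~learner) +
    ggplot2::labs(x = "night", y = "predicted next-day risk",
                  colour = "next-day status",
                  title = sprintf("Participant %s - %s",
                                  object$participant_id,
                                  object$outcome$name)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot SHAP attributions
#'
#' One jittered row of points per retained feature, positioned by
#' attribution and coloured by the normalized feature value (0--1), in the
#' style of a SHAP beeswarm.
#'
#' @param object A `shap_summary`.
#' @param max_features Show at most this many features (by ranking score).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shap_summary <- function(object, max_features = 10, ...) {
  keep <- head(object$ranking$feature[object$ranking$retained], max_features)
  if (length(keep) == 0) keep <- head(object$ranking$feature, max_features)
  df <- object$attributions %>%
    filter(.data$feature %in% keep) %>%
    mutate(feature = factor(.data$feature, levels = rev(keep)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$feature,
                                   colour = .data$value_scaled)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_viridis_c(name = "feature value\n(scaled 0-1)") +
    ggplot2::labs(x = "phi (log-odds attribution)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot temporal GAM curves
#'
#' Per-group smooth means with 95% confidence ribbons over minutes since
#' sleep onset.
#'
#' @param object A `gam_curves`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gam_curves <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$minute, y = .data$estimate,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "minutes since sleep onset", y = object$signal,
                  colour = "next-day status", fill = "next-day status") +
    ggplot2::theme_minimal()
}

#' Tile map of next-day status by participant and night
#'
#' @param object A `wearable_cohort` or diary tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wearable_cohort <- function(object, ...) {
  diary <- object$diary %>%
    group_by(.data$participant_id) %>%
    mutate(night = rank(.data$calendar_day)) %>%
    ungroup()
  ggplot2::ggplot(diary, ggplot2::aes(x = .data$night,
                                      y = .data$participant_id,
                                      fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "night", y = NULL, fill = "next-day status") +
    ggplot2::theme_minimal()
}
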