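#' SHAP feature attributions for a fitted personalized model
#'
#' Computes exact additive attributions of each interval-row prediction on
#' the link (log-odds) scale: coefficient-times-centered-value for the
#' elastic net, and exact TreeSHAP for the tree learners. Per row and
#' feature, `phi` is the shift the feature contributes relative to the
#' model's base value, so `base + sum(phi)` reproduces the model output
#' (local accuracy). Features whose attributions never reach `filter` in
#' absolute value are filtered from the retained set; the per-feature
#' direction is the sign of the correlation between feature value and
#' `phi`.
#'
#' @param model A `nocturne_model` from [fit_final()].
#' @param interval_rows Interval feature rows on the model's feature space.
#' @param filter Retention threshold on attribution magnitude.
#' @param rank_by `"max"` (default) retains/ranks features by the maximum
#'   absolute per-row attribution; `"mean"` by the mean absolute
#'   attribution.
#' @return An object of class `shap_summary`: long `attributions` tibble
#'   (`row`, `feature`, `phi`, `value_scaled` min-max normalized to
#'   `[0, 1]`), a per-feature `ranking` tibble with the retained flag and
#'   direction, the `base_value`, and per-row model `margin`s.
#' @export
shap_summary <- function(model, interval_rows, filter = 0.25,
                         rank_by = c("max", "mean")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(model, "nocturne_model"))
  missing_cols <- setdiff(model$features, names(interval_rows))
  if (length(missing_cols) > 0)
    abort(sprintf("interval rows lack model feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))

  xs <- interval_matrix(apply_scaler(model$scaler, interval_rows))
  xs <- xs[, model$features, drop = FALSE]
  if (model$learner == "elastic_net") {
    b <- as.numeric(coef(model$model$fit, s = model$params$lambda))
    names(b) <- c("(Intercept)", colnames(xs))
    xbar <- model$train_col_means[colnames(xs)]
    phi <- sweep(xs, 2, xbar) %*% diag(b[-1], nrow = ncol(xs))
    colnames(phi) <- colnames(xs)
    base <- b[1] + sum(b[-1] * xbar)
  } else {
    contrib <- predict(model$model$fit,
                       xgboost::xgb.DMatrix(xs, nthread = 1),
                       predcontrib = TRUE)
    # last column is the bias/base-value term
    bias_col <- ncol(contrib)
    base <- contrib[1, bias_col]
    phi <- contrib[, -bias_col, drop = FALSE]
    colnames(phi) <- colnames(xs)
  }
  margin <- base + rowSums(phi)

  raw <- as.matrix(interval_rows[model$features])
  rng <- apply(raw, 2, function(v) diff(range(v, na.rm = TRUE)))
  value_scaled <- sweep(raw, 2, apply(raw, 2, min, na.rm = TRUE))
  value_scaled <- sweep(value_scaled, 2, ifelse(rng == 0, 1, rng), "/")

  attributions <- tibble(
    row = rep(seq_len(nrow(xs)), times = ncol(xs)),
    feature = rep(colnames(xs), each = nrow(xs)),
    phi = as.numeric(phi),
    value_scaled = as.numeric(value_scaled)
  )
  ranking <- attributions %>%
    group_by(.data$feature) %>%
    summarise(max_abs_phi = max(abs(.data$phi)),
              mean_abs_phi = mean(abs(.data$phi)),
              direction = sign(suppressWarnings(
                cor(.data$value_scaled, .data$phi)) %||% NA_real_),
              .groups = "drop") %>%
    mutate(direction = if_else(is.na(.data$direction), 0, .data$direction),
           score = if (rank_by == "max") .data$max_abs_phi else .data$mean_abs_phi,
           retained = .data$score >= filter) %>%
    arrange(dplyr::desc(.data$score))

  structure(list(attributions = attributions, ranking = ranking,
                 base_value = unname(base), margin = margin,
                 filter = filter, rank_by = rank_by,
                 learner = model$learner),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat(sprintf("<shap_summary> %s, %d/%d features retained at |phi| >= %.2f (%s)\n",
              x$learner, sum(x$ranking$retained), nrow(x$ranking),
              x$filter, x$rank_by))
  print(as.data.frame(head(x$ranking, 8)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.shap_summary <- function(x, ...) x$ranking

signal_column <- function(signal) {
  if (!signal %in% names(PHYSIO_SIGNALS))
    abort(sprintf("unknown signal '%s'; available: %s", signal,
                  paste(names(PHYSIO_SIGNALS), collapse = ", ")))
  PHYSIO_SIGNALS[[signal]]
}

#' Smooth temporal contrast of a nocturnal signal across outcome groups
#'
#' Fits, per next-day outcome group, a generalized additive model of the
#' minute-level signal on minutes since sleep onset (cubic regression
#' spline, basis dimension `k`, smoothness chosen by GCV) over the first
#' `horizon` minutes of sleep, and evaluates mean and pointwise 95%
#' confidence band on a common 1-minute grid. Sleep onset is the night's
#' first asleep-state minute; out-of-bed and unobserved minutes are
#' excluded. Groups with fewer than `min_nights` nights are skipped with a
#' message.
#'
#' @param minutes Labeled minutes tibble (e.g. `attach_labels()$minutes`).
#' @param signal `"prv"` or `"eda"` (any physiological signal name works).
#' @param horizon Minutes of sleep analysed (default 420).
#' @param k Spline basis dimension.
#' @param min_nights Minimum nights per group.
#' @return An object of class `gam_curves`: a `curves` tibble (`group`,
#'   `minute`, `estimate`, `ci_lo`, `ci_hi`), pairwise `contrasts` between
#'   groups with the location of the largest positive difference, and the
#'   per-group `edf` of the smooths.
#' @export
fit_temporal_gam <- function(minutes, signal = c("prv", "eda"),
                             horizon = 420, k = 20, min_nights = 3) {
  signal <- match.arg(signal, choices = names(PHYSIO_SIGNALS))
  col <- signal_column(signal)
  assert_columns(minutes, c("label", "state", "minute_index", col),
                 "labeled minutes table")

  dat <- minutes %>%
    group_by(.data$participant_id, .data$night_index) %>%
    mutate(t_sleep = .data$minute_index -
             .data$minute_index[match("asleep", .data$state)]) %>%
    ungroup() %>%
    filter(!is.na(.data$t_sleep), .data$t_sleep >= 0,
           .data$t_sleep <= horizon,
           .data$state != "out_of_bed", .data$observed,
           !is.na(.data[[col]]))

  counts <- dat %>%
    distinct(.data$participant_id, .data$night_index, .data$label) %>%
    count(.data$label)
  keep <- intersect(LABEL_LEVELS, counts$label[counts$n >= min_nights])
  skipped <- setdiff(counts$label, keep)
  if (length(skipped) > 0)
    inform(sprintf("fit_temporal_gam: group(s) with < %d nights skipped: %s",
                   min_nights, paste(skipped, collapse = ", ")))
  if (length(keep) < 2)
    abort("fit_temporal_gam needs >= 2 outcome groups with enough nights")

  # night-level random intercept so the confidence band reflects
  # night-to-night variation, not just minute noise (minutes within a night
  # are far from independent)
  form <- as.formula(sprintf(
    "y ~ s(t_sleep, bs = 'cr', k = %d) + s(night_f, bs = 're')", k))
  fits <- list()
  curves <- purrr::map_dfr(keep, function(g) {
    d <- dat[dat$label == g, ]
    dd <- data.frame(y = d[[col]], t_sleep = d$t_sleep,
                     night_f = factor(interpaste(d$participant_id,
                                                 d$night_index)))
    fit <- mgcv::gam(form, data = dd, method = "GCV.Cp")
    fits[[g]] <<- fit
    grid <- data.frame(t_sleep = seq(0, horizon, by = 1),
                       night_f = dd$night_f[1])
    pr <- predict(fit, newdata = grid, se.fit = TRUE,
                  exclude = "s(night_f)", newdata.guaranteed = TRUE)
    tibble(group = g, minute = grid$t_sleep, estimate = as.numeric(pr$fit),
           ci_lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
           ci_hi = as.numeric(pr$fit + 1.96 * pr$se.fit))
  })

  combos <- utils::combn(keep, 2, simplify = FALSE)
  contrasts <- purrr::map_dfr(combos, function(pr) {
    a <- curves[curves$group == pr[2], ]; b <- curves[curves$group == pr[1], ]
    diff <- a$estimate - b$estimate
    tibble(group_a = pr[2], group_b = pr[1],
           peak_minute = a$minute[which.max(diff)],
           peak_difference = max(diff))
  })

  structure(list(signal = signal, curves = curves, contrasts = contrasts,
                 edf = vapply(fits, function(f) sum(f$edf) - 1, numeric(1)),
                 fits = fits, horizon = horizon, k = k),
            class = "gam_curves")
}

#' @export
print.gam_curves <- function(x, ...) {
  cat(sprintf("<gam_curves> %s over first %d min of sleep; groups: %s\n",
              x$signal, x$horizon,
              paste(unique(x$curves$group), collapse = ", ")))
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.gam_curves <- function(x, ...) x$curves
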