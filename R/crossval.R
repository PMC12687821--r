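#' Outcome definitions
#'
#' Two binary outcomes are modeled: `migraine_vs_rest` (positive nights are
#' those preceding a migraine day) and `headache_vs_none` (positives precede
#' any headache day, migraine or not).
#'
#' @param name One of `"migraine_vs_rest"`, `"headache_vs_none"`.
#' @return A list of class `outcome_def` with `name` and `positives`.
#' @export
outcome_def <- function(name = c("migraine_vs_rest", "headache_vs_none")) {
  name <- match.arg(name)
  positives <- switch(name,
                      migraine_vs_rest = "migraine",
                      headache_vs_none = c("migraine", "non_migraine"))
  structure(list(name = name, positives = positives), class = "outcome_def")
}

is_positive <- function(label, outcome) label %in% outcome$positives

#' Participant eligibility for an outcome
#'
#' A participant enters the nested cross-validation for an outcome only with
#' at least 2 positive and 2 negative nights, so that every outer training
#' fold still contains at least one night of each class for inner pairing.
#'
#' @param nights Tibble with `participant_id`, `night_index`, `label`.
#' @param outcome An [outcome_def()].
#' @return A tibble per participant: positive/negative night counts, an
#'   `eligible` flag and a `reason` for exclusion (`NA` when eligible).
#' @export
eligible <- function(nights, outcome) {
  nights %>%
    group_by(.data$participant_id) %>%
    summarise(n_pos = sum(is_positive(.data$label, outcome)),
              n_neg = sum(!is_positive(.data$label, outcome)),
              .groups = "drop") %>%
    mutate(eligible = .data$n_pos >= 2 & .data$n_neg >= 2,
           reason = case_when(
             .data$eligible ~ NA_character_,
             .data$n_pos < 2 ~ sprintf("only %d positive night(s)", .data$n_pos),
             TRUE ~ sprintf("only %d negative night(s)", .data$n_neg)),
           outcome = outcome$name)
}

#' Enumerate leave-one-night-out outer folds
#'
#' One fold per night: that night is the held-out test set and every other
#' night is available for training and tuning.
#'
#' @param night_ids Vector of night identifiers.
#' @return A tibble with `test_night` and a list-column `training` of the
#'   remaining night ids.
#' @export
enumerate_l1no <- function(night_ids) {
  night_ids <- unique(night_ids)
  tibble(test_night = night_ids,
         training = purrr::map(night_ids, ~ setdiff(night_ids, .x)))
}

#' Enumerate leave-two-nights-out validation pairs
#'
#' All (positive night, negative night) combinations among the training
#' nights; when the full product exceeds `cap`, `cap` pairs are sampled
#' uniformly without replacement (deterministic under `seed`).
#'
#' @param nights Tibble with `night_index` and `label` for the training
#'   nights of one participant.
#' @param outcome An [outcome_def()].
#' @param cap Maximum number of pairs.
#' @param seed Integer seed for the subsample.
#' @return A tibble with `pos_night` and `neg_night`.
#' @export
enumerate_l2no <- function(nights, outcome, cap = 200, seed = 1L) {
  pos <- nights$night_index[is_positive(nights$label, outcome)]
  neg <- nights$night_index[!is_positive(nights$label, outcome)]
  if (length(pos) == 0 || length(neg) == 0)
    abort("enumerate_l2no: training nights must include both classes",
          class = "nocturne_fold_error")
  pairs <- tidyr::expand_grid(pos_night = pos, neg_night = neg)
  if (nrow(pairs) > cap) {
    keep <- withr::with_seed(derive_seed(seed, "l2no"),
                             sample.int(nrow(pairs), cap))
    pairs <- pairs[sort(keep), ]
  }
  pairs
}

interval_matrix <- function(rows) {
  as.matrix(rows[feature_columns(rows)])
}

# matrix-space center/scale with the zero-variance -> 0 convention of
# apply_scaler()
scale_mat <- function(X, mu, sdv) {
  degenerate <- !is.finite(sdv) | sdv == 0
  s <- ifelse(degenerate, 1, sdv)
  out <- sweep(sweep(X, 2, mu), 2, s, "/")
  if (any(degenerate)) out[, degenerate] <- 0
  out
}

night_mean_prob <- function(model, x, nights_vec, ids) {
  p <- predict_prob(model, x)
  vapply(ids, function(nid) mean(p[nights_vec == nid]), numeric(1))
}

#' Tune a learner with paired leave-two-nights-out validation
#'
#' For every hyperparameter setting and every validation pair, the learner
#' is fit on the remaining training nights (with the center/scale transform
#' refit on those nights only) and the two held-out nights' probabilities
#' are aggregated to nightly means. A setting scores the fraction of pairs
#' in which the positive night receives the higher nightly probability
#' (ties count 1/2). The best-scoring setting wins; ties go to the least
#' complex setting, i.e. the earliest row of the grid (see
#' [default_grids()]).
#'
#' @param intervals Interval feature rows of the training nights (one
#'   participant, labeled).
#' @param outcome An [outcome_def()].
#' @param learner One of `"elastic_net"`, `"random_forest"`, `"gbm"`.
#' @param grid Tibble of hyperparameter settings, least complex first.
#' @param pair_cap Maximum number of validation pairs (see
#'   [enumerate_l2no()]).
#' @param seed Integer seed.
#' @return A list: `params` (winning row as a list), `score`, and the
#'   per-setting `scores` tibble.
#' @export
tune_learner <- function(intervals, outcome, learner, grid, pair_cap = 200,
                         seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0)
    abort("tune_learner: empty hyperparameter grid")
  if (nrow(grid) == 1)   # a single setting wins unconditionally
    return(list(params = as.list(grid[1, ]), score = NA_real_,
                scores = mutate(grid, score = NA_real_)))
  nights <- distinct(intervals, .data$night_index, .data$label)
  pairs <- enumerate_l2no(nights, outcome, cap = pair_cap, seed = seed)

  X <- interval_matrix(intervals)
  night_vec <- intervals$night_index
  y_all <- as.integer(is_positive(intervals$label, outcome))

  score_mat <- matrix(NA_real_, nrow = nrow(pairs), ncol = nrow(grid))
  for (i in seq_len(nrow(pairs))) {
    hold <- c(pairs$pos_night[i], pairs$neg_night[i])
    in_valid <- night_vec %in% hold
    mu <- colMeans(X[!in_valid, , drop = FALSE])
    sdv <- apply(X[!in_valid, , drop = FALSE], 2, sd)
    xi <- scale_mat(X[!in_valid, , drop = FALSE], mu, sdv)
    xv <- scale_mat(X[in_valid, , drop = FALSE], mu, sdv)
    yi <- y_all[!in_valid]
    w <- class_weights(yi)
    nv <- night_vec[in_valid]

    if (learner == "elastic_net") {
      # one path fit per mixing value scores every penalty in the grid
      for (a in unique(grid$alpha)) {
        lams <- grid$lambda[grid$alpha == a]
        path <- sort(unique(c(max(lams) * c(8, 4, 2), lams)),
                     decreasing = TRUE)
        fit <- glmnet::glmnet(xi, yi, family = "binomial", weights = w,
                              alpha = a, lambda = path, standardize = FALSE)
        pv <- predict(fit, xv, s = lams, type = "response")
        for (j in seq_along(lams)) {
          g <- which(grid$alpha == a & grid$lambda == lams[j])
          ph <- c(mean(pv[nv == hold[1], j]), mean(pv[nv == hold[2], j]))
          score_mat[i, g] <- (ph[1] > ph[2]) + 0.5 * (ph[1] == ph[2])
        }
      }
    } else {
      for (g in seq_len(nrow(grid))) {
        model <- fit_learner(learner, xi, yi, as.list(grid[g, ]), weights = w,
                             seed = derive_seed(seed, "tune", i, g))
        ph <- night_mean_prob(model, xv, nv, hold)
        score_mat[i, g] <- (ph[1] > ph[2]) + 0.5 * (ph[1] == ph[2])
      }
    }
  }
  scores <- colMeans(score_mat)
  best <- which.max(scores)  # first max = least complex on ties
  list(params = as.list(grid[best, ]), score = scores[best],
       scores = mutate(grid, score = scores))
}

#' Fit the final model on all training nights
#'
#' Refits the learner with the chosen hyperparameters on every interval row
#' of the training nights; the scaler is refit on the same rows. The
#' returned object carries everything needed for prediction and SHAP
#' attribution.
#'
#' @inheritParams tune_learner
#' @param params Hyperparameter list (e.g. `tune_learner()$params`).
#' @return An object of class `nocturne_model`.
#' @export
fit_final <- function(intervals, outcome, learner, params, seed = 1L) {
  scaler <- fit_scaler(intervals)
  xs <- interval_matrix(apply_scaler(scaler, intervals))
  y <- as.integer(is_positive(intervals$label, outcome))
  model <- fit_learner(learner, xs, y, params,
                       seed = derive_seed(seed, "final"))
  structure(list(learner = learner, params = params, model = model,
                 scaler = scaler, features = colnames(xs),
                 outcome = outcome, train_col_means = colMeans(xs)),
            class = "nocturne_model")
}

#' @export
print.nocturne_model <- function(x, ...) {
  cat(sprintf("<nocturne_model> %s for %s (%d features)\n",
              x$learner, x$outcome$name, length(x$features)))
  invisible(x)
}

#' Aggregate interval probabilities into one nightly prediction
#'
#' Scores every interval row of a night with the fitted model and averages
#' the interval probabilities into the nightly risk `p_hat`, with a 95%
#' normal-theory band (`mean +/- 1.96 * SE` over intervals, clipped to
#' `[0, 1]`).
#'
#' @param model A `nocturne_model` from [fit_final()].
#' @param night_intervals Interval rows of one night.
#' @return A one-row tibble: ids, `p_hat`, `ci_lo`, `ci_hi`, `n_intervals`,
#'   and `label` if present.
#' @export
predict_night <- function(model, night_intervals) {
  if (nrow(night_intervals) == 0) {
    inform("predict_night: night has no interval rows; skipped")
    return(tibble())
  }
  xs <- interval_matrix(apply_scaler(model$scaler, night_intervals))
  p <- predict_prob(model$model, xs)
  se <- if (length(p) > 1) sd(p) / sqrt(length(p)) else 0
  out <- tibble(
    participant_id = night_intervals$participant_id[1],
    night_index = night_intervals$night_index[1],
    p_hat = mean(p),
    ci_lo = max(0, mean(p) - 1.96 * se),
    ci_hi = min(1, mean(p) + 1.96 * se),
    n_intervals = length(p)
  )
  if ("label" %in% names(night_intervals)) out$label <- night_intervals$label[1]
  out
}

#' Run the full nested cross-validation for one participant
#'
#' The complete person-specific procedure: for every leave-one-night-out
#' outer fold and every learner, hyperparameters are tuned on the training
#' nights with paired leave-two-nights-out validation, the winning setting
#' is refit on all training nights, and the held-out night is scored. The
#' nightly predictions accumulated over outer folds give each learner's
#' AUROC and AUPRC; the best learner is the one with the highest AUROC.
#' All randomness derives from `seed`.
#'
#' @param intervals Labeled interval feature rows of one participant.
#' @param outcome An [outcome_def()].
#' @param learners Character vector of learners to evaluate.
#' @param seed Integer seed.
#' @param grids Named list of hyperparameter grids (see [default_grids()]).
#' @param pair_cap Cap on inner validation pairs per outer fold.
#' @return An object of class `participant_result`: nightly `predictions`,
#'   per-learner `metrics` (AUPRC, prevalence, AUROC), `best` learner name,
#'   participant id and outcome.
#' @export
run_participant <- function(intervals, outcome, learners = LEARNERS,
                            seed = 1L, grids = default_grids(),
                            pair_cap = 200) {
  pid <- unique(intervals$participant_id)
  if (length(pid) != 1)
    abort("run_participant expects intervals of exactly one participant")
  nights <- distinct(intervals, .data$night_index, .data$label)
  elig <- eligible(mutate(nights, participant_id = pid), outcome)
  if (!elig$eligible[1])
    abort(sprintf("participant %s ineligible for %s: %s", pid, outcome$name,
                  elig$reason[1]), class = "nocturne_eligibility_error")

  folds <- enumerate_l1no(nights$night_index)
  preds <- purrr::map_dfr(seq_len(nrow(folds)), function(k) {
    test_night <- folds$test_night[k]
    train <- intervals[intervals$night_index != test_night, ]
    test <- intervals[intervals$night_index == test_night, ]
    purrr::map_dfr(learners, function(lr) {
      fold_seed <- derive_seed(seed, pid, outcome$name, lr, test_night)
      tuned <- tune_learner(train, outcome, lr, grids[[lr]],
                            pair_cap = pair_cap, seed = fold_seed)
      fitted <- fit_final(train, outcome, lr, tuned$params, seed = fold_seed)
      predict_night(fitted, test) %>% mutate(learner = lr)
    })
  }) %>%
    mutate(positive = is_positive(.data$label, outcome),
           outcome = outcome$name)

  metrics <- preds %>%
    group_by(.data$learner) %>%
    group_modify(~ tibble(auprc = auprc(.x), prevalence = mean(.x$positive),
                          auroc = auroc(.x))) %>%
    ungroup() %>%
    mutate(participant_id = pid, outcome = outcome$name)

  best <- metrics$learner[which.max(metrics$auroc)]
  structure(list(participant_id = pid, outcome = outcome,
                 predictions = preds, metrics = metrics, best = best,
                 seed = seed),
            class = "participant_result")
}

#' @export
print.participant_result <- function(x, ...) {
  cat(sprintf("<participant_result> %s, outcome %s, %d nights\n",
              x$participant_id, x$outcome$name,
              nrow(distinct(x$predictions, .data$night_index))))
  print(as.data.frame(x$metrics[c("learner", "auprc", "prevalence", "auroc")]),
        row.names = FALSE, digits = 3)
  cat("best learner:", x$best, "\n")
  invisible(x)
}

#' @export
tidy.participant_result <- function(x, ...) x$metrics

#' @export
glance.participant_result <- function(x, ...) {
  x$metrics %>% filter(.data$learner == x$best) %>%
    rename(best_learner = "learner")
}
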