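LEARNERS <- c("elastic_net", "random_forest", "gbm")

#' Default hyperparameter grids for the three learners
#'
#' Small desk-scale grids. Each grid tibble is ordered from least to most
#' complex setting; [tune_learner()] breaks score ties toward the earlier
#' (simpler) row. Complexity orderings: elastic net -- larger penalty
#' simpler, then sparser (higher mixing) simpler; random forest -- larger
#' minimum leaf simpler, then fewer candidate features per split; gradient
#' boosting -- fewer rounds, then shallower trees, then smaller learning
#' rate.
#'
#' @param num_trees Forest size for the random-forest learner.
#' @return Named list of tibbles keyed by learner.
#' @export
default_grids <- function(num_trees = 500) {
  enet <- tidyr::expand_grid(alpha = c(0.1, 0.5, 0.9),
                             lambda = c(0.001, 0.01, 0.1, 1)) %>%
    arrange(dplyr::desc(.data$lambda), dplyr::desc(.data$alpha))
  rf <- tidyr::expand_grid(mtry_frac = c(sqrt(36) / 36, 1 / 3),
                           min_leaf = c(1, 5, 20)) %>%
    mutate(num_trees = num_trees) %>%
    arrange(dplyr::desc(.data$min_leaf), .data$mtry_frac)
  gbm <- tidyr::expand_grid(nrounds = c(100, 300), max_depth = c(2, 3),
                            eta = c(0.05, 0.1)) %>%
    arrange(.data$nrounds, .data$max_depth, .data$eta)
  list(elastic_net = enet, random_forest = rf, gbm = gbm)
}

#' Compact grids for quick runs
#'
#' A reduced version of [default_grids()] (one to two settings per learner,
#' smaller forests) for demonstrations, tests and calibration studies where
#' the tuning loop's size, not its outcome, is the binding constraint.
#' @param num_trees Forest size for the random-forest learner.
#' @return Named list of tibbles keyed by learner.
#' @export
compact_grids <- function(num_trees = 100) {
  list(
    elastic_net = tibble(alpha = 0.5, lambda = c(0.1, 0.01)),
    random_forest = tibble(mtry_frac = 1 / 3, min_leaf = 5,
                           num_trees = num_trees),
    gbm = tibble(nrounds = c(50, 50), max_depth = c(2, 3), eta = 0.1)
  )
}

# inverse-prevalence interval weights: each class contributes half the mass
class_weights <- function(y) {
  n <- length(y)
  w <- numeric(n)
  w[y == 1] <- n / (2 * max(sum(y == 1), 1))
  w[y == 0] <- n / (2 * max(sum(y == 0), 1))
  w
}

# Fit one learner on a scaled feature matrix. y is 0/1; weights optional.
# Random forests are single-round bagged parallel-tree ensembles (eta = 1,
# subsample 0.632, per-node feature subsampling), gradient boosting the
# usual shrunken additive trees; both in xgboost so exact TreeSHAP
# attributions are available. min_leaf maps to min_child_weight through the
# binary-logistic hessian bound (0.25 per row).
fit_learner <- function(learner, x, y, params, weights = NULL, seed = 1L) {
  if (is.null(weights)) weights <- class_weights(y)
  fit <- switch(
    learner,
    elastic_net = {
      glmnet::glmnet(x, y, family = "binomial", weights = weights,
                     alpha = params$alpha,
                     lambda = params$lambda * c(8, 4, 2, 1),
                     standardize = FALSE)
    },
    random_forest = ,
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = weights,
                                     nthread = 1)
      xp <- if (learner == "random_forest") {
        list(objective = "binary:logistic", eta = 1, max_depth = 12,
             subsample = 0.632, colsample_bynode = params$mtry_frac,
             min_child_weight = 0.25 * params$min_leaf,
             num_parallel_tree = params$num_trees, nthread = 1)
      } else {
        list(objective = "binary:logistic", eta = params$eta,
             max_depth = params$max_depth, min_child_weight = 1,
             nthread = 1)
      }
      nrounds <- if (learner == "random_forest") 1 else params$nrounds
      withr::with_seed(seed, {
        xgboost::xgb.train(params = xp, data = dtrain, nrounds = nrounds,
                           verbose = 0)
      })
    },
    abort(sprintf("unknown learner '%s'; available: %s", learner,
                  paste(LEARNERS, collapse = ", ")))
  )
  structure(list(learner = learner, fit = fit, params = params),
            class = "nocturne_learner_fit")
}

# probabilities on the positive class
predict_prob <- function(model, x) {
  if (model$learner == "elastic_net") {
    as.numeric(predict(model$fit, x, s = model$params$lambda,
                       type = "response"))
  } else {
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  }
}

# link-scale (log-odds) output, used by SHAP local-accuracy checks
predict_margin <- function(model, x) {
  if (model$learner == "elastic_net") {
    as.numeric(predict(model$fit, x, s = model$params$lambda,
                       type = "link"))
  } else {
    as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1),
                       outputmargin = TRUE))
  }
}
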