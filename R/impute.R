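#' Chained-equations imputation of the interval feature table
#'
#' Fills missing cells in the 5-minute interval feature table with a
#' multivariate chained-equations scheme run independently within each
#' (participant, night) stratum, so imputation can never borrow information
#' across days or from the outcome: the label column is excluded from the
#' predictor set. Continuous columns are imputed by predictive mean matching
#' (linear regression on all other feature columns; each missing cell
#' receives the observed value of one of the `n_donors` rows with the
#' closest predicted mean). The `n_imputations` completed tables are
#' averaged into a single analysis table (a documented simplification of
#' full multiple-imputation pooling, since the downstream nested
#' cross-validation consumes one table).
#'
#' A column that is entirely missing within a stratum cannot be modeled
#' there and falls back to the participant-level median (global median if
#' the participant has none), with a message.
#'
#' @param interval_table Tibble from [interval_features()], possibly with
#'   `NA` feature cells.
#' @param n_imputations Number of completed tables to average.
#' @param n_iterations Chained-equation sweeps per table.
#' @param seed Integer seed; output is deterministic given it.
#' @param n_donors Predictive-mean-matching donor pool size.
#' @return The interval table with no missing feature cells; observed cells
#'   are returned unchanged.
#' @export
impute_mice <- function(interval_table, n_imputations = 5, n_iterations = 10,
                        seed = 1L, n_donors = 5) {
  feat_cols <- feature_columns(interval_table)
  x <- as.matrix(interval_table[feat_cols])
  if (!anyNA(x)) return(interval_table)

  strata <- interpaste(interval_table$participant_id,
                       interval_table$night_index)
  n_fallback <- 0L

  # participant-level medians for the all-missing-column fallback
  part_med <- lapply(split(seq_len(nrow(x)), interval_table$participant_id),
                     function(i) apply(x[i, , drop = FALSE], 2, median,
                                       na.rm = TRUE))
  glob_med <- apply(x, 2, median, na.rm = TRUE)

  completed <- withr::with_seed(derive_seed(seed, "mice"), {
    sets <- lapply(seq_len(n_imputations), function(m) {
      xm <- x
      for (s in unique(strata)) {
        rows <- which(strata == s)
        pid <- interval_table$participant_id[rows[1]]
        sub <- x[rows, , drop = FALSE]
        all_na <- colSums(!is.na(sub)) == 0
        if (any(all_na)) {
          n_fallback <<- n_fallback + sum(all_na)
          for (j in which(all_na)) {
            fill <- part_med[[pid]][j]
            if (is.na(fill)) fill <- glob_med[j]
            sub[, j] <- fill
          }
        }
        xm[rows, ] <- impute_stratum_pmm(sub, n_iterations, n_donors)
      }
      xm
    })
    Reduce(`+`, sets) / n_imputations
  })
  # observed cells pass through untouched
  completed[!is.na(x)] <- x[!is.na(x)]
  if (n_fallback > 0)
    inform(sprintf("impute_mice: %d all-missing stratum column(s) filled with participant medians",
                   n_fallback))
  out <- interval_table
  out[feat_cols] <- as_tibble(completed)
  out
}

interpaste <- function(...) paste(..., sep = "\r")

# One chained-equations pass over a stratum matrix (rows = intervals).
impute_stratum_pmm <- function(sub, n_iterations, n_donors) {
  miss <- is.na(sub)
  if (!any(miss)) return(sub)
  # start from column medians
  for (j in which(colSums(miss) > 0)) {
    med <- median(sub[, j], na.rm = TRUE)
    sub[miss[, j], j] <- med
  }
  incomplete <- which(colSums(miss) > 0)
  # keep only predictors with variation to stabilise the regressions
  for (it in seq_len(n_iterations)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      if (sum(obs) < 3) next   # too few observed rows to model; keep medians
      preds <- setdiff(seq_len(ncol(sub)), j)
      preds <- preds[apply(sub[, preds, drop = FALSE], 2, sd) > 0]
      if (length(preds) == 0) next
      yhat <- pmm_predict(sub[, j], sub[, preds, drop = FALSE], obs)
      sub[!obs, j] <- pmm_draw(sub[obs, j], yhat$fit_obs, yhat$fit_mis,
                               n_donors)
    }
  }
  sub
}

pmm_predict <- function(y, xmat, obs) {
  X <- cbind(1, xmat)
  beta <- suppressWarnings(stats::lm.fit(X[obs, , drop = FALSE], y[obs]))$coefficients
  beta[is.na(beta)] <- 0   # collinear predictors contribute nothing
  fitted_all <- drop(X %*% beta)
  list(fit_obs = fitted_all[obs], fit_mis = fitted_all[!obs])
}

pmm_draw <- function(y_obs, fit_obs, fit_mis, n_donors) {
  vapply(fit_mis, function(f) {
    d <- abs(fit_obs - f)
    donors <- order(d)[seq_len(min(n_donors, length(d)))]
    y_obs[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}
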