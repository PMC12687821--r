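pred_tbl <- function(p, y) tibble::tibble(p_hat = p, positive = as.logical(y))

# independent oracle: concordance counted over every positive/negative pair
auroc_brute <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

test_that("AUROC matches known values and the pairwise-concordance oracle", {
  expect_equal(auroc(pred_tbl(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  expect_equal(auroc(pred_tbl(rep(0.4, 6), c(1, 0, 1, 0, 0, 1))), 0.5)
  expect_equal(auroc(pred_tbl(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))), 0.75)

  withr::with_seed(41, {
    for (i in 1:200) {
      n <- sample(4:50, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
      p <- round(runif(n), sample(c(1, 2, 7), 1))  # include heavy ties
      expect_equal(auroc(pred_tbl(p, y)), auroc_brute(p, y), tolerance = 1e-12)
    }
  })
  expect_error(auroc(pred_tbl(c(0.2, 0.3), c(1, 1))), "negative")
  expect_error(auroc(pred_tbl(c(0.2, 0.3), c(0, 0))), "positive")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, {
    for (i in 1:20) {
      y <- c(0, 1, rbinom(28, 1, 0.3))
      p <- runif(30)
      ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auroc(pred_tbl(p, y)), ref, tolerance = 1e-10)
    }
  })
})

test_that("AUPRC has the known degenerate values and respects prevalence", {
  expect_equal(auprc(pred_tbl(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))), 1)
  # constant scores collapse to a single operating point at prevalence
  expect_equal(auprc(pred_tbl(rep(0.4, 10), c(rep(1, 3), rep(0, 7)))), 0.3)
  # planted-signal predictions keep AUPRC at or above prevalence
  withr::with_seed(23, {
    y <- rbinom(40, 1, 0.3); y[1:2] <- c(0, 1)
    p <- plogis(2 * y + rnorm(40))
    expect_gte(auprc(pred_tbl(p, y)), mean(y))
  })
})

test_that("threshold metrics implement the >= rule and edge thresholds", {
  p <- c(0.9, 0.5, 0.3, 0.1); y <- c(1, 0, 1, 0)
  tm <- threshold_metrics(pred_tbl(p, y), 0.5)
  expect_equal(tm$tp, 1); expect_equal(tm$fp, 1)  # tie at 0.5 called positive
  expect_equal(tm$sensitivity, 0.5)
  expect_equal(tm$specificity, 0.5)

  hi <- threshold_metrics(pred_tbl(p, y), 0.95)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_equal(hi$precision, 0)
  expect_true(hi$no_positive_calls)

  lo <- threshold_metrics(pred_tbl(p, y), 0.01)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
})

test_that("confusion recovery reproduces published threshold rows", {
  # all positives called at the low threshold: 12/39 positive nights
  r1 <- confusion_from_summary(1.00, 0.222, 12, 27)
  expect_equal(r1$tp, 12); expect_equal(r1$tn, 6)
  expect_equal(r1$fp, 21); expect_equal(r1$fn, 0)
  expect_equal(round(100 * r1$precision, 1), 36.4)   # 12/33
  expect_equal(round(100 * r1$accuracy, 1), 46.2)    # 18/39
  expect_true(r1$consistent)

  r2 <- confusion_from_summary(0.75, 0.75, 20, 24)
  expect_equal(r2$tp, 15)   # "15 of 20" true positives
  expect_equal(r2$tn, 18); expect_equal(r2$fp, 6)
  expect_equal(round(100 * r2$precision, 1), 71.4)   # 15/21
  expect_equal(r2$accuracy, 0.75)

  perfect <- confusion_from_summary(1, 1, 7, 13)
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_equal(perfect$accuracy, 1)
  expect_error(confusion_from_summary(0.5, 0.5, -1, 5), "non-negative")
})

test_that("the accuracy identity matches thresholded counts on random instances", {
  # 0.222 is a 3-decimal printed specificity; agreement is to that precision
  expect_equal(accuracy_from_summary(1.0, 0.222, 12 / 39), 0.4615,
               tolerance = 1e-3)
  expect_equal(accuracy_from_summary(0.75, 0.75, 0.123), 0.75)
  expect_equal(accuracy_from_summary(0.6, 0.6, 0.9), 0.6)

  withr::with_seed(59, {
    for (i in 1:200) {
      n <- sample(6:60, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.35))
      p <- runif(n)
      th <- runif(1, 0.05, 0.95)
      tm <- threshold_metrics(pred_tbl(p, y), th)
      expect_equal(accuracy_from_summary(tm$sensitivity, tm$specificity,
                                         mean(y)),
                   tm$accuracy, tolerance = 1e-12)
    }
  })
})

test_that("thresholding then confusion recovery round-trips", {
  withr::with_seed(71, {
    y <- c(0, 1, rbinom(30, 1, 0.4)); p <- runif(32)
  })
  tm <- threshold_metrics(pred_tbl(p, y), 0.4)
  back <- confusion_from_summary(tm$sensitivity, tm$specificity,
                                 tm$positive_days,
                                 tm$total_days - tm$positive_days)
  expect_equal(back$tp, tm$tp); expect_equal(back$fp, tm$fp)
  expect_equal(back$tn, tm$tn); expect_equal(back$fn, tm$fn)
  expect_true(back$consistent)
})
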