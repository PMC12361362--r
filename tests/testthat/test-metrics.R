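test_that("classification metrics hit the closed-form anchor cases", {
  perfect <- confusion_counts(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(accuracy(perfect), 1)
  expect_equal(precision(perfect), 1)
  expect_equal(f1_score(perfect), 1)
  expect_equal(mcc(perfect), 1)
  expect_equal(csi(perfect), 1)
  expect_equal(fpr(perfect), 0)

  sym <- confusion_counts(tp = 1, tn = 1, fp = 1, fn = 1)
  expect_equal(mcc(sym), 0)
  expect_equal(accuracy(sym), 0.5)
  expect_equal(csi(sym), 1 / 3)
  expect_equal(fpr(sym), 0.5)

  c3 <- confusion_counts(tp = 90, tn = 80, fp = 10, fn = 20)
  expect_equal(accuracy(c3), 0.85)
  expect_equal(precision(c3), 0.9)
  expect_equal(f1_score(c3), 180 / 210)
  expect_equal(mcc(c3), (90 * 80 - 10 * 20) /
                 sqrt(100 * 110 * 90 * 100))
})

test_that("all ten metric formulas match a brute-force oracle on random inputs", {
  # independent formula transcriptions, written directly from the
  # definitions rather than calling the package implementations
  oracle <- list(
    accuracy = function(tp, tn, fp, fn) (tp + tn) / (tp + tn + fp + fn),
    precision = function(tp, tn, fp, fn) tp / (tp + fp),
    f1 = function(tp, tn, fp, fn) 2 * tp / (2 * tp + fp + fn),
    mcc = function(tp, tn, fp, fn) {
      d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (d == 0) 0 else (tp * tn - fp * fn) / d
    },
    csi = function(tp, tn, fp, fn) tp / (tp + fp + fn),
    fpr = function(tp, tn, fp, fn) fp / (fp + tn)
  )
  withr::with_seed(17, {
    for (i in 1:1000) {
      k <- sample(0:50, 4, replace = TRUE)
      if (k[1] + k[3] + k[4] == 0 || k[1] + k[3] == 0 || k[3] + k[2] == 0) next
      cc <- confusion_counts(tp = k[1], tn = k[2], fp = k[3], fn = k[4])
      expect_equal(accuracy(cc), oracle$accuracy(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
      expect_equal(precision(cc), oracle$precision(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
      expect_equal(f1_score(cc), oracle$f1(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
      expect_equal(mcc(cc), oracle$mcc(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
      expect_equal(csi(cc), oracle$csi(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
      expect_equal(fpr(cc), oracle$fpr(k[1], k[2], k[3], k[4]), tolerance = 1e-12)
    }
    for (i in 1:1000) {
      n <- sample(1:30, 1)
      a <- stats::runif(n, 0.05, 1)
      p <- stats::runif(n, 0, 1)
      expect_equal(rmse(a, p), sqrt(sum((a - p)^2) / n), tolerance = 1e-12)
      expect_equal(mae(a, p), sum(abs(a - p)) / n, tolerance = 1e-12)
      expect_equal(smape(a, p),
                   sum(abs(p - a) / ((abs(p) + abs(a)) / 2)) / n, tolerance = 1e-12)
      expect_equal(mpe(a, p), sum(abs(p - a) / a) / n, tolerance = 1e-12)
    }
  })
})

test_that("regression metrics hit the hand-computed anchor cases", {
  a <- c(0.3, 0.5, 0.9)
  expect_equal(rmse(a, a), 0)
  expect_equal(mae(a, a), 0)
  expect_equal(smape(a, a), 0)
  expect_equal(mpe(a, a), 0)

  expect_equal(mae(1, 3), 2)
  expect_equal(rmse(1, 3), 2)
  expect_equal(smape(1, 3), 2 / ((1 + 3) / 2))
  expect_equal(mpe(1, 3), 2)

  # residuals 3 and 4
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(mae(c(3, 4), c(0, 0)), 3.5)

  expect_error(mpe(c(0, 1), c(1, 1)), "zero")
  expect_error(rmse(1:3, 1:2), "equal length")
  # both-zero smape term contributes 0
  expect_equal(smape(c(0, 1), c(0, 1)), 0)
})

test_that("metric inequalities and symmetries hold on random inputs", {
  withr::with_seed(31, {
    for (i in 1:200) {
      k <- sample(1:40, 4, replace = TRUE)
      cc <- confusion_counts(tp = k[1], tn = k[2], fp = k[3], fn = k[4])
      # f1 is the harmonic mean of precision and recall
      prec <- k[1] / (k[1] + k[3])
      rec <- k[1] / (k[1] + k[4])
      expect_equal(f1_score(cc), 2 * prec * rec / (prec + rec), tolerance = 1e-12)
      # mcc flips sign when swapping tp<->fp and tn<->fn
      cc_swap <- confusion_counts(tp = k[3], tn = k[4], fp = k[1], fn = k[2])
      expect_equal(mcc(cc_swap), -mcc(cc), tolerance = 1e-12)

      n <- sample(2:20, 1)
      a <- stats::rnorm(n); p <- stats::rnorm(n)
      expect_gte(rmse(a, p), mae(a, p) - 1e-12)
      expect_lte(smape(a, p), 2)
    }
  })
})

test_that("reports assemble all metrics with optional percent scaling", {
  cc <- confusion_counts(tp = 90, tn = 80, fp = 10, fn = 20)
  rep_frac <- classification_report(cc)
  rep_pct <- classification_report(cc, percent = TRUE)
  expect_equal(rep_pct[["accuracy"]], 85)
  expect_equal(rep_pct[["mcc"]], rep_frac[["mcc"]])  # mcc not rescaled

  rr <- regression_report(c(1, 2), c(1.5, 2.5), percent = TRUE)
  expect_equal(rr[["mae"]], 0.5)
  expect_equal(rr[["mpe"]], mean(c(0.5 / 1, 0.5 / 2)) * 100)
})

test_that("confusion tallies from label vectors match direct counting", {
  actual <- c(1, 1, 0, 0, 1, 0)
  pred <- c(1, 0, 0, 1, 1, 0)
  cc <- tabulate_confusion(actual, pred)
  expect_equal(cc$tp, 2)
  expect_equal(cc$tn, 2)
  expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 1)
  expect_error(tabulate_confusion(c(0, 2), c(0, 1)), "0/1")
})
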