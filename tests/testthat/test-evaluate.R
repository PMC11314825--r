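test_that("confusion counts tally the four cells", {
  cm <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cm$TP, 1L); expect_identical(cm$FN, 1L)
  expect_identical(cm$TN, 1L); expect_identical(cm$FP, 1L)

  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_identical(perfect$FP + perfect$FN, 0L)

  allneg <- confusion_counts(c(1, 0), c(0, 0))
  expect_identical(allneg$TP, 0L); expect_identical(allneg$FN, 1L)
  expect_identical(allneg$TN, 1L); expect_identical(allneg$FP, 0L)

  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0, 1")
})

test_that("metrics follow the defining ratios exactly", {
  m <- classification_metrics(confusion_counts(
    truth = c(rep(1, 3), rep(0, 7)),
    predicted = c(1, 1, 0, 1, rep(0, 6))))  # TP2 FN1 FP1 TN6
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$F1, 2 / 3)
  expect_length(m$undefined, 0L)

  p <- classification_metrics(confusion_counts(c(1, 0), c(1, 0)))
  expect_equal(unlist(p[c("accuracy", "precision", "recall", "F1")]),
               c(accuracy = 1, precision = 1, recall = 1, F1 = 1))

  u <- classification_metrics(confusion_counts(c(0, 0), c(0, 0)))
  expect_true("precision" %in% u$undefined)
  expect_equal(u$precision, 0)
})

test_that("metrics agree with an independent tally over all two-sample label patterns", {
  for (t1 in 0:1) for (t2 in 0:1) for (p1 in 0:1) for (p2 in 0:1) {
    truth <- c(t1, t2); pred <- c(p1, p2)
    cm <- confusion_counts(truth, pred)
    # independent tally
    tp <- sum(truth & pred); tn <- sum(!truth & !pred)
    fp <- sum(!truth & pred); fn <- sum(truth & !pred)
    expect_identical(c(cm$TP, cm$TN, cm$FP, cm$FN),
                     as.integer(c(tp, tn, fp, fn)))
    m <- classification_metrics(cm)
    expect_equal(m$accuracy, (tp + tn) / 2)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    if (2 * tp + fp + fn > 0) expect_equal(m$F1, 2 * tp / (2 * tp + fp + fn))
    # harmonic identity where both parts are defined and nonzero
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$F1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("AUC handles separation, ties, and the four-point example", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)

  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, brute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  # curve is a monotone staircase from (0,0) to (1,1)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))

  expect_error(roc_auc(c(0.3, 0.4), c(1, 1)), "both classes")
})

test_that("AUC equals the pair-counting oracle and respects its invariances", {
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(8:30, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- roc_auc(scores, labels)$auc
    expect_equal(a, brute_auc(scores, labels))
    # invariant under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * scores), labels)$auc, a)
    # label flip complements
    expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(suppressMessages(pROC::auc(labels, scores))))
})

test_that("group comparison reports means, SDs and sensible p-values", {
  # hand-computed toy table
  ft <- data.frame(f = c(1, 3, 10, 14))
  g <- c("a", "a", "b", "b")
  cmp <- compare_groups(ft, g)
  expect_equal(cmp$mean_a, 2); expect_equal(cmp$sd_a, sqrt(2))
  expect_equal(cmp$mean_b, 12); expect_equal(cmp$sd_b, sqrt(8))
  expect_equal(cmp$p_value,
               stats::t.test(c(1, 3), c(10, 14))$p.value)

  # identical groups: p ~ 1
  same <- data.frame(f = c(1, 2, 3, 1, 2, 3))
  cs <- compare_groups(same, rep(c("a", "b"), each = 3))
  expect_gt(cs$p_value, 0.99)
  expect_equal(cs$mean_a, cs$mean_b)

  # groups five sigma apart are overwhelmingly distinguishable
  set.seed(23)
  far <- data.frame(f = c(rnorm(50), rnorm(50, mean = 5)))
  gf <- rep(c("a", "b"), each = 50)
  expect_lt(compare_groups(far, gf)$p_value, 1e-6)
  expect_lt(compare_groups(far, gf, test = "mwu")$p_value, 1e-6)

  expect_error(compare_groups(ft, c("a", "a", "a", "b")), "at least 2")
})
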