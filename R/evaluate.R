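#' Confusion counts for binary labels
#'
#' @param truth,predicted Equal-length vectors over \{0, 1\}; 1 is the
#'   positive (pre-AF) class.
#' @return An object of class `confusion_counts`: list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("labels must lie in {0, 1}", call. = FALSE)
  }
  structure(list(TP = sum(truth == 1L & predicted == 1L),
                 TN = sum(truth == 0L & predicted == 0L),
                 FP = sum(truth == 0L & predicted == 1L),
                 FN = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  FP %d  TN %d (n = %d)\n",
              x$TP, x$FN, x$FP, x$TN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' F1 `2TP/(2TP+FP+FN)`. A zero denominator makes the affected metric 0 and
#' sets the `undefined` flag naming it.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `eval_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `F1` and `undefined` (character vector of
#'   degenerate metrics).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("empty confusion counts", call. = FALSE)
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  structure(list(
    accuracy = (counts$TP + counts$TN) / n,
    precision = div(counts$TP, counts$TP + counts$FP, "precision"),
    recall = div(counts$TP, counts$TP + counts$FN, "recall"),
    F1 = div(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN, "F1"),
    undefined = undefined), class = "eval_metrics")
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with tie
#' correction: the probability that a random positive outscores a random
#' negative, ties counting one half. The returned curve is the standard
#' monotone staircase from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Labels over \{0, 1\}; both classes must be present.
#' @return A list of class `roc_result`: `auc`, and `curve` (data frame
#'   with `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  structure(list(auc = auc,
                 curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d operating points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Per-feature group comparison (mean, SD, two-sample test)
#'
#' Summarises each feature column per group and tests the group difference,
#' by default with Welch's unequal-variance t-test (matching a mean +- SD
#' presentation); `test = "mwu"` switches to the Mann-Whitney U
#' (Wilcoxon rank-sum) test.
#'
#' @param features Data frame or matrix of numeric feature columns.
#' @param groups Two-level grouping vector, one entry per row.
#' @param test `"welch"` or `"mwu"`.
#' @return A data frame of class `feature_comparison`: one row per feature
#'   with group means, SDs and the two-sided p-value.
#' @export
compare_groups <- function(features, groups, test = c("welch", "mwu")) {
  test <- match.arg(test)
  features <- as.data.frame(features)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  lv <- levels(groups)
  rows <- lapply(names(features), function(nm) {
    v <- as.numeric(features[[nm]])
    a <- v[groups == lv[1]]
    b <- v[groups == lv[2]]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      1  # identical degenerate groups: no evidence of difference
    } else if (test == "welch") {
      stats::t.test(a, b)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(feature = nm,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("sd_", lv[1]),
                       paste0("mean_", lv[2]), paste0("sd_", lv[2]))
  class(out) <- c("feature_comparison", "data.frame")
  attr(out, "test") <- test
  out
}
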