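# Verification-side evaluation: thresholded classification, confusion
# statistics, rank-based ROC/AUC with bootstrap confidence intervals, and
# subgroup true-positive-rate analyses over positive pairs.

#' Threshold verification scores into class labels
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param t Threshold in (0, 1); a score equal to `t` counts positive.
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(scores, t = 0.5) {
  assert_that(t > 0 && t < 1, "threshold must lie strictly in (0, 1)")
  as.integer(scores >= t)
}

#' Confusion counts from predictions and truth
#'
#' @param predicted,truth Binary 0/1 vectors of equal length.
#' @return Object of class `confusion_counts` with `tp`, `fn`, `tn`, `fp`,
#'   `p`, `n`.
#' @export
confusion_counts <- function(predicted, truth) {
  assert_that(length(predicted) == length(truth),
              "predicted and truth must have equal length")
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 p = tp + fn, n = tn + fp),
            class = "confusion_counts")
}

#' Derived statistics from confusion counts
#'
#' accuracy = (TP+TN)/(P+N), specificity = TN/N, recall = TP/P,
#' precision = TP/(TP+FP), F1 = 2*precision*recall/(precision+recall).
#' A metric whose denominator is zero is reported as `NA` rather than
#' raising an error.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `tp`, `fn`, `tn`, `fp`.
#' @return Named list: `accuracy`, `specificity`, `recall`, `precision`,
#'   `f1`.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  p <- tp + fn; n <- tn + fp
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- safe(tp + tn, p + n)
  specificity <- safe(tn, n)
  recall <- safe(tp, p)
  precision <- safe(tp, tp + fp)
  f1 <- if (!is.na(precision) && !is.na(recall) &&
            (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(accuracy = accuracy, specificity = specificity, recall = recall,
       precision = precision, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation (equivalent to the two-sample rank statistic)
#' with mid-rank tie correction: ties between a positive and a negative
#' score contribute 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  assert_that(pos > 0 && neg > 0,
              "roc_auc requires both classes to be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Resamples the (score, label) pairs with replacement `B` times, computes
#' the AUC of each replicate, and returns the percentile interval.
#' Replicates that draw a single class are redrawn.
#'
#' @param scores,labels As in [roc_auc()].
#' @param B Number of bootstrap replicates (>= 100; reference setting
#'   10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `low`, `high` and the replicate vector `auc_boot`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 10000L, level = 0.95,
                             seed = 1L) {
  assert_that(B >= 100, "B must be >= 100")
  labels <- as.integer(labels)
  n <- length(scores)
  with_seed(seed, {
    aucs <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        lb <- labels[idx]
        if (any(lb == 1) && any(lb == 0)) break
      }
      aucs[b] <- roc_auc(scores[idx], lb)
    }
    alpha <- (1 - level) / 2
    qs <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE,
                          type = 7)
    list(low = qs[1], high = qs[2], auc_boot = aucs)
  })
}

#' ROC curve points
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame with `threshold`, `fpr`, `tpr`, one row per unique
#'   score plus the two endpoints.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1) / pos, 0)
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0) / neg, 0)
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' Full verification report
#'
#' Combines the AUC with its bootstrap confidence interval and the
#' threshold-derived confusion statistics.
#'
#' @param scores,labels Aligned scores and truth labels.
#' @param t Decision threshold.
#' @param B,level,seed Bootstrap settings; see [bootstrap_auc_ci()].
#' @return Object of class `verification_report`.
#' @export
verification_report <- function(scores, labels, t = 0.5, B = 2000L,
                                level = 0.95, seed = 1L) {
  counts <- confusion_counts(classify(scores, t), labels)
  ci <- bootstrap_auc_ci(scores, labels, B = B, level = level, seed = seed)
  structure(c(list(auc = roc_auc(scores, labels), ci_low = ci$low,
                   ci_high = ci$high, threshold = t, counts = counts),
              confusion_metrics(counts)),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report>\n  AUC %.4f (95%% CI %.4f-%.4f)\n",
              x$auc, x$ci_low, x$ci_high))
  cat(sprintf(
    "  acc %.4f  spec %.4f  recall %.4f  prec %.4f  F1 %.4f  (t = %.2f)\n",
    x$accuracy, x$specificity, x$recall, x$precision, x$f1, x$threshold))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n", x$counts$tp, x$counts$fn,
              x$counts$tn, x$counts$fp))
  invisible(x)
}

#' Write a verification report as JSON
#' @param report A `verification_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_verification_report <- function(report, path) {
  out <- report
  class(out) <- NULL
  out$counts <- unclass(out$counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Subgroup true-positive rate over positive pairs
#'
#' Bins the POSITIVE pairs of a scored pair set by an attribute of the
#' pair and reports the per-bin TPR with absolute counts, mirroring
#' follow-up robustness analyses: TPR versus the age gap in years, versus
#' changes in the disease pattern, and versus projection-view changes.
#' Pairs whose attribute cannot be computed (sentinel `"unknown"` values)
#' and bins without positives are omitted.
#'
#' @param pairs A `pair_set` (or data frame) with `first_id`, `second_id`,
#'   `label`.
#' @param scores Scores aligned to `pairs`.
#' @param cohort The cohort the pair ids refer to.
#' @param attribute `"age_gap_years"`, `"disease_change"` or
#'   `"view_change"`.
#' @param bins For `age_gap_years`: breaks passed to `cut(right = FALSE)`;
#'   default `0:13` gives one bin per year gap 0..12. Ignored otherwise.
#' @param t Decision threshold.
#' @return Data frame with `bin`, `tpr`, `tp`, `p`. For `disease_change`,
#'   one row per newly appearing finding label (a pair with several new
#'   findings contributes to each), plus a `"no change"` row.
#' @export
subgroup_tpr <- function(pairs, scores, cohort,
                         attribute = c("age_gap_years", "disease_change",
                                       "view_change"),
                         bins = 0:13, t = 0.5) {
  attribute <- match.arg(attribute)
  assert_that(nrow(pairs) == length(scores),
              "pairs and scores must be aligned")
  keep <- pairs$label == 1
  pairs <- pairs[keep, , drop = FALSE]
  scores <- scores[keep]
  assert_that(nrow(pairs) > 0, "no positive pairs to analyse")
  rec <- cohort$records
  i1 <- match(pairs$first_id, rec$image_id)
  i2 <- match(pairs$second_id, rec$image_id)
  assert_that(!anyNA(i1) && !anyNA(i2),
              "pair ids missing from the cohort")
  hit <- classify(scores, t) == 1

  tally <- function(key, hit) {
    tab <- tapply(hit, key, function(h) c(tp = sum(h), p = length(h)))
    out <- do.call(rbind, tab)
    data.frame(bin = rownames(out), tpr = out[, "tp"] / out[, "p"],
               tp = out[, "tp"], p = out[, "p"], row.names = NULL,
               stringsAsFactors = FALSE)
  }

  if (attribute == "age_gap_years") {
    gap <- abs(rec$age_years[i1] - rec$age_years[i2])
    key <- cut(gap, breaks = bins, right = FALSE)
    ok <- !is.na(key)
    res <- tally(as.character(key[ok]), hit[ok])
    res[order(match(res$bin, levels(key))), , drop = FALSE]
  } else if (attribute == "view_change") {
    v1 <- rec$view[i1]; v2 <- rec$view[i2]
    ok <- v1 != "unknown" & v2 != "unknown"
    tally(ifelse(v1[ok] != v2[ok], "view change", "same view"), hit[ok])
  } else {
    # disease_change: bin by each finding newly appearing in the later
    # follow-up; a pair with several new findings contributes to each bin
    fu1 <- rec$follow_up_index[i1]; fu2 <- rec$follow_up_index[i2]
    early <- ifelse(fu1 <= fu2, i1, i2)
    late <- ifelse(fu1 <= fu2, i2, i1)
    rows <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      new_f <- setdiff(rec$findings[[late[k]]], rec$findings[[early[k]]])
      new_f <- setdiff(new_f, "No Finding")
      rows[[k]] <- data.frame(
        bin = if (length(new_f) == 0) "no change" else new_f,
        hit = hit[k], stringsAsFactors = FALSE)
    }
    long <- do.call(rbind, rows)
    tally(long$bin, long$hit)
  }
}
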