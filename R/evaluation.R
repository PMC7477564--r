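# Screening-performance evaluation: ordinal confusion matrices, the five
# binarized screening metrics, rank-based AUC, the DG1-exclusion
# re-binning, and discrepancy reports of severe misgrades. Metrics with a
# zero denominator are reported as NA ("undefined"), never coerced to 0.

#' Ordinal confusion matrix
#'
#' @param true,pred equal-length integer grade vectors in 0..k-1.
#' @param k number of grades (4 for DG).
#' @return k x k integer matrix of class `confusion_matrix`; rows = true
#'   grade, columns = predicted grade, dimnames "DG0".."DG(k-1)".
#' @export
confusion_matrix <- function(true, pred, k = 4L) {
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length", call. = FALSE)
  }
  if (length(true) && (any(true < 0 | true > k - 1) ||
                       any(pred < 0 | pred > k - 1))) {
    stop("grades must lie in 0..", k - 1, call. = FALSE)
  }
  lv <- 0:(k - 1)
  m <- table(factor(true, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(m), k, k,
              dimnames = list(true = paste0("DG", lv),
                              pred = paste0("DG", lv)))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' The five screening metrics from a binarized confusion matrix
#'
#' Grades in `positive_grades` count as positive; the matrix collapses to
#' 2x2 and the metrics are
#' sensitivity = TP / positive labels, specificity = TN / negative labels,
#' PPV = TP / positive predictions, NPV = TN / negative predictions,
#' accuracy = (TP + TN) / total. Undefined ratios (zero denominator) are
#' returned as NA.
#'
#' @param cm a [confusion_matrix()].
#' @param positive_grades non-empty proper subset of the grade set.
#' @return object of class `binary_metrics`: list with tp/fp/fn/tn and the
#'   five metrics (plus `auc`, NA until filled by [auc_score()]).
#' @export
binarized_metrics <- function(cm, positive_grades = 1:3) {
  k <- nrow(cm)
  if (length(positive_grades) == 0 || length(positive_grades) >= k ||
      any(!positive_grades %in% 0:(k - 1))) {
    stop("positive_grades must be a non-empty proper subset of 0..",
         k - 1, call. = FALSE)
  }
  pos <- positive_grades + 1L
  neg <- setdiff(seq_len(k), pos)
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, neg])
  fp <- sum(cm[neg, pos]); tn <- sum(cm[neg, neg])
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fp + tn + fn),
    auc = NA_real_), class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%",
                                                            100 * v)
  cat("sensitivity ", fmt(x$sensitivity),
      "  specificity ", fmt(x$specificity),
      "  PPV ", fmt(x$ppv), "  NPV ", fmt(x$npv),
      "  accuracy ", fmt(x$accuracy), "\n", sep = "")
  if (!is.na(x$auc)) cat("AUC ", sprintf("%.3f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive scores above a random negative,
#' ties counted 1/2 -- computed from midranks, equivalent to exhaustive
#' pair counting, and invariant under strictly monotone score transforms.
#'
#' @param true_binary logical or 0/1 vector.
#' @param scores continuous scores, higher = more positive.
#' @return AUC in [0, 1]; NA with a warning when only one class is
#'   present.
#' @export
auc_score <- function(true_binary, scores) {
  y <- as.logical(true_binary)
  if (length(y) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Drop DG1 labels and re-bin DG1 predictions
#'
#' The stricter evaluation that targets obvious dysplasia: cells truly
#' graded 1 are removed; cells predicted 1 are re-binned to 0 or 2 using
#' the continuous ensemble DG score against the threshold `split` (default
#' 1.0, the midpoint of grades 0 and 2 on the score scale).
#'
#' @param true integer true grades.
#' @param scores continuous DG scores aligned with `true`.
#' @param final integer predicted grades.
#' @param split re-binning threshold on the continuous score.
#' @return list with `true` and `pred`, grades in {0, 2, 3}.
#' @export
exclude_dg1_rebin <- function(true, scores, final, split = 1.0) {
  stopifnot(length(true) == length(scores),
            length(true) == length(final))
  keep <- true != 1L
  tr <- true[keep]; sc <- scores[keep]; fg <- final[keep]
  fg[fg == 1L] <- ifelse(sc[fg == 1L] < split, 0L, 2L)
  list(true = tr, pred = fg)
}

#' Severe-misgrade discrepancy report
#'
#' Lists the cells whose true and predicted grades differ by at least
#' `min_diff`: false negatives (true > predicted, missed dysplasia) and
#' false positives (predicted > true, overcalled dysplasia).
#'
#' @param true,pred integer grade vectors.
#' @param min_diff minimum |true - pred| to report (>= 1).
#' @param ids optional cell identifiers.
#' @return list with data.frames `false_negative` and `false_positive`
#'   (columns id, true, pred, diff) and integer counts `n_false_negative`,
#'   `n_false_positive`.
#' @export
discrepancy_report <- function(true, pred, min_diff = 2L, ids = NULL) {
  if (min_diff < 1) stop("min_diff must be >= 1", call. = FALSE)
  stopifnot(length(true) == length(pred))
  if (is.null(ids)) ids <- as.character(seq_along(true))
  diff <- true - pred
  mk <- function(sel) {
    df <- data.frame(id = ids[sel], true = true[sel], pred = pred[sel],
                     diff = abs(diff[sel]), stringsAsFactors = FALSE)
    df[order(-df$diff), , drop = FALSE]
  }
  fn <- mk(diff >= min_diff)
  fp <- mk(-diff >= min_diff)
  list(false_negative = fn, false_positive = fp,
       n_false_negative = nrow(fn), n_false_positive = nrow(fp))
}

#' Evaluate pooled cross-validation predictions
#'
#' Convenience wrapper producing the confusion matrix, binarized metrics
#' with AUC, the DG1-exclusion variant, and the severe-discrepancy report
#' from a pooled prediction table.
#'
#' @param predictions data.frame as returned by
#'   [run_cross_validation()]`$predictions`.
#' @param min_diff discrepancy bound for the report.
#' @return list with `confusion`, `metrics`, `metrics_excl_dg1`,
#'   `discrepancies`.
#' @export
evaluate_predictions <- function(predictions, min_diff = 2L) {
  cm <- confusion_matrix(predictions$true_dg, predictions$final_grade, 4L)
  m <- binarized_metrics(cm, 1:3)
  m$auc <- auc_score(predictions$true_dg >= 1, predictions$dg_score)
  rb <- exclude_dg1_rebin(predictions$true_dg, predictions$dg_score,
                          predictions$final_grade)
  cm2 <- confusion_matrix(rb$true, rb$pred, 4L)
  m2 <- binarized_metrics(cm2, 2:3)
  keep <- predictions$true_dg != 1L
  if (any(keep) && length(unique(predictions$true_dg[keep] >= 2)) == 2) {
    m2$auc <- auc_score(predictions$true_dg[keep] >= 2,
                        predictions$dg_score[keep])
  }
  list(confusion = cm,
       metrics = m,
       metrics_excl_dg1 = m2,
       discrepancies = discrepancy_report(predictions$true_dg,
                                          predictions$final_grade,
                                          min_diff,
                                          ids = predictions$item_id))
}
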