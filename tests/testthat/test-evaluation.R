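test_that("confusion matrices tally true/predicted grade pairs", {
  cm <- confusion_matrix(c(0, 1, 2, 3), c(0, 1, 2, 3), 4)
  expect_equal(unname(diag(unclass(cm))), rep(1L, 4))
  expect_equal(sum(cm), 4L)
  empty <- confusion_matrix(integer(0), integer(0), 4)
  expect_true(all(empty == 0))
  set.seed(3)
  tr <- sample(0:3, 100, replace = TRUE)
  pr <- sample(0:3, 100, replace = TRUE)
  cm2 <- confusion_matrix(tr, pr, 4)
  for (i in 0:3) for (j in 0:3) {
    expect_equal(unclass(cm2)[i + 1, j + 1], sum(tr == i & pr == j))
  }
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "0..3")
  expect_error(confusion_matrix(0:1, 0L, 4), "equal length")
})

test_that("the published confusion matrix reproduces its recomputable screening metrics", {
  ref <- reference_confusion()
  cm <- confusion_matrix(ref$true, ref$pred, 4)
  expect_equal(unclass(cm), unclass(ref$matrix), ignore_attr = TRUE)
  m <- binarized_metrics(cm, 1:3)
  expect_equal(m$tp, 122)
  expect_equal(m$sensitivity, 122 / 134)
  expect_equal(round(100 * m$sensitivity, 1), 91.0)
  expect_equal(m$npv, 1623 / 1635)
  expect_equal(round(100 * m$npv, 1), 99.3)
})

test_that("metrics with empty denominators are reported as undefined", {
  cm <- confusion_matrix(c(0, 0, 0), c(0, 1, 2), 4)
  m <- binarized_metrics(cm, 1:3)
  expect_true(is.na(m$sensitivity))  # no positive labels
  expect_equal(m$specificity, 1 / 3)
  expect_true(is.na(m$ppv) || m$ppv == 0)  # ppv = 0/2 defined here
  cmd <- confusion_matrix(c(1, 1), c(1, 1), 4)
  expect_true(is.na(binarized_metrics(cmd, 1:3)$specificity))
  expect_error(binarized_metrics(cm, 0:3), "subset")
})

test_that("all five metrics are 1 on a diagonal matrix and satisfy the accuracy identity", {
  cm <- confusion_matrix(rep(0:3, c(5, 2, 3, 1)), rep(0:3, c(5, 2, 3, 1)),
                         4)
  m <- binarized_metrics(cm, 1:3)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
  set.seed(9)
  for (rep in 1:10) {
    tr <- sample(0:3, 60, replace = TRUE)
    pr <- sample(0:3, 60, replace = TRUE)
    cmr <- confusion_matrix(tr, pr, 4)
    m1 <- binarized_metrics(cmr, 1:3)
    npos <- sum(tr >= 1); nneg <- sum(tr == 0)
    # weighted sensitivity of the positive set and its complement = accuracy
    expect_equal((m1$sensitivity * npos + m1$specificity * nneg) /
                   (npos + nneg), m1$accuracy)
  }
})

test_that("rank-based AUC equals exhaustive pair counting and honours ties", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_warning(res <- auc_score(c(1, 1), c(0.3, 0.5)), "one class")
  expect_true(is.na(res))
  set.seed(4)
  y <- rbinom(50, 1, 0.4)
  if (sum(y) == 0 || sum(y) == 50) y[1:2] <- c(0, 1)
  s <- round(runif(50), 1)  # coarse scores force ties
  pairs <- 0; tot <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    tot <- tot + 1
    pairs <- pairs + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(auc_score(y, s), pairs / tot)
  # invariance under strictly monotone transforms
  expect_equal(auc_score(y, exp(3 * s)), auc_score(y, s))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rbinom(80, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(80)
  expect_equal(auc_score(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("DG1 exclusion drops true-1 cells and re-bins predicted 1 by score", {
  # identity when no grade-1 labels or predictions appear
  out <- exclude_dg1_rebin(c(0, 2, 3), c(0.2, 1.8, 2.9), c(0, 2, 3))
  expect_equal(out$true, c(0, 2, 3))
  expect_equal(out$pred, c(0, 2, 3))
  # re-binning around the score threshold 1.0
  out2 <- exclude_dg1_rebin(c(0, 0), c(0.8, 1.3), c(1, 1))
  expect_equal(out2$pred, c(0, 2))
  # hand-computed mixed fixture
  tr <- c(0, 1, 2, 3, 0, 1, 2, 0, 3, 2)
  sc <- c(0.4, 1.2, 2.1, 2.8, 0.9, 0.3, 1.4, 1.6, 3.0, 0.2)
  fg <- c(0, 1, 2, 3, 1, 0, 1, 1, 3, 0)
  out3 <- exclude_dg1_rebin(tr, sc, fg)
  keep <- tr != 1
  expect_equal(out3$true, tr[keep])
  expect_equal(out3$pred, c(0, 2, 3, 0, 2, 2, 3, 0))
  # cells with neither side at grade 1 are untouched
  expect_equal(out3$pred[out3$true %in% c(0, 2, 3) & fg[keep] != 1],
               fg[keep][fg[keep] != 1])
})

test_that("discrepancy reports list severe misgrades on both sides", {
  ref <- reference_confusion()
  rep2 <- discrepancy_report(ref$true, ref$pred, min_diff = 2)
  expect_equal(rep2$n_false_negative, 9L)  # 6 + 1 + 2 severe misses
  expect_equal(discrepancy_report(0:3, 0:3, 2)$n_false_negative, 0L)
  expect_equal(discrepancy_report(0:3, 0:3, 2)$n_false_positive, 0L)
  set.seed(12)
  tr <- sample(0:3, 80, replace = TRUE)
  pr <- sample(0:3, 80, replace = TRUE)
  r <- discrepancy_report(tr, pr, min_diff = 2)
  expect_equal(r$n_false_negative, sum(tr - pr >= 2))
  expect_equal(r$n_false_positive, sum(pr - tr >= 2))
  expect_true(all(diff(r$false_negative$diff) <= 0))
  expect_error(discrepancy_report(tr, pr, min_diff = 0), "min_diff")
})
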