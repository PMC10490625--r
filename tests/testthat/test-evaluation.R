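# Brute-force counting oracle: per-class precision/recall/F1 computed
# instance by instance, independent of the confusion-matrix path.
brute_metrics <- function(truth, pred, classes) {
  out <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  })
  do.call(rbind, out)
}

# Mann-Whitney U oracle for AUC, ties counted half.
mw_auc <- function(pos_scores, neg_scores) {
  u <- 0
  for (p in pos_scores)
    u <- u + sum(p > neg_scores) + 0.5 * sum(p == neg_scores)
  u / (length(pos_scores) * length(neg_scores))
}

test_that("the confusion matrix counts true/predicted pairs", {
  cls <- c("a", "b", "c")
  cm <- confusion(c("a", "b", "c"), c("a", "b", "c"), cls)
  expect_equal(diag(cm), c(a = 1L, b = 1L, c = 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  cm2 <- confusion(c("a", "b", "c", "a"), rep("b", 4), cls)
  expect_true(all(cm2[, c("a", "c")] == 0))
  expect_equal(sum(cm2[, "b"]), 4L)

  cm3 <- confusion(c("a", "a", "a", "b", "b", "b"),
                   c("a", "a", "b", "b", "b", "a"), c("a", "b"))
  expect_equal(unname(cm3), matrix(c(2L, 1L, 1L, 2L), 2))
  expect_error(confusion("a", "z", cls), "z")
})

test_that("metrics reproduce the hand-computed binary toy", {
  # TP = 3, FP = 1, FN = 1, TN = 5 for class "pos"
  cm <- confusion(truth = c(rep("pos", 4), rep("neg", 6)),
                  predicted = c("pos", "pos", "pos", "neg",
                                "pos", rep("neg", 5)),
                  classes = c("pos", "neg"))
  m <- classification_metrics(cm)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.75)
  expect_equal(pos$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
})

test_that("F1 reproduces printed two-decimal worked examples", {
  expect_equal(round(f1_score(0.77, 0.71), 2), 0.74)
  expect_equal(round(f1_score(0.88, 0.85), 2), 0.86)
})

test_that("metrics agree exactly with brute-force counting on random data", {
  classes <- activity_classes()
  withr::with_seed(42, {
    for (rep in 1:50) {
      n <- sample(20:60, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      m <- classification_metrics(confusion(truth, pred, classes))
      oracle <- brute_metrics(truth, pred, classes)
      expect_equal(m$per_class$precision, unname(oracle[, "precision"]))
      expect_equal(m$per_class$recall, unname(oracle[, "recall"]))
      expect_equal(m$per_class$f1, unname(oracle[, "f1"]))
      expect_equal(m$accuracy, mean(truth == pred))
    }
  })
})

test_that("weighted-average F1 lies between the per-class extremes", {
  withr::with_seed(7, {
    truth <- sample(activity_classes(), 200, replace = TRUE)
    pred <- ifelse(runif(200) < 0.6, truth,
                   sample(activity_classes(), 200, replace = TRUE))
  })
  m <- classification_metrics(confusion(truth, pred, activity_classes()))
  expect_gte(m$weighted_avg[["f1"]], min(m$per_class$f1))
  expect_lte(m$weighted_avg[["f1"]], max(m$per_class$f1))
})

test_that("ROC/AUC handles the perfect, tied and degenerate cases", {
  truth <- c(rep("pos", 3), rep("neg", 3))
  probs <- cbind(pos = c(.9, .8, .7, .3, .2, .1),
                 neg = 1 - c(.9, .8, .7, .3, .2, .1))
  r <- roc_auc(truth, probs)
  expect_equal(r$per_class$pos$auc, 1)

  tied <- cbind(pos = rep(0.5, 6), neg = rep(0.5, 6))
  expect_equal(roc_auc(truth, tied)$per_class$pos$auc, 0.5)

  degen <- roc_auc(rep("pos", 4), cbind(pos = runif(4), neg = runif(4)))
  expect_true(is.na(degen$per_class$neg$auc))
  expect_true("neg" %in% degen$degenerate)
})

test_that("trapezoid AUC equals the normalized Mann-Whitney U, including ties", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      n_pos <- sample(5:30, 1); n_neg <- sample(5:30, 1)
      # coarse score grid forces plenty of ties
      scores <- sample(seq(0, 1, by = 0.1), n_pos + n_neg, replace = TRUE)
      truth <- c(rep("pos", n_pos), rep("neg", n_neg))
      probs <- cbind(pos = scores, neg = 1 - scores)
      auc <- roc_auc(truth, probs)$per_class$pos$auc
      expect_equal(auc, mw_auc(scores[1:n_pos],
                               scores[(n_pos + 1):(n_pos + n_neg)]),
                   tolerance = 1e-9)
    }
  })
})

test_that("AUC of random scores on balanced labels is near chance", {
  withr::with_seed(3, {
    truth <- rep(c("pos", "neg"), each = 100)
    probs <- cbind(pos = runif(200), neg = runif(200))
  })
  auc <- roc_auc(truth, probs)$per_class$pos$auc
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)
})

test_that("AUC agrees with an established implementation on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    truth <- sample(c("pos", "neg"), 80, replace = TRUE)
    scores <- runif(80)
  })
  mine <- roc_auc(truth, cbind(pos = scores, neg = 1 - scores))
  ref <- pROC::auc(pROC::roc(response = truth, predictor = scores,
                             levels = c("neg", "pos"), direction = "<",
                             quiet = TRUE))
  expect_equal(mine$per_class$pos$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("the text report mirrors the per-class table layout", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                  c("a", "b"))
  lines <- format_eval_table(classification_metrics(cm))
  expect_match(lines[1], "Accuracy = 75")
  expect_match(lines[2], "Precision")
  expect_length(lines, 2 + 2 + 1)
})
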