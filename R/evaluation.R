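# Evaluation surface: confusion matrix, per-class and weighted
# precision/recall/F1, overall accuracy, and one-vs-rest ROC/AUC.

#' Confusion matrix from label vectors
#'
#' @param truth,predicted Equal-length label vectors over `classes`.
#' @param classes Ordered class labels (default: the four activities).
#' @return Integer matrix (rows = true class, columns = predicted class)
#'   of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), classes)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' Per class (one-vs-rest): precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of the two; a zero denominator gives 0 (flagged in
#' the `zero_division` attribute). Overall accuracy is the diagonal total
#' over all instances. Weighted averages weight per-class metrics by
#' true-class support.
#'
#' @param cm A [confusion()] matrix.
#' @return List of class `eval_metrics`: `per_class` data.frame
#'   (precision, recall, f1, support), `accuracy`, `weighted_avg`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  zero_division <- classes[(tp + fp == 0) | (tp + fn == 0) |
                             (precision + recall == 0)]
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowSums(cm)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL)
  w <- support / total
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / total,
    weighted_avg = c(precision = sum(w * precision),
                     recall = sum(w * recall), f1 = sum(w * f1)),
    zero_division = zero_division,
    confusion = cm
  ), class = "eval_metrics")
}

#' F1 score from a precision/recall pair
#' @param precision,recall Scalars in `[0, 1]`.
#' @return Harmonic mean `2pr/(p+r)` (0 if both are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps thresholds over the unique predicted scores for
#' that class and accumulates (FPR, TPR) points; AUC is the trapezoid
#' integral, which equals the Mann-Whitney U statistic normalized by
#' (positives x negatives), ties counted half.
#'
#' @param truth Label vector.
#' @param probabilities Instances x classes score matrix with class
#'   column names (rows need not be normalized for the sweep itself).
#' @return List of class `roc_result`: per class a list with `curve`
#'   (data.frame fpr, tpr), `auc`; degenerate classes (no positive or no
#'   negative) get `auc = NA` and are named in `degenerate`.
#' @export
roc_auc <- function(truth, probabilities) {
  truth <- as.character(truth)
  classes <- colnames(probabilities)
  if (is.null(classes)) stop("probability matrix needs class column names")
  out <- list(); degenerate <- character(0)
  for (cl in classes) {
    pos <- truth == cl
    scores <- probabilities[, cl]
    if (!any(pos) || all(pos)) {
      out[[cl]] <- list(curve = NULL, auc = NA_real_)
      degenerate <- c(degenerate, cl)
      next
    }
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; p <- pos[ord]
    # cumulative counts at each unique-threshold boundary
    dup <- rev(duplicated(rev(s)))       # TRUE where next score identical
    tpc <- cumsum(p); fpc <- cumsum(!p)
    keep <- !dup
    tpr <- c(0, tpc[keep] / sum(pos))
    fpr <- c(0, fpc[keep] / sum(!pos))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    out[[cl]] <- list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  }
  structure(list(per_class = out, degenerate = degenerate),
            class = "roc_result")
}

#' Evaluate a trained model on a test table
#'
#' @param model A `trained_model`.
#' @param test Feature table with `label`.
#' @return List of class `eval_report`: `metrics` ([classification_metrics()]),
#'   `roc` ([roc_auc()]), `probabilities`, `predicted`.
#' @export
evaluate_model <- function(model, test) {
  probs <- predict_activity_proba(model, test)
  predicted <- colnames(probs)[max.col(probs, ties.method = "first")]
  cm <- confusion(test$label, predicted, classes = model$classes)
  structure(list(metrics = classification_metrics(cm),
                 roc = roc_auc(test$label, probs),
                 probabilities = probs,
                 predicted = predicted),
            class = "eval_report")
}

#' Render an evaluation report as a plain-text table
#'
#' Mirrors the per-class precision/recall/F1 layout with a weighted-average
#' row and the overall accuracy in the header.
#'
#' @param report An `eval_report` (or `eval_metrics`).
#' @return Character vector of lines, invisibly; printed when called
#'   interactively via `cat`.
#' @export
format_eval_table <- function(report) {
  m <- if (inherits(report, "eval_report")) report$metrics else report
  pc <- m$per_class
  lines <- c(
    sprintf("Accuracy = %.2f%%", 100 * m$accuracy),
    sprintf("%-18s %9s %9s %9s", "Activity Class", "Precision", "Recall",
            "F1-Score"),
    sprintf("%-18s %9.2f %9.2f %9.2f", pc$class, pc$precision, pc$recall,
            pc$f1),
    sprintf("%-18s %9.2f %9.2f %9.2f", "Weighted Average",
            m$weighted_avg["precision"], m$weighted_avg["recall"],
            m$weighted_avg["f1"])
  )
  invisible(lines)
}

# JSON-friendly view of an eval_report.
eval_report_to_list <- function(report) {
  m <- report$metrics
  aucs <- vapply(m$per_class$class, function(cl)
    report$roc$per_class[[cl]]$auc %||% NA_real_, numeric(1))
  list(accuracy = m$accuracy,
       per_class = cbind(m$per_class, auc = aucs),
       weighted_avg = as.list(m$weighted_avg),
       confusion = list(classes = rownames(m$confusion),
                        counts = unclass(m$confusion)))
}
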