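# Univariate feature selection and data splitting. The score is the
# one-way ANOVA F statistic of each feature across the activity labels,
# computed from its definition (between-group over within-group mean
# squares) and vectorized over features.

#' Score features by one-way ANOVA F across activity classes
#'
#' @param table Feature table (feature columns plus `label`).
#' @return List of class `selection_result`: `scores` (named, decreasing),
#'   and the full per-feature F values in table order. Constant features
#'   score 0; perfect separators (zero within-class variance, nonzero
#'   between) score `Inf` and rank first.
#' @export
score_features <- function(table) {
  stopifnot("label" %in% names(table))
  y <- table$label
  classes <- levels(droplevels(factor(y)))
  if (length(classes) < 2) stop("need at least 2 classes to score features")
  counts <- table(y)
  if (any(counts < 2))
    stop("class '", names(counts)[which(counts < 2)[1]],
         "' has fewer than 2 rows")
  X <- as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  n <- nrow(X); k <- length(classes)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(Xi, 2, mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb <= 1e-24 & ssw <= 1e-24] <- 0        # constant feature
  names(f) <- colnames(X)
  structure(list(scores = sort(f, decreasing = TRUE), f = f,
                 classes = classes), class = "selection_result")
}

#' Keep the k highest-scoring features
#'
#' Ties are broken by the fixed feature-table column order, so selection is
#' reproducible. `k` larger than the number of features keeps everything
#' with a warning.
#'
#' @param table Feature table.
#' @param result A `selection_result` from [score_features()] (computed on
#'   `table` if omitted — fit it on the training partition only to avoid
#'   leakage).
#' @param k Number of features to keep (default 20).
#' @return The table restricted to the selected features plus `label`;
#'   attribute `selected` lists them in rank order.
#' @export
select_top_k <- function(table, result = score_features(table), k = 20) {
  stopifnot(k >= 1)
  fcols <- setdiff(names(table), "label")
  f <- result$f[fcols]
  if (k > length(fcols)) {
    warning("k = ", k, " exceeds the ", length(fcols),
            " available features; keeping all")
    k <- length(fcols)
  }
  # rank by score, ties by column order (order() is stable)
  ord <- order(-f, seq_along(f))
  selected <- fcols[ord[seq_len(k)]]
  out <- table[, c(selected, "label"), drop = FALSE]
  attr(out, "selected") <- selected
  attr(out, "scores") <- f[selected]
  out
}

#' Stratified train/test split
#'
#' Samples `test_fraction` of each class (rounded) into the test set, so
#' class proportions are preserved within one instance per class.
#' Deterministic given `seed`.
#'
#' @param table Feature table with a `label` column.
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` data.frames.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = 1) {
  stopifnot_scalar_number(test_fraction, "test_fraction", lower = 1e-9,
                          upper = 1 - 1e-9)
  y <- table$label
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      n_test <- round(test_fraction * length(idx))
      if (n_test < 1 || n_test >= length(idx))
        stop("class '", cl, "' too small for a ", test_fraction, " split")
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# Stratified, disjoint, exhaustive fold assignment over rows of `y`.
stratified_folds <- function(y, folds, seed = 1) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      if (length(idx) < folds)
        stop("class '", cl, "' has fewer rows (", length(idx),
             ") than folds (", folds, ")")
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}
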