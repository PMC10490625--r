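# Ensemble tree classifiers: random forest (ranger), gradient boosting and
# extreme gradient boosting (both via xgboost; the plain gradient-boosting
# family runs unregularized with the classical 0.1 learning rate, the
# extreme variant keeps xgboost's regularized defaults).

MODEL_FAMILIES <- c("random_forest", "gradient_boosting",
                    "extreme_gradient_boosting")

#' Model specification
#'
#' @param family One of `"random_forest"`, `"gradient_boosting"`,
#'   `"extreme_gradient_boosting"`.
#' @param n_estimators Number of trees / boosting rounds (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param seed Integer seed for the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, n_estimators, max_depth,
                       seed = 1) {
  family <- match.arg(family)
  stopifnot_scalar_number(n_estimators, "n_estimators", lower = 1)
  stopifnot_scalar_number(max_depth, "max_depth", lower = 1)
  structure(list(family = family, n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)), class = "model_spec")
}

# Reference operating points reported for each family on the study-scale
# problem; the default grids always contain them.
reference_spec <- function(family) {
  switch(family,
         random_forest = c(n = 98L, depth = 21L),
         gradient_boosting = c(n = 50L, depth = 8L),
         extreme_gradient_boosting = c(n = 83L, depth = 10L))
}

#' Default hyperparameter grid for a model family
#'
#' Grids span the canonical search ranges (random forest and extreme
#' gradient boosting: 1--100 estimators x depth 1--30; gradient boosting:
#' 1--50 estimators x depth 1--14), thinned by the strides for desk-scale
#' runs. The family's reference operating point (98/21, 50/8, 83/10) is
#' always included.
#'
#' @param family Model family name.
#' @param n_stride,depth_stride Strides through the estimator and depth
#'   ranges (default 1 = exhaustive).
#' @return data.frame with columns `n_estimators`, `max_depth`.
#' @export
default_grid <- function(family = MODEL_FAMILIES, n_stride = 1,
                         depth_stride = 1) {
  family <- match.arg(family)
  rng <- switch(family,
                random_forest = list(n = 100L, depth = 30L),
                gradient_boosting = list(n = 50L, depth = 14L),
                extreme_gradient_boosting = list(n = 100L, depth = 30L))
  ref <- reference_spec(family)
  ns <- sort(unique(c(seq(n_stride, rng$n, by = n_stride), ref[["n"]])))
  ds <- sort(unique(c(seq(depth_stride, rng$depth, by = depth_stride),
                      ref[["depth"]])))
  expand.grid(n_estimators = ns, max_depth = ds, KEEP.OUT.ATTRS = FALSE)
}

fit_one <- function(X, y, spec) {
  classes <- levels(y)
  if (length(classes) < 2) stop("single-class training data")
  if (spec$family == "random_forest") {
    fit <- ranger::ranger(x = as.data.frame(X), y = y,
                          num.trees = spec$n_estimators,
                          max.depth = spec$max_depth,
                          probability = TRUE, seed = spec$seed,
                          num.threads = 1)
    list(engine = "ranger", fit = fit, classes = classes)
  } else {
    eta <- if (spec$family == "gradient_boosting") 0.1 else 0.3
    lambda <- if (spec$family == "gradient_boosting") 0 else 1
    dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                   label = as.integer(y) - 1L)
    params <- list(objective = "multi:softprob",
                   num_class = length(classes),
                   max_depth = spec$max_depth, eta = eta, lambda = lambda,
                   nthread = 1, seed = spec$seed)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = spec$n_estimators, verbose = 0)
    list(engine = "xgboost", fit = fit, classes = classes)
  }
}

#' Train a classifier on a feature table
#'
#' @param train Feature table (feature columns plus `label`).
#' @param spec A [model_spec()].
#' @return Object of class `trained_model` exposing class probabilities via
#'   [predict_activity_proba()] and labels via `predict()`.
#' @export
train_model <- function(train, spec) {
  stopifnot(inherits(spec, "model_spec"))
  fcols <- setdiff(names(train), "label")
  y <- droplevels(factor(train$label))
  fitted <- fit_one(train[, fcols, drop = FALSE], y, spec)
  structure(list(spec = spec, feature_names = fcols,
                 classes = fitted$classes, engine = fitted$engine,
                 fit = fitted$fit,
                 train_stats = list(
                   mean = colMeans(train[, fcols, drop = FALSE]),
                   sd = apply(train[, fcols, drop = FALSE], 2, stats::sd),
                   quartiles = apply(train[, fcols, drop = FALSE], 2,
                                     stats::quantile,
                                     probs = c(.25, .5, .75)))),
            class = "trained_model")
}

#' Class-probability predictions of a trained model
#'
#' @param model A `trained_model`.
#' @param newdata data.frame or matrix with the model's feature columns.
#' @return Matrix instances x classes; rows sum to 1.
#' @export
predict_activity_proba <- function(model, newdata) {
  stopifnot(inherits(model, "trained_model"))
  missing <- setdiff(model$feature_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  X <- newdata[, model$feature_names, drop = FALSE]
  if (model$engine == "ranger") {
    p <- predict(model$fit, as.data.frame(X),
                 num.threads = 1)$predictions
    p <- p[, model$classes, drop = FALSE]
  } else {
    p <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(X)))
    if (!is.matrix(p)) p <- matrix(p, ncol = length(model$classes),
                                   byrow = TRUE)
    colnames(p) <- model$classes
  }
  p
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  p <- predict_activity_proba(object, newdata)
  factor(colnames(p)[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Tune n_estimators and max_depth by stratified cross-validation
#'
#' Evaluates every grid row by mean k-fold cross-validated accuracy on the
#' training table and returns the best spec. Ties favor the smaller model:
#' fewer estimators, then shallower trees.
#'
#' @param train Training feature table.
#' @param family Model family.
#' @param grid data.frame of `n_estimators`, `max_depth` (default: the
#'   family's [default_grid()]).
#' @param folds Number of CV folds (default 10).
#' @param seed Seed controlling fold assignment and fits.
#' @return The winning [model_spec()]; attributes `cv_accuracy` (per grid
#'   row) and `folds` record the search.
#' @export
tune_hyperparameters <- function(train, family = MODEL_FAMILIES,
                                 grid = NULL, folds = 10, seed = 1) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family, n_stride = 25,
                                          depth_stride = 7)
  stopifnot(nrow(grid) >= 1, folds >= 2)
  y <- droplevels(factor(train$label))
  fold_of <- stratified_folds(y, folds, seed)
  fcols <- setdiff(names(train), "label")
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    spec <- model_spec(family, grid$n_estimators[g], grid$max_depth[g],
                       seed = seed)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- train[fold_of != f, , drop = FALSE]
      te <- train[fold_of == f, , drop = FALSE]
      m <- train_model(tr, spec)
      correct <- correct + sum(predict(m, te) == te$label)
    }
    acc[g] <- correct / nrow(train)
  }
  best <- order(-acc, grid$n_estimators, grid$max_depth)[1]
  log_stage("tune", sprintf("%s: best n=%d depth=%d (CV accuracy %.4f)",
                            family, grid$n_estimators[best],
                            grid$max_depth[best], acc[best]))
  out <- model_spec(family, grid$n_estimators[best], grid$max_depth[best],
                    seed = seed)
  attr(out, "cv_accuracy") <- cbind(grid, accuracy = acc)
  attr(out, "folds") <- folds
  out
}

#' Pooled out-of-fold class probabilities
#'
#' Refits the spec on each training fold and predicts the held-out fold,
#' yielding one out-of-fold probability row per training instance (the
#' basis for cross-validated ROC curves).
#'
#' @param train Training feature table.
#' @param spec A [model_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return Matrix rows = instances of `train`, columns = classes.
#' @export
cv_probabilities <- function(train, spec, folds = 10, seed = 1) {
  y <- droplevels(factor(train$label))
  fold_of <- stratified_folds(y, folds, seed)
  probs <- matrix(NA_real_, nrow(train), length(levels(y)),
                  dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    m <- train_model(train[fold_of != f, , drop = FALSE], spec)
    probs[fold_of == f, ] <-
      predict_activity_proba(m, train[fold_of == f, , drop = FALSE])
  }
  probs
}
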