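# From-scratch tabular local-surrogate (LIME-style) explainer: perturb an
# instance with Gaussian noise scaled by the training-data spread, weight
# perturbations by an exponential proximity kernel in standardized units,
# fit a proximity-weighted ridge regression of the black-box class
# probability, keep the K largest standardized coefficients, and refit on
# the kept set. The explanation minimizes the proximity-weighted loss under
# a hard K-feature sparsity constraint.

#' Explainer configuration
#'
#' @param n_samples Number of perturbations (default 5000, minimum 10).
#' @param kernel_width Proximity kernel scale in standardized distance
#'   units; default `0.75 * sqrt(d)` with `d` the feature count.
#' @param num_features Number K of features retained in the explanation
#'   (default 10).
#' @param ridge_penalty Nonnegative ridge regularizer (default 0.01).
#' @param seed RNG seed for the perturbations.
#' @return An object of class `lime_config`.
#' @export
lime_config <- function(n_samples = 5000, kernel_width = NULL,
                        num_features = 10, ridge_penalty = 0.01,
                        seed = 1) {
  stopifnot_scalar_number(n_samples, "n_samples", lower = 10)
  if (!is.null(kernel_width))
    stopifnot_scalar_number(kernel_width, "kernel_width", lower = 1e-12)
  stopifnot_scalar_number(num_features, "num_features", lower = 1)
  stopifnot_scalar_number(ridge_penalty, "ridge_penalty", lower = 0)
  structure(list(n_samples = as.integer(n_samples),
                 kernel_width = kernel_width,
                 num_features = as.integer(num_features),
                 ridge_penalty = ridge_penalty,
                 seed = as.integer(seed)), class = "lime_config")
}

#' Perturb an instance using training-data statistics
#'
#' Each perturbation draws every feature from a normal law centered on the
#' instance's value with the training-set spread (features with zero
#' spread stay fixed). The proximity weight of a sample is
#' `exp(-D^2 / kernel_width^2)` with `D` the Euclidean distance to the
#' instance in standardized units. The unperturbed instance is always the
#' first sample, with weight exactly 1.
#'
#' @param instance Named numeric feature vector.
#' @param train_stats List with named vectors `mean` and `sd` from the
#'   model's training partition.
#' @param config A [lime_config()].
#' @return List with `samples` (n_samples x d matrix) and `weights`.
#' @export
sample_perturbations <- function(instance, train_stats, config) {
  d <- length(instance)
  sds <- train_stats$sd[names(instance)]
  if (any(is.na(sds))) stop("train_stats lacks a spread for some features")
  if (any(sds < 0)) stop("negative spreads are invalid")
  kw <- config$kernel_width %||% (0.75 * sqrt(d))
  with_seed(config$seed, {
    noise <- matrix(stats::rnorm(config$n_samples * d), config$n_samples,
                    d)
    noise <- sweep(noise, 2, sds, `*`)
    noise[1, ] <- 0                       # the instance itself
    samples <- sweep(noise, 2, as.numeric(instance), `+`)
    colnames(samples) <- names(instance)
    z <- sweep(noise, 2, ifelse(sds > 0, sds, 1), `/`)
    d2 <- rowSums(z^2)
    weights <- exp(-d2 / kw^2)
    list(samples = samples, weights = weights, kernel_width = kw)
  })
}

# Weighted ridge with unpenalized intercept on standardized predictors.
weighted_ridge <- function(Z, w, y, lambda) {
  wm <- function(v) sum(w * v) / sum(w)
  yc <- y - wm(y)
  Zc <- sweep(Z, 2, apply(Z, 2, wm))
  A <- crossprod(Zc * w, Zc) + diag(lambda, ncol(Z))
  b <- crossprod(Zc * w, yc)
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) {
    # singular system: documented fallback — raise the penalty once
    A <- crossprod(Zc * w, Zc) + diag(max(lambda, 1e-8) * 100, ncol(Z))
    beta <- solve(A, b)
  }
  intercept <- wm(y) - sum(apply(Z, 2, wm) * beta)
  fitted <- as.numeric(Z %*% beta) + intercept
  ss_res <- sum(w * (y - fitted)^2)
  ss_tot <- sum(w * (y - wm(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(coefficients = as.numeric(beta), intercept = intercept, r2 = r2)
}

#' Fit the sparse local surrogate
#'
#' Fits a proximity-weighted ridge of the black-box probability on all
#' standardized features, keeps the `num_features` largest absolute
#' standardized coefficients, and refits the weighted ridge on the kept
#' set.
#'
#' @param samples Perturbation matrix from [sample_perturbations()].
#' @param weights Proximity weights.
#' @param y Black-box probability of the target class for every sample.
#' @param config A [lime_config()].
#' @param train_stats Training means and spreads used to standardize.
#' @return List: `coefficients` (named, standardized units, only the kept
#'   features), `intercept`, `r2` (weighted; `NA` for a constant target).
#' @export
fit_local_surrogate <- function(samples, weights, y, config, train_stats) {
  fnames <- colnames(samples)
  sds <- train_stats$sd[fnames]
  mus <- train_stats$mean[fnames]
  Z <- sweep(sweep(samples, 2, mus), 2, ifelse(sds > 0, sds, 1), `/`)
  if (stats::var(y) == 0)
    return(list(coefficients = stats::setNames(numeric(ncol(Z)), fnames)[
      seq_len(min(config$num_features, ncol(Z)))],
      intercept = y[1], r2 = NA_real_))
  full <- weighted_ridge(Z, weights, y, config$ridge_penalty)
  k <- min(config$num_features, ncol(Z))
  keep <- order(-abs(full$coefficients), seq_len(ncol(Z)))[seq_len(k)]
  refit <- weighted_ridge(Z[, keep, drop = FALSE], weights, y,
                          config$ridge_penalty)
  list(coefficients = stats::setNames(refit$coefficients, fnames[keep]),
       intercept = refit$intercept, r2 = refit$r2)
}

# Render the instance's value relative to the training quartiles as the
# threshold condition shown next to each contribution.
quartile_condition <- function(feature, value, quartiles) {
  q <- quartiles[, feature]
  if (value <= q[1]) sprintf("%s <= %.3g", feature, q[1])
  else if (value <= q[2]) sprintf("%.3g < %s <= %.3g", q[1], feature, q[2])
  else if (value <= q[3]) sprintf("%.3g < %s <= %.3g", q[2], feature, q[3])
  else sprintf("%s > %.3g", feature, q[3])
}

#' Explain one prediction of a trained model
#'
#' Generates perturbations around the instance, queries the black box for
#' class probabilities, fits the sparse local surrogate for the predicted
#' class, and reports signed feature contributions ordered by magnitude,
#' each rendered with the instance's position relative to the training
#' quartiles.
#'
#' @param model A `trained_model`.
#' @param instance One-row data.frame or named vector with the model's
#'   features.
#' @param config A [lime_config()].
#' @param target_class Class to explain; default the model's prediction.
#' @return Object of class `explanation`: `predicted_class`,
#'   `class_probabilities`, `contributions` (data.frame feature, weight,
#'   condition), `intercept`, `local_fidelity_r2`.
#' @export
explain_instance <- function(model, instance, config = lime_config(),
                             target_class = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (is.data.frame(instance)) {
    stopifnot(nrow(instance) == 1)
    instance <- unlist(instance[, setdiff(names(instance), "label"),
                                drop = FALSE])
  }
  extra <- setdiff(names(instance), model$feature_names)
  missing <- setdiff(model$feature_names, names(instance))
  if (length(missing) || length(extra))
    stop("feature-name mismatch; missing: {",
         paste(missing, collapse = ", "), "} extra: {",
         paste(extra, collapse = ", "), "}")
  instance <- instance[model$feature_names]
  probs <- predict_activity_proba(model, t(as.matrix(instance)))[1, ]
  predicted <- names(probs)[which.max(probs)]
  target_class <- target_class %||% predicted
  pert <- sample_perturbations(instance, model$train_stats, config)
  bb <- predict_activity_proba(model, pert$samples)[, target_class]
  fit <- fit_local_surrogate(pert$samples, pert$weights, bb, config,
                             model$train_stats)
  ord <- order(-abs(fit$coefficients))
  feats <- names(fit$coefficients)[ord]
  contributions <- data.frame(
    feature = feats,
    weight = as.numeric(fit$coefficients[ord]),
    condition = vapply(feats, function(f)
      quartile_condition(f, instance[[f]], model$train_stats$quartiles),
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(predicted_class = predicted,
                 target_class = target_class,
                 class_probabilities = probs,
                 contributions = contributions,
                 intercept = fit$intercept,
                 local_fidelity_r2 = fit$r2),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> predicted %s (p = %.2f); surrogate R2 = %s\n",
              x$predicted_class,
              x$class_probabilities[[x$predicted_class]],
              ifelse(is.na(x$local_fidelity_r2), "NA",
                     sprintf("%.3f", x$local_fidelity_r2))))
  for (i in seq_len(nrow(x$contributions)))
    cat(sprintf("  %+8.4f  %s\n", x$contributions$weight[i],
                x$contributions$condition[i]))
  invisible(x)
}
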