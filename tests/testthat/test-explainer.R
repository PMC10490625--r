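toy_stats <- function(d, mean = 0, sd = 1) {
  nm <- paste0("f", seq_len(d))
  list(mean = stats::setNames(rep(mean, d), nm),
       sd = stats::setNames(rep(sd, d), nm))
}

test_that("perturbation weights follow the proximity kernel", {
  d <- 4
  inst <- stats::setNames(rep(0, d), paste0("f", 1:d))
  cfg <- lime_config(n_samples = 50, kernel_width = 2, seed = 1)
  pert <- sample_perturbations(inst, toy_stats(d), cfg)
  expect_identical(pert$weights[1], 1)              # the instance itself
  expect_equal(pert$samples[1, ], inst)
  # a sample at standardized distance = kernel_width has weight exp(-1)
  z <- sqrt(rowSums(pert$samples^2))
  w_expected <- exp(-z^2 / 4)
  expect_equal(pert$weights, w_expected)
  expect_equal(exp(-1), 0.3679, tolerance = 1e-4)
})

test_that("perturbations are centered on the instance with the training spread", {
  d <- 3
  inst <- stats::setNames(c(2, -1, 0.5), paste0("f", 1:3))
  stats3 <- list(mean = stats::setNames(rep(0, 3), names(inst)),
                 sd = stats::setNames(c(1, 2, 0), names(inst)))
  pert <- sample_perturbations(inst, stats3,
                               lime_config(n_samples = 5000, seed = 2))
  se <- c(1, 2, 0) / sqrt(5000)
  for (j in 1:2)
    expect_lt(abs(mean(pert$samples[, j]) - inst[j]), 3 * se[j] + 1e-12)
  # zero-spread features stay fixed
  expect_true(all(pert$samples[, 3] == inst[3]))
})

test_that("a constant black box yields zero coefficients and flagged fidelity", {
  d <- 5
  inst <- stats::setNames(rep(0, d), paste0("f", 1:d))
  cfg <- lime_config(n_samples = 100, num_features = 3, seed = 1)
  pert <- sample_perturbations(inst, toy_stats(d), cfg)
  fit <- fit_local_surrogate(pert$samples, pert$weights,
                             rep(0.42, nrow(pert$samples)), cfg,
                             toy_stats(d))
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, 0.42)
  expect_true(is.na(fit$r2))
})

test_that("the surrogate recovers a linear black box with high fidelity", {
  d <- 6
  inst <- stats::setNames(rep(0.5, d), paste0("f", 1:d))
  cfg <- lime_config(n_samples = 2000, num_features = 3, seed = 3)
  st <- toy_stats(d)
  pert <- sample_perturbations(inst, st, cfg)
  w_true <- c(2, -1, 0.5, 0, 0, 0)
  y <- as.numeric(pert$samples %*% w_true)
  fit <- fit_local_surrogate(pert$samples, pert$weights, y, cfg, st)
  expect_equal(names(fit$coefficients)[1], "f1")
  expect_setequal(names(fit$coefficients), c("f1", "f2", "f3"))
  expect_gte(fit$r2, 0.99)
  # standardized coefficient signs match the generating weights
  expect_equal(sign(fit$coefficients[c("f1", "f2", "f3")]),
               c(f1 = 1, f2 = -1, f3 = 1))
})

test_that("a single-feature black box ranks that feature first", {
  d <- 8
  inst <- stats::setNames(rep(0, d), paste0("f", 1:d))
  cfg <- lime_config(n_samples = 1000, num_features = 2, seed = 4)
  st <- toy_stats(d)
  pert <- sample_perturbations(inst, st, cfg)
  y <- plogis(3 * pert$samples[, "f5"])
  fit <- fit_local_surrogate(pert$samples, pert$weights, y, cfg, st)
  expect_equal(names(fit$coefficients)[1], "f5")
  expect_gt(fit$coefficients[["f5"]], 0)
})

test_that("explanations of a fitted model are deterministic and complete", {
  tab <- make_separable_table(n_per_class = 20, n_features = 5, seed = 5)
  m <- train_model(tab, model_spec("random_forest", 50, 8, seed = 1))
  inst <- tab[1, ]
  cfg <- lime_config(n_samples = 500, num_features = 5, seed = 6)
  e1 <- explain_instance(m, inst, cfg)
  e2 <- explain_instance(m, inst, cfg)
  expect_identical(e1$contributions, e2$contributions)
  expect_equal(sum(e1$class_probabilities), 1, tolerance = 1e-6)
  # num_features = d covers every feature
  expect_setequal(e1$contributions$feature, paste0("feat", 1:5))
  expect_equal(nrow(e1$contributions), 5)
  expect_match(e1$contributions$condition[1], "feat")
})

test_that("features the model ignores stay below the top-K cut", {
  # feat1-feat3 carry equal class signal, feat4/feat5 are pure noise; the
  # noise features must fall outside the K kept features. Explained
  # instances come from the extreme classes, where the class-probability
  # surface is locally monotone and the surrogate's linear terms carry the
  # informative features' full signal.
  withr::with_seed(6, {
    classes <- activity_classes()
    rows <- lapply(seq_along(classes), function(ci) {
      X <- matrix(rnorm(25 * 5), 25)
      X[, 1:3] <- X[, 1:3] + 4 * ci
      X
    })
    X <- do.call(rbind, rows)
    colnames(X) <- paste0("feat", 1:5)
    tab <- as.data.frame(X)
    tab$label <- factor(rep(classes, each = 25))
  })
  m <- train_model(tab, model_spec("random_forest", 150, 4, seed = 2))
  cfg <- lime_config(n_samples = 5000, num_features = 3, seed = 7)
  edge_rows <- c(seq(2, 20, by = 2), seq(82, 100, by = 2))
  below <- 0
  for (i in edge_rows) {
    ex <- explain_instance(m, tab[i, ], cfg)
    if (!any(c("feat4", "feat5") %in% ex$contributions$feature))
      below <- below + 1
  }
  expect_gte(below / length(edge_rows), 0.9)
})

test_that("feature-name mismatches are reported with the symmetric difference", {
  tab <- make_separable_table(n_per_class = 10, n_features = 3)
  m <- train_model(tab, model_spec("random_forest", 10, 3))
  bad <- stats::setNames(rep(0, 3), c("feat1", "feat2", "wrong"))
  expect_error(explain_instance(m, bad), "wrong")
  expect_error(explain_instance(m, bad), "feat3")
})
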