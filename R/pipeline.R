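# End-to-end orchestration: simulate/ingest -> preprocess -> features ->
# select -> tune/train -> evaluate -> explain, with a provenance manifest
# whose row counts must reconcile exactly.

#' Pipeline configuration
#'
#' Aggregates every stage's parameters with the analysis defaults: 60 Hz
#' notch, 0.5--44 Hz band-pass, 25 dB SNR threshold, 10-s epochs, top-20
#' feature selection, 80/20 stratified split, 10-fold tuning. All
#' parameters are validated before any computation starts.
#'
#' @param input Path to a recording (`.edf`/`.csv`) or `NULL` to simulate.
#' @param simulation A [simulation_config()] used when `input` is `NULL`.
#' @param notch_hz,band_pass,snr_threshold_db,epoch_length_s Preprocessing
#'   parameters.
#' @param bands,welch Feature parameters.
#' @param k Number of selected features.
#' @param family Model family to tune and train.
#' @param grid Optional tuning grid; default is the family grid thinned
#'   for desk-scale runs.
#' @param folds CV folds.
#' @param test_fraction Held-out fraction.
#' @param n_explanations Number of test instances to explain.
#' @param lime A [lime_config()].
#' @param seed Global seed, expanded deterministically into per-stage
#'   seeds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            notch_hz = 60, band_pass = c(0.5, 44),
                            snr_threshold_db = 25, epoch_length_s = 10,
                            bands = eeg_bands(), welch = welch_params(),
                            k = 20, family = "random_forest",
                            grid = NULL, folds = 10, test_fraction = 0.2,
                            n_explanations = 4, lime = lime_config(),
                            seed = 1) {
  stopifnot_scalar_number(notch_hz, "notch_hz", lower = 1)
  stopifnot_scalar_number(snr_threshold_db, "snr_threshold_db")
  stopifnot_scalar_number(epoch_length_s, "epoch_length_s", lower = 1e-9)
  stopifnot_scalar_number(k, "k", lower = 1)
  stopifnot_scalar_number(test_fraction, "test_fraction", lower = 1e-9,
                          upper = 1 - 1e-9)
  stopifnot_scalar_number(folds, "folds", lower = 2)
  stopifnot(length(band_pass) == 2, band_pass[1] < band_pass[2])
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(input) && is.null(simulation))
    simulation <- simulation_config(seed = stage_seeds(seed)$simulate)
  structure(list(input = input, simulation = simulation,
                 notch_hz = notch_hz, band_pass = band_pass,
                 snr_threshold_db = snr_threshold_db,
                 epoch_length_s = epoch_length_s, bands = bands,
                 welch = welch, k = k, family = family, grid = grid,
                 folds = folds, test_fraction = test_fraction,
                 n_explanations = n_explanations, lime = lime,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full pipeline and write a run directory
#'
#' Executes every stage in order and writes `features.csv` (+ JSON
#' sidecar), `model_manifest.json`, `evaluation.json`, `evaluation.txt`,
#' `explanations.json` and `manifest.json` into `out_dir`. The manifest
#' records all parameters, per-stage seeds and row counts; the counts
#' satisfy epochs = kept + rejected and feature rows = kept - dropped.
#' Re-running with the same config reproduces all numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the run artifacts (`features`, `model`,
#'   `evaluation`, `explanations`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("eeg_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage("pipeline", "stage 1/7: ",
            if (is.null(config$input)) "simulate" else "ingest")
  recording <- if (is.null(config$input)) {
    generate_recording(config$simulation)
  } else read_recording(config$input)

  log_stage("pipeline", "stage 2/7: preprocess")
  epochs <- preprocess_recording(
    recording, notch_hz = config$notch_hz, band_pass = config$band_pass,
    snr_threshold_db = config$snr_threshold_db,
    epoch_length_s = config$epoch_length_s, ica_seed = seeds$ica)
  n_epochs <- length(epochs$labels)
  n_kept <- sum(epochs$kept)

  log_stage("pipeline", "stage 3/7: features")
  features <- build_feature_table(epochs, config$bands, config$welch)
  write_feature_table(features, file.path(out_dir, "features.csv"))

  log_stage("pipeline", "stage 4/7: split + select (train only)")
  split <- split_train_test(features, config$test_fraction, seeds$split)
  scores <- score_features(split$train)
  train_sel <- select_top_k(split$train, scores, config$k)
  selected <- attr(train_sel, "selected")
  test_sel <- split$test[, c(selected, "label"), drop = FALSE]

  log_stage("pipeline", "stage 5/7: tune + train (", config$family, ")")
  spec <- tune_hyperparameters(train_sel, config$family,
                               grid = config$grid, folds = config$folds,
                               seed = seeds$tune)
  spec$seed <- seeds$train
  model <- train_model(train_sel, spec)
  jsonlite::write_json(
    list(family = spec$family, n_estimators = spec$n_estimators,
         max_depth = spec$max_depth, seed = spec$seed,
         feature_names = model$feature_names,
         cv_accuracy = attr(spec, "cv_accuracy")),
    file.path(out_dir, "model_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_stage("pipeline", "stage 6/7: evaluate")
  report <- evaluate_model(model, test_sel)
  jsonlite::write_json(eval_report_to_list(report),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_eval_table(report), file.path(out_dir,
                                                  "evaluation.txt"))
  roc_pts <- do.call(rbind, lapply(names(report$roc$per_class), function(cl) {
    cv <- report$roc$per_class[[cl]]$curve
    if (is.null(cv)) return(NULL)
    cbind(class = cl, cv)
  }))
  utils::write.csv(roc_pts, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)

  log_stage("pipeline", "stage 7/7: explain")
  lime_cfg <- config$lime
  lime_cfg$seed <- seeds$explain
  n_expl <- min(config$n_explanations, nrow(test_sel))
  explanations <- lapply(seq_len(n_expl), function(i) {
    ex <- explain_instance(model, test_sel[i, , drop = FALSE], lime_cfg)
    list(instance = i, predicted_class = ex$predicted_class,
         class_probabilities = as.list(ex$class_probabilities),
         intercept = ex$intercept,
         local_fidelity_r2 = ex$local_fidelity_r2,
         contributions = ex$contributions)
  })
  jsonlite::write_json(explanations,
                       file.path(out_dir, "explanations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    parameters = list(
      notch_hz = config$notch_hz, band_pass = config$band_pass,
      snr_threshold_db = config$snr_threshold_db,
      epoch_length_s = config$epoch_length_s, k = config$k,
      family = config$family, folds = config$folds,
      test_fraction = config$test_fraction,
      welch = unclass(config$welch),
      lime = unclass(lime_cfg)),
    seeds = seeds,
    versions = list(
      package = as.character(utils::packageVersion("eegactivity")),
      r = R.version.string),
    counts = list(
      epochs_total = n_epochs,
      epochs_kept = n_kept,
      epochs_rejected = n_epochs - n_kept,
      rejected_fraction = (n_epochs - n_kept) / n_epochs,
      feature_rows = nrow(features),
      feature_rows_dropped = attr(features, "dropped") %||% 0L,
      train_rows = nrow(split$train),
      test_rows = nrow(split$test)),
    selected_features = selected)
  stopifnot(manifest$counts$epochs_total ==
              manifest$counts$epochs_kept + manifest$counts$epochs_rejected,
            manifest$counts$feature_rows ==
              manifest$counts$epochs_kept -
              manifest$counts$feature_rows_dropped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(features = features, model = model, evaluation = report,
                 explanations = explanations, manifest = manifest,
                 out_dir = out_dir))
}
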