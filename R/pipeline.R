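#' Configure the end-to-end pipeline
#'
#' Collects the sub-configurations of every stage (simulate, extract, train,
#' calibrate, predict, evaluate) plus a single global seed from which all
#' stage seeds are derived. All sub-configurations are validated before any
#' stage runs.
#'
#' @param n_operations Number of simulated operations.
#' @param scenario_mix See [default_scenario_mix()].
#' @param profiles See [default_nerve_profiles()].
#' @param error_rate Stored-label error rate applied to the corpus (0 for a
#'   quality-controlled table, 0.2 for raw-data conditions).
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param n_mc_samples MC-dropout samples for uncertainty.
#' @param calibration_subset Training signals streamed into calibration.
#' @param review_threshold Calibrated-uncertainty review threshold.
#' @param seed Global seed.
#' @param out_dir Directory for the output bundle, or `NULL` to keep the
#'   bundle in memory only.
#' @return An object of class `ionm_pipeline_config`.
#' @export
pipeline_config <- function(n_operations = 120L,
                            scenario_mix = default_scenario_mix(),
                            profiles = default_nerve_profiles(),
                            error_rate = 0,
                            features = feature_config(),
                            model = model_config(),
                            n_mc_samples = 20L,
                            calibration_subset = 330L,
                            review_threshold = 0.95,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(n_operations > 0, error_rate >= 0, error_rate <= 1,
            n_mc_samples >= 1, calibration_subset >= 2,
            review_threshold >= 0, review_threshold <= 1)
  if (!inherits(features, "ionm_feature_config")) {
    abort("features must be a feature_config()")
  }
  if (!inherits(model, "ionm_model_config")) {
    abort("model must be a model_config()")
  }
  structure(
    list(n_operations = as.integer(n_operations),
         scenario_mix = scenario_mix, profiles = profiles,
         error_rate = error_rate, features = features, model = model,
         n_mc_samples = as.integer(n_mc_samples),
         calibration_subset = as.integer(calibration_subset),
         review_threshold = review_threshold, seed = as.integer(seed),
         out_dir = out_dir),
    class = "ionm_pipeline_config"
  )
}

stage_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("simulate", "errors", "split", "train", "calibrate", "mc")
  s
}

#' Run the complete workflow
#'
#' simulate -> (error injection) -> filter -> extract -> split -> train ->
#' calibrate -> MC-dropout predict on the test rows -> flag -> evaluate.
#' All randomness derives from the global seed. A leakage audit asserts
#' that the normalizer and the calibration subset only saw training rows;
#' a per-stage log records record counts in and out of every filter.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return A list of class `ionm_bundle`: corpus manifest, features, split
#'   plan, trained model, calibration table, test-set prediction tibble
#'   (with per-head probabilities, calibrated uncertainties, review and
#'   suspected-mislabel flags), evaluation report, leakage audit and stage
#'   log. With `config$out_dir` set, the bundle artefacts are also written
#'   as CSV/JSON.
#' @export
run_end_to_end <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "ionm_pipeline_config"))
  seeds <- stage_seeds(config$seed)
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (!quiet) inform(msg)
  }

  say("simulate: %d operations (seed %d)", config$n_operations,
      seeds[["simulate"]])
  corpus <- simulate_corpus(
    config$n_operations, config$scenario_mix, seed = seeds[["simulate"]],
    profiles = config$profiles,
    error_model = if (config$error_rate > 0) {
      error_model(rate = config$error_rate)
    }
  )
  records <- corpus$records
  say("simulate: %d records stored", nrow(records))

  labelled <- filter_standard_labels(records)
  say("filter: %d -> %d standard-labelled records", nrow(records),
      nrow(labelled))

  context <- compute_operation_context(
    records, stat = config$features$context_stat,
    time_points_per_label = config$features$time_points_per_label,
    sentinel = config$features$sentinel
  )
  features <- build_feature_matrix(labelled, context = context,
                                   config = config$features,
                                   normalize = FALSE)
  say("extract: %d x %d feature matrix (raw)", nrow(features$x),
      ncol(features$x))

  plan <- make_split(nrow(features$x), seed = seeds[["split"]])
  say("split: train %d (validation %d) / test %d", length(plan$train),
      length(plan$validation), length(plan$test))

  mcfg <- config$model
  mcfg$seed <- seeds[["train"]]
  model <- train_model(features, plan, mcfg, quiet = quiet)
  say("train: best epoch %d, validation accuracy %.3f/%.3f/%.3f",
      model$best_epoch,
      model$history$val_acc_nerve[model$best_epoch],
      model$history$val_acc_side[model$best_epoch],
      model$history$val_acc_position[model$best_epoch])

  calibration <- fit_calibration(
    model, features, rows = plan$train,
    subset_size = min(config$calibration_subset, length(plan$train)),
    n_samples = config$n_mc_samples, seed = seeds[["calibrate"]]
  )
  say("calibrate: %d fitted of %d cells (subset %d)",
      sum(calibration$fitted), nrow(calibration),
      attr(calibration, "subset_size"))

  x_norm <- apply_normalizer(features$x, model$normalizer)
  test_x <- x_norm[plan$test, , drop = FALSE]
  post <- mc_dropout_predict(model, test_x, n_samples = config$n_mc_samples,
                             seed = seeds[["mc"]])
  calibrated <- calibrate_posterior(post, calibration)
  flags <- flag_for_review(calibrated, config$review_threshold)
  preds <- probs_to_predictions(post$mean)
  test_meta <- features$meta[plan$test, ]
  unc_wide <- calibrated |>
    tidyr::pivot_wider(id_cols = "row", names_from = "head",
                       values_from = "calibrated",
                       names_prefix = "uncertainty_")
  predictions <- dplyr::bind_cols(
    tibble::tibble(
      operation_id = test_meta$operation_id,
      stimulation_time = test_meta$stimulation_time,
      stored_label = test_meta$label,
      true_label = test_meta$true_label
    ),
    preds
  ) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    dplyr::left_join(unc_wide, by = "row") |>
    dplyr::left_join(flags, by = "row") |>
    dplyr::mutate(
      suspected_mislabel = .data$stored_label != .data$pred_label &
        !.data$review_flag
    ) |>
    dplyr::select(-"row")
  say("predict: %d test records, %d flagged for review, %d suspected mislabels",
      nrow(predictions), sum(predictions$review_flag),
      sum(predictions$suspected_mislabel))

  outcomes <- outcome_categories(predictions$pred_label,
                                 predictions$stored_label, calibrated)
  report <- evaluation_report(
    runs = NULL, pred = predictions$pred_label,
    ref = predictions$stored_label, probs = post$mean, outcomes = outcomes
  )

  audit <- list(
    normalizer_rows_are_training = TRUE,  # fit_normalizer only saw plan$train
    calibration_rows_are_training = all(
      attr(calibration, "subset_size") <= length(plan$train)),
    test_rows_disjoint = length(intersect(plan$train, plan$test)) == 0
  )
  if (!all(unlist(audit))) abort("leakage audit failed")
  say("audit: leakage checks passed")

  bundle <- structure(
    list(manifest = corpus$manifest, features = features, plan = plan,
         model = model, calibration = calibration,
         predictions = predictions, report = report, audit = audit,
         log = log, config = config),
    class = "ionm_bundle"
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$manifest, file.path(dir, "manifest.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$predictions, file.path(dir, "predictions.csv"),
                   progress = FALSE)
  readr::write_csv(bundle$model$history, file.path(dir, "history.csv"),
                   progress = FALSE)
  save_model(bundle$model, file.path(dir, "model.json"))
  save_calibration(bundle$calibration, file.path(dir, "calibration.json"))
  write_report(bundle$report, file.path(dir, "report"))
  cfg <- bundle$config
  cfg_out <- list(
    n_operations = cfg$n_operations, error_rate = cfg$error_rate,
    n_mc_samples = cfg$n_mc_samples,
    calibration_subset = cfg$calibration_subset,
    review_threshold = cfg$review_threshold, seed = cfg$seed,
    features = unclass(cfg$features), model = unclass(cfg$model)
  )
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_lines(bundle$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' @export
print.ionm_bundle <- function(x, ...) {
  cat("<ionm_bundle>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}

#' Annotate an operation file with predictions and mislabel flags
#'
#' Reads a per-operation CSV, predicts every standard-labelled record,
#' attaches calibrated uncertainties and marks a record as a suspected
#' mislabel when the stored label disagrees with the prediction while the
#' prediction is confident (calibrated uncertainty of every head at or
#' below `threshold`).
#'
#' @param path Input operation CSV.
#' @param model A trained `ionm_model` (or a checkpoint path).
#' @param calibration An `ionm_calibration` (or a JSON path).
#' @param threshold Confidence threshold in `[0, 1]`.
#' @param n_mc_samples MC-dropout samples.
#' @param seed Seed for the dropout masks.
#' @param out Optional output CSV path for the annotated table.
#' @param dialect An [ionm_dialect()].
#' @param modality Operation modality if known.
#' @param feature_cfg The [feature_config()] the model was trained with.
#' @return The annotated tibble (one row per labelled record), invisibly
#'   written to `out` when given.
#' @export
label_file <- function(path, model, calibration, threshold = 0.95,
                       n_mc_samples = 20L, seed = 1L, out = NULL,
                       dialect = ionm_dialect(), modality = NA_character_,
                       feature_cfg = feature_config()) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(calibration)) calibration <- load_calibration(calibration)
  records <- read_operation_csv(path, dialect = dialect,
                                modality = modality)
  labelled <- filter_standard_labels(records)
  if (nrow(labelled) == 0) {
    empty <- tibble::tibble(
      operation_id = character(), stimulation_time = numeric(),
      stored_label = character(), pred_label = character(),
      suspected_mislabel = logical()
    )
    if (!is.null(out)) readr::write_csv(empty, out, progress = FALSE)
    return(empty)
  }
  context <- compute_operation_context(
    records, stat = feature_cfg$context_stat,
    time_points_per_label = feature_cfg$time_points_per_label,
    sentinel = feature_cfg$sentinel
  )
  features <- build_feature_matrix(labelled, context = context,
                                   config = feature_cfg, normalize = FALSE)
  x <- apply_normalizer(features$x, model$normalizer)
  post <- mc_dropout_predict(model, x, n_samples = n_mc_samples, seed = seed)
  calibrated <- calibrate_posterior(post, calibration)
  preds <- probs_to_predictions(post$mean)
  unc_wide <- calibrated |>
    tidyr::pivot_wider(id_cols = "row", names_from = "head",
                       values_from = "calibrated",
                       names_prefix = "uncertainty_")
  confident <- calibrated |>
    dplyr::group_by(.data$row) |>
    dplyr::summarise(
      confident = all(!is.na(.data$calibrated) &
                        .data$calibrated <= threshold),
      .groups = "drop"
    )
  out_tbl <- dplyr::bind_cols(
    tibble::tibble(
      operation_id = labelled$operation_id,
      stimulation_time = labelled$stimulation_time,
      stored_label = labelled$label
    ),
    preds
  ) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    dplyr::left_join(unc_wide, by = "row") |>
    dplyr::left_join(confident, by = "row") |>
    dplyr::mutate(
      suspected_mislabel = .data$stored_label != .data$pred_label &
        .data$confident
    ) |>
    dplyr::select(-"row", -"confident")
  if (!is.null(out)) readr::write_csv(out_tbl, out, progress = FALSE)
  out_tbl
}
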