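#' Pipeline configuration
#'
#' One serializable object holding every constant the pipeline uses, so a
#' run's effective configuration can be persisted next to its outputs and
#' re-running with the persisted file reproduces them.
#'
#' @param epoch_length epoch length in seconds.
#' @param clip_limit,cutoff signal-conditioning constants (g, Hz).
#' @param classifier a [classifier_config()].
#' @param grid_steps named list of peak-grid resolutions (`prominence_step`,
#'   `distance_step`, `width_step`).
#' @param k cross-validation folds.
#' @param seed global seed; stage seeds are derived from it by stable
#'   hashing.
#' @param baseline baseline selection: `"none"`, `"ducharme_threshold"` or
#'   `"verisense"`.
#' @param output_dir output directory for the `cmd_*` entry points.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(epoch_length = 10, clip_limit = 2, cutoff = 5,
                            classifier = classifier_config(),
                            grid_steps = list(prominence_step = 0.1,
                                              distance_step = 0.2,
                                              width_step = 0.3),
                            k = 10, seed = 1L,
                            baseline = c("none", "ducharme_threshold", "verisense"),
                            output_dir = "wristep-output") {
  structure(list(epoch_length = epoch_length, clip_limit = clip_limit,
                 cutoff = cutoff, classifier = classifier,
                 grid_steps = grid_steps, k = k, seed = as.integer(seed),
                 baseline = match.arg(baseline), output_dir = output_dir,
                 version = "1"),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$classifier <- unclass(cfg$classifier)
  cfg$classifier$class_balance_target <- as.list(cfg$classifier$class_balance_target)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cl <- cfg$classifier
  classifier <- classifier_config(
    backend = cl$backend, learning_rate = cl$learning_rate,
    class_balance_target = unlist(cl$class_balance_target),
    early_stop_patience = cl$early_stop_patience,
    max_train_epochs = cl$max_train_epochs, batch_size = cl$batch_size,
    augment = cl$augment, n_augment = cl$n_augment, seed = cl$seed)
  pipeline_config(epoch_length = cfg$epoch_length, clip_limit = cfg$clip_limit,
                  cutoff = cfg$cutoff, classifier = classifier,
                  grid_steps = cfg$grid_steps, k = cfg$k, seed = cfg$seed,
                  baseline = cfg$baseline, output_dir = cfg$output_dir)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
config_grid <- function(config) {
  default_peak_grid(config$grid_steps$prominence_step,
                    config$grid_steps$distance_step,
                    config$grid_steps$width_step)
}

#' Save / load a model checkpoint
#'
#' A checkpoint carries the fitted classifier, HMM smoother, tuned peak
#' parameters, the config snapshot and a format version, serialized as JSON
#' so it is portable and inspectable.
#'
#' @param model a `trained_classifier`.
#' @param hmm an [hmm_params].
#' @param peaks a [peak_params].
#' @param config the effective [pipeline_config()].
#' @param path output path.
#' @export
save_checkpoint <- function(model, hmm, peaks, config, path) {
  ck <- list(
    version = "1",
    backend = model$backend,
    theta = model$theta, center = model$center, scale = model$scale,
    class_weights = as.list(model$class_weights),
    sample_rate = model$sample_rate,
    history = model$history, best_epoch = model$best_epoch,
    hmm = list(prior = as.numeric(hmm$prior),
               transition = as.numeric(hmm$transition),
               emission = as.numeric(hmm$emission)),
    peaks = unclass(peaks),
    config = jsonlite::fromJSON(jsonlite::toJSON(
      {cfg <- unclass(config); cfg$classifier <- unclass(cfg$classifier); cfg},
      auto_unbox = TRUE, null = "null"))
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ck$version, "1"))
    stopf("checkpoint version '%s' not supported by this package version", ck$version)
  model <- structure(list(backend = ck$backend, theta = as.numeric(ck$theta),
                          center = as.numeric(ck$center),
                          scale = as.numeric(ck$scale),
                          class_weights = unlist(ck$class_weights),
                          history = as.data.frame(ck$history),
                          best_epoch = ck$best_epoch,
                          sample_rate = ck$sample_rate,
                          encoder = NULL, version = ck$version),
                     class = "trained_classifier")
  names(model$center) <- names(model$scale) <- NULL
  list(model = model,
       hmm = hmm_params(ck$hmm$prior, matrix(ck$hmm$transition, 2, 2),
                        matrix(ck$hmm$emission, 2, 2)),
       peaks = peak_params(ck$peaks$prominence, ck$peaks$distance,
                           ck$peaks$width_max),
       config = ck$config)
}

log_msg <- function(out_dir, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(out_dir))
    cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stopf("output directory '%s' is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

#' Write a synthetic cohort to disk
#'
#' One recording CSV and one step-time CSV per participant, plus a manifest
#' listing every output; re-running with the same seed reproduces the files
#' byte for byte.
#'
#' @param n_participants number of participants (>= 1).
#' @param config a [pipeline_config()].
#' @param duration per-participant recording length in seconds.
#' @param force overwrite a non-empty output directory.
#' @return the manifest path, invisibly.
#' @export
cmd_simulate <- function(n_participants, config = pipeline_config(),
                         duration = 480, force = FALSE) {
  if (n_participants < 1) stopf("n_participants must be at least 1")
  out <- prepare_out_dir(config$output_dir, force)
  cohort <- simulate_cohort(n_participants, duration = duration,
                            seed = derive_seed(config$seed, "simulate"))
  files <- character(0)
  for (p in cohort) {
    rp <- file.path(out, sprintf("%s_recording.csv", p$id))
    sp <- file.path(out, sprintf("%s_steps.csv", p$id))
    write_recording(p$recording, rp)
    data.table::fwrite(data.table::data.table(step_time = p$step_times), sp)
    files <- c(files, rp, sp)
  }
  write_config(config, file.path(out, "config.yaml"))
  manifest <- file.path(out, "manifest.csv")
  data.table::fwrite(data.table::data.table(file = basename(files)), manifest)
  log_msg(out, "simulated %d participants (seed %d) into %s",
          n_participants, config$seed, out)
  invisible(manifest)
}

#' Train the pipeline and write a checkpoint
#'
#' Runs cross-validation when `cv = TRUE` and then the final fit: an 80/20
#' participant-level train/validation split of the whole cohort, classifier
#' training, HMM fitting on validation predictions, and peak-parameter
#' tuning, all persisted to `checkpoint.json` with the training log.
#'
#' @param cohort list of participants (see [simulate_cohort()] for the
#'   structure; recordings loaded from disk work the same way).
#' @param config a [pipeline_config()].
#' @param cv also run k-fold cross-validation and write its report.
#' @param force overwrite a non-empty output directory.
#' @return list with `checkpoint` path and (when `cv`) the CV `report`.
#' @export
cmd_train <- function(cohort, config = pipeline_config(), cv = FALSE,
                      force = FALSE) {
  out <- prepare_out_dir(config$output_dir, force)
  write_config(config, file.path(out, "config.yaml"))
  cv_report <- NULL
  if (cv) {
    cv_report <- run_cv(cohort, k = config$k, config = config$classifier,
                        grid = config_grid(config), seed = config$seed)
    jsonlite::write_json(
      list(mape = cv_report$pooled$mape,
           mape_fold_mean = cv_report$pooled$mape_fold_mean,
           mean_bias = cv_report$pooled$mean_bias,
           kappa = cv_report$pooled$classification$kappa),
      file.path(out, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  }
  ids <- vapply(cohort, `[[`, character(1), "id")
  n_val <- max(1L, round(0.2 * length(ids)))
  val_ids <- with_seed(derive_seed(config$seed, "finalfit"), sample(ids, n_val))
  train_ids <- setdiff(ids, val_ids)
  names(cohort) <- ids
  gather <- function(sel) {
    list(windows = do.call(c, lapply(cohort[sel], function(p)
           epoch_windows(p$recording, p$epochs))),
         labels = do.call(c, lapply(cohort[sel], function(p)
           ifelse(p$epochs$valid, p$epochs$true_label, NA_character_))))
  }
  model <- train_classifier(gather(train_ids), gather(val_ids),
                            config$classifier,
                            sample_rate = cohort[[1]]$recording$sample_rate)
  data.table::fwrite(model$history, file.path(out, "training_log.csv"))
  val_pred <- lapply(cohort[val_ids], function(p)
    predict_epochs(model, epoch_windows(p$recording, p$epochs),
                   valid = p$epochs$valid)$label)
  val_true <- lapply(cohort[val_ids], function(p) p$epochs$true_label)
  hmm <- fit_hmm(val_pred, val_true)
  peaks <- tune_params(cohort[val_ids], config_grid(config))
  ck <- file.path(out, "checkpoint.json")
  save_checkpoint(model, hmm, peaks, config, ck)
  log_msg(out, "trained on %d participants (val %d), checkpoint %s",
          length(train_ids), length(val_ids), ck)
  list(checkpoint = ck, report = cv_report)
}

#' Count steps in recordings with a trained checkpoint
#'
#' @param recordings named list of [raw_recording]s (or a directory of
#'   `*_recording.csv` files).
#' @param checkpoint path to a checkpoint from [cmd_train()].
#' @param config a [pipeline_config()] (for the output directory).
#' @param force overwrite a non-empty output directory.
#' @return path to the written `step_events.csv` (participant, epoch_start,
#'   steps) with per-participant totals in `step_totals.csv`.
#' @export
cmd_count <- function(recordings, checkpoint, config = pipeline_config(),
                      force = FALSE) {
  out <- prepare_out_dir(config$output_dir, force)
  ck <- load_checkpoint(checkpoint)
  if (is.character(recordings)) {
    paths <- list.files(recordings, pattern = "_recording\\.csv$",
                        full.names = TRUE)
    recordings <- stats::setNames(lapply(paths, read_recording),
                                  sub("_recording\\.csv$", "", basename(paths)))
  }
  rows <- list(); totals <- list()
  for (id in names(recordings)) {
    ev <- hybrid_count(recordings[[id]], ck$model, ck$hmm, ck$peaks,
                       epoch_length = config$epoch_length)
    rows[[id]] <- data.frame(
      participant = id,
      epoch_start = (seq_along(ev$epoch_counts) - 1L) * ev$epoch_length,
      steps = ev$epoch_counts)
    totals[[id]] <- data.frame(participant = id, steps = ev$total)
  }
  data.table::fwrite(do.call(rbind, rows), file.path(out, "step_events.csv"))
  data.table::fwrite(do.call(rbind, totals), file.path(out, "step_totals.csv"))
  log_msg(out, "counted steps for %d recordings", length(recordings))
  file.path(out, "step_events.csv")
}

#' Evaluate predicted against true per-participant step totals
#'
#' @param truth,predicted data.frames with columns `participant`, `steps`.
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return the [eval_report], also written as `eval_report.json` and a flat
#'   `eval_report.csv`.
#' @export
cmd_evaluate <- function(truth, predicted, config = pipeline_config(),
                         force = FALSE) {
  out <- prepare_out_dir(config$output_dir, force)
  m <- merge(truth, predicted, by = "participant",
             suffixes = c("_true", "_pred"))
  rep <- eval_report(stats::setNames(m$steps_true, m$participant),
                     stats::setNames(m$steps_pred, m$participant))
  jsonlite::write_json(
    list(n = rep$n, mape = rep$mape, mean_bias = rep$mean_bias,
         spearman = rep$spearman,
         bland_altman = rep$bland_altman[c("mean_diff", "lower", "upper")]),
    file.path(out, "eval_report.json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(rep$per_participant, file.path(out, "eval_report.csv"))
  log_msg(out, "evaluated %d participants: MAPE %.2f%%", rep$n, rep$mape)
  rep
}

#' Aggregate minute-level steps into daily summaries
#'
#' @param participants named list; each element a list with `minute_steps`
#'   (days x 1440), `missing` mask, and the QC inputs of [qc_screen()].
#' @param config a [pipeline_config()].
#' @param force overwrite a non-empty output directory.
#' @return data.frame of per-participant summaries, also written as
#'   `daily_summary.csv`.
#' @export
cmd_aggregate <- function(participants, config = pipeline_config(),
                          force = FALSE) {
  out <- prepare_out_dir(config$output_dir, force)
  rows <- lapply(names(participants), function(id) {
    p <- participants[[id]]
    s <- daily_summary(p$minute_steps, p$missing, p$wear_hours,
                       p$hours_covered,
                       calibration_ok = isTRUE(p$calibration_ok) ||
                         is.null(p$calibration_ok),
                       mean_acceleration_mg = if (is.null(p$mean_acceleration_mg))
                         NA_real_ else p$mean_acceleration_mg)
    data.frame(participant = id, median_daily_steps = s$median_daily,
               peak_cadence = s$peak_cadence,
               imputed_minutes = s$imputed_minutes,
               include = s$include,
               qc_flags = paste(s$qc_flags, collapse = ";"))
  })
  res <- do.call(rbind, rows)
  data.table::fwrite(res, file.path(out, "daily_summary.csv"))
  log_msg(out, "aggregated %d participants (%d excluded)",
          nrow(res), sum(!res$include))
  res
}
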