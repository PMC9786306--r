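# Config-driven orchestration: simulate -> synchronize/extract -> select ->
# train -> monitor AFT on a held-out session -> classify fatigue -> report.

#' Default pipeline configuration
#'
#' Nested configuration for \code{\link{run_pipeline}} covering the study
#' layout (cohort size, per-activity bout length, the unseen worker's
#' profile and schedule), feature selection, the sequence-model
#' hyperparameters, the AFT windowing schemes and the fatigue-classifier
#' stage. Any entry can be overridden via \code{...} using nested lists;
#' scalars not supplied keep their defaults.
#'
#' @param ... Named overrides merged over the defaults, e.g.
#'   \code{simulation = list(n_subjects = 4)}.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  base <- list(
    simulation = list(
      n_subjects = 10, duration_s = 300, seed = 1,
      rof_interval_s = 300,
      unseen = list(participant_id = "U01", age = 29, body_mass = 75,
                    height = 168, resting_hr = 96),
      unseen_schedule = NULL,  # NULL = evaluation_schedule()
      unseen_rof_interval_s = 60),
    features = list(k = 100, r_threshold = 0.1, mi_threshold = 0.1),
    model = list(L = 100, stride = 1, eval_stride = 1, hidden = c(64, 32),
                 dense = 32, dropout = 0.3, epochs = 50, batch_size = 64,
                 learning_rate = 1e-3, validation_split = 0.1,
                 patience = 5,
                 # optional per-task overrides of the entries above
                 activity = list(), vo2 = list()),
    aft = list(schemes = c("1-min", "2-min", "per-activity")),
    classify = list(model = "DT", subset = "AFT", folds = 10,
                    compare_subsets = TRUE),
    output_dir = NULL,
    run_loso = TRUE,
    write_sessions = FALSE)
  cfg <- utils::modifyList(base, list(...))
  stopifnot(cfg$simulation$n_subjects >= 2, cfg$model$L >= 1,
            all(cfg$aft$schemes %in% c("1-min", "2-min", "5-min",
                                       "per-activity")))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File ending in .yaml/.yml or .json; entries override the
#'   defaults of \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json"))
  do.call(pipeline_config, lst)
}

# task-specific model settings: base block overlaid with per-task entries
.model_for <- function(cfg, task) {
  m <- cfg$model
  ov <- m[[task]]
  m$activity <- m$vo2 <- NULL
  if (length(ov)) m <- utils::modifyList(m, ov)
  m
}

# train final activity + vo2 models on all cohort sessions
.train_final_models <- function(sessions, cfg, seed) {
  x_all <- do.call(rbind, lapply(sessions, `[[`, "x"))
  act <- unlist(lapply(sessions, function(s) as.character(s$activity)))
  sel_a <- as.character(anova_f_select(x_all, act, k = cfg$features$k))
  sc_a <- fit_scaler(x_all[, sel_a, drop = FALSE], "zscore")
  vo2 <- unlist(lapply(sessions, `[[`, "vo2"))
  sel_v <- as.character(corr_mi_select(x_all, vo2,
                                       cfg$features$r_threshold,
                                       cfg$features$mi_threshold))
  if (length(sel_v) < 2) {
    r <- abs(as.vector(cor(x_all, vo2)))
    sel_v <- colnames(x_all)[order(-r)[1:20]]
  }
  sc_v <- fit_scaler(x_all[, sel_v, drop = FALSE], "minmax")
  rm(x_all)

  batches_for <- function(sel, sc, m) {
    bs <- lapply(sessions, function(s)
      make_sequences(apply_scaler(s$x[, sel, drop = FALSE], sc),
                     L = m$L, stride = m$stride, pad = "repeat"))
    list(batch = combine_seq_batches(bs), per_session = bs)
  }
  ma <- .model_for(cfg, "activity")
  ba <- batches_for(sel_a, sc_a, ma)
  ya <- factor(unlist(lapply(seq_along(sessions), function(i)
    as.character(sessions[[i]]$activity)[ba$per_session[[i]]$index])),
    levels = activity_codes())
  fit_a <- bilstm(ba$batch, ya, task = "classification",
                  hidden = ma$hidden, dense = ma$dense,
                  dropout = ma$dropout, epochs = ma$epochs,
                  batch_size = ma$batch_size,
                  learning_rate = ma$learning_rate,
                  validation_split = ma$validation_split,
                  patience = ma$patience, seed = child_seed(seed, 101L))
  mv <- .model_for(cfg, "vo2")
  bv <- batches_for(sel_v, sc_v, mv)
  yv <- unlist(lapply(seq_along(sessions), function(i)
    sessions[[i]]$vo2[bv$per_session[[i]]$index]))
  fit_v <- bilstm(bv$batch, yv, task = "regression", hidden = mv$hidden,
                  dense = mv$dense, dropout = mv$dropout,
                  epochs = mv$epochs, batch_size = mv$batch_size,
                  learning_rate = mv$learning_rate,
                  validation_split = mv$validation_split,
                  patience = mv$patience, seed = child_seed(seed, 102L))
  list(activity = list(fit = fit_a, selected = sel_a, scaler = sc_a),
       vo2 = list(fit = fit_v, selected = sel_v, scaler = sc_v))
}

# per-second activity + vo2 predictions for one session's features;
# monitoring is always stride 1 so the predicted series stays at 1 Hz
.predict_session <- function(models, sf, cfg) {
  seq_for <- function(mod, m) {
    xs <- apply_scaler(sf$x[, mod$selected, drop = FALSE], mod$scaler)
    make_sequences(xs, L = m$L, stride = 1, pad = "repeat")
  }
  ba <- seq_for(models$activity, .model_for(cfg, "activity"))
  bv <- seq_for(models$vo2, .model_for(cfg, "vo2"))
  list(index = ba$index,
       activity = predict(models$activity$fit, ba),
       vo2 = predict(models$vo2$fit, bv))
}

#' Run the full fatigue-monitoring pipeline
#'
#' Executes the framework end to end on synthetic data: simulates a
#' training cohort and one unseen evaluation session; extracts per-second
#' features; (optionally) runs leave-one-subject-out CV for both sequence
#' models; trains final activity and oxygen-uptake models on the whole
#' cohort; predicts the unseen session per second and computes actual and
#' predicted AFT plus \%HRR; compares the ten fatigue classifiers on the
#' cohort's per-activity feature table; evaluates the best/configured
#' classifier on the unseen session's predicted-AFT features per windowing
#' scheme; and tests actual-vs-predicted level agreement with a
#' chi-squared test. When \code{config$output_dir} is set, artifacts
#' (session CSVs, CV tables, metrics JSON, run manifest) are written there.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return A report bundle (named list) with elements \code{loso},
#'   \code{classifier_comparison}, \code{unseen}, \code{chi_squared},
#'   \code{aft}, \code{seed}, invisibly-written artifacts aside.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$simulation$seed
  simc <- config$simulation

  # --- stage 1: simulate
  profiles <- cohort_profiles(simc$n_subjects, seed = child_seed(seed, 1L))
  cfg_sim <- sim_config(seed = child_seed(seed, 2L),
                        rof_interval_s = simc$rof_interval_s)
  cohort <- simulate_cohort(profiles, cfg_sim,
                            duration_s = simc$duration_s)
  unseen_prof <- do.call(participant_profile, simc$unseen)
  cfg_unseen <- sim_config(seed = child_seed(seed, 3L),
                           rof_interval_s = simc$unseen_rof_interval_s)
  unseen_sched <- if (is.null(simc$unseen_schedule)) evaluation_schedule()
    else activity_schedule(simc$unseen_schedule$activity_id,
                           simc$unseen_schedule$duration_s)
  unseen_cat <- participant_catalog(activity_catalog(), cfg_unseen,
                                    child_seed(seed, 3001L))
  unseen <- simulate_session(unseen_prof, unseen_sched, unseen_cat,
                             cfg_unseen)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(config$write_sessions)) {
      for (i in seq_along(cohort))
        write_session(cohort[[i]],
                      file.path(out_dir, "sessions",
                                cohort[[i]]$profile$participant_id))
      write_session(unseen, file.path(out_dir, "sessions", "unseen"))
    }
  }

  # --- stage 2: synchronize + features
  feats <- lapply(cohort, session_features)
  unseen_sf <- session_features(unseen)

  # --- stage 3: LOSO CV of the sequence models
  loso <- NULL
  if (isTRUE(config$run_loso)) {
    ma <- .model_for(config, "activity")
    mv <- .model_for(config, "vo2")
    loso <- list(
      activity = loso_cv(feats, "activity", k = config$features$k,
                         L = ma$L, stride = ma$stride,
                         eval_stride = ma$eval_stride, hidden = ma$hidden,
                         dense = ma$dense, dropout = ma$dropout,
                         epochs = ma$epochs, batch_size = ma$batch_size,
                         learning_rate = ma$learning_rate,
                         validation_split = ma$validation_split,
                         patience = ma$patience,
                         seed = child_seed(seed, 4L)),
      vo2 = loso_cv(feats, "vo2",
                    r_threshold = config$features$r_threshold,
                    mi_threshold = config$features$mi_threshold,
                    L = mv$L, stride = mv$stride,
                    eval_stride = mv$eval_stride, hidden = mv$hidden,
                    dense = mv$dense, dropout = mv$dropout,
                    epochs = mv$epochs, batch_size = mv$batch_size,
                    learning_rate = mv$learning_rate,
                    validation_split = mv$validation_split,
                    patience = mv$patience, seed = child_seed(seed, 5L)))
  }

  # --- stage 4: final models + unseen-session monitoring
  models <- .train_final_models(feats, config, seed)
  pred <- .predict_session(models, unseen_sf, config)
  mt <- mac_table()
  act_chr <- as.character(unseen_sf$activity)
  aft_actual <- compute_aft(unseen_sf$vo2, act_chr, mt,
                            unseen_prof$body_mass, "actual",
                            unseen_prof$participant_id)
  aft_pred <- compute_aft(pred$vo2, as.character(pred$activity), mt,
                          unseen_prof$body_mass, "predicted",
                          unseen_prof$participant_id)
  hrr <- compute_hrr(unseen_sf$hr, unseen_prof$resting_hr, unseen_prof$age)

  # --- stage 5: fatigue classifiers on the cohort table
  train_table <- cohort_fatigue_table(feats, mt)
  comparison <- NULL
  best_model <- config$classify$model
  if (isTRUE(config$classify$compare_subsets)) {
    comparison <- compare_classifiers(train_table,
                                      folds = config$classify$folds,
                                      seed = child_seed(seed, 6L))
    bm <- comparison$subsets[[config$classify$subset]]$best
    if (!is.na(bm)) best_model <- bm
  }
  classifier <- fit_fatigue_classifier(train_table, model = best_model,
                                       subset = config$classify$subset,
                                       seed = child_seed(seed, 7L))

  # --- stage 6: unseen-session fatigue evaluation + agreement test
  tables <- list(); pairs <- list()
  for (sch in config$aft$schemes) {
    tables[[sch]] <- fatigue_features(
      aft_pred, unseen_sf$hr, hrr, sch, act_chr, unseen$rof,
      scaler = train_table$scaler)
    pairs[[sch]] <- data.frame(
      actual = windowed_average(unclass(aft_actual), sch, act_chr)$value,
      predicted = windowed_average(unclass(aft_pred), sch, act_chr)$value)
  }
  unseen_report <- evaluate_unseen(classifier, tables, pairs)
  chi <- lapply(unseen_report, function(s)
    tryCatch(chi_squared_agreement(s$actual, s$predicted),
             error = function(e) list(statistic = NA_real_, df = NA_real_,
                                      p_value = NA_real_,
                                      note = conditionMessage(e))))

  report <- list(
    seed = seed,
    loso = loso,
    classifier_comparison = comparison,
    classifier = classifier,
    unseen = unseen_report,
    chi_squared = chi,
    aft = list(actual = aft_actual, predicted = aft_pred,
               pairs = pairs),
    activity_accuracy_unseen = mean(
      as.character(pred$activity) == act_chr[pred$index]),
    vo2_unseen = regression_metrics(unseen_sf$vo2[pred$index], pred$vo2))

  if (!is.null(out_dir)) .write_report(report, config, out_dir)
  report
}

# persist the auditable pieces of a report bundle
.write_report <- function(report, config, out_dir) {
  if (!is.null(report$loso)) {
    write.csv(report$loso$activity$folds,
              file.path(out_dir, "loso_activity.csv"), row.names = FALSE)
    write.csv(report$loso$vo2$folds,
              file.path(out_dir, "loso_vo2.csv"), row.names = FALSE)
  }
  if (!is.null(report$classifier_comparison)) {
    cmp <- do.call(rbind, lapply(report$classifier_comparison$subsets,
                                 function(s)
                                   cbind(subset = s$subset, s$metrics)))
    write.csv(cmp, file.path(out_dir, "classifier_comparison.csv"),
              row.names = FALSE)
  }
  for (sn in names(report$unseen)) {
    write.csv(as.data.frame(report$unseen[[sn]]$confusion),
              file.path(out_dir, paste0("confusion_", gsub("[^A-Za-z0-9]",
                                                           "_", sn),
                                        ".csv")))
  }
  summary <- list(
    seed = report$seed,
    package_version = as.character(utils::packageVersion("aftmon")),
    loso_activity_accuracy =
      if (!is.null(report$loso)) report$loso$activity$aggregate$accuracy,
    loso_vo2_r2 = if (!is.null(report$loso)) report$loso$vo2$aggregate$r2,
    unseen = lapply(report$unseen, function(s)
      c(s$metrics, list(aft_r2 = s$aft_r2, aft_rmse = s$aft_rmse))),
    chi_squared = lapply(report$chi_squared, function(x)
      x[c("statistic", "df", "p_value")]))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}

#' Reference desk-scale study configuration
#'
#' The configuration of the package's reference synthetic study: a
#' 10-worker training cohort performing all 14 activities for 5 minutes
#' each, one unseen evaluation worker (29 y, 75 kg, 168 cm, resting HR 96)
#' on the bundled ~85-min evaluation schedule with minute-wise fatigue
#' ratings, and sequence models scaled for a single CPU: 30-step windows,
#' training stride 20, hidden sizes 16/8, with task-specific training
#' schedules (6 epochs for activity recognition, up to 14 with early
#' stopping for oxygen-uptake regression) and the top 30 ANOVA-F features
#' for the activity model. The methods vignette discusses these choices.
#'
#' @param seed Integer master seed for the whole study.
#' @return A \code{\link{pipeline_config}}.
#' @export
study_config <- function(seed = 1L) {
  pipeline_config(
    simulation = list(seed = as.integer(seed)),
    features = list(k = 30),
    model = list(L = 30, stride = 20, eval_stride = 5,
                 hidden = c(16, 8), dense = 16, batch_size = 64,
                 learning_rate = 3e-3,
                 activity = list(dropout = 0.3, epochs = 6,
                                 validation_split = 0.1, patience = 3),
                 vo2 = list(dropout = 0.2, epochs = 14,
                            validation_split = 0.15, patience = 4)))
}
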