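# Leave-one-subject-out cross-validation of the sequence models.

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the fold's model is trained on all other
#' subjects' sessions and evaluated on the held-out subject. Feature
#' selection and scaling are re-fit inside every fold on training rows
#' only (no leakage): the activity task selects the top-\code{k} features
#' by ANOVA F and standardizes (z-score); the oxygen-uptake task selects
#' by absolute Pearson correlation and mutual information > 0.1 and
#' min-max normalizes. Per-second predictions use stride-1 sliding windows
#' with left-padding by default; larger strides subsample windows for
#' speed.
#'
#' @param sessions List of \code{\link{session_features}} objects with
#'   distinct subject ids (>= 2).
#' @param task "activity" (14-class recognition) or "vo2" (regression).
#' @param k Features kept by ANOVA F selection (activity task).
#' @param r_threshold,mi_threshold Selection thresholds (vo2 task).
#' @param L Sequence length in seconds.
#' @param stride Training window stride.
#' @param eval_stride Evaluation window stride.
#' @param hidden,dense,dropout,epochs,batch_size,learning_rate,validation_split,patience
#'   Passed to \code{\link{bilstm}}.
#' @param seed Integer seed; each fold derives its own child seed.
#' @param verbose Print fold progress.
#' @return Object of class \code{cv_report}: \code{task}, \code{folds}
#'   (per-fold data.frame), \code{aggregate} (named list), pooled
#'   \code{confusion} (activity task), \code{selected} (per-fold feature
#'   names), \code{scalers} (per-fold \code{scaler_params}).
#' @export
loso_cv <- function(sessions, task = c("activity", "vo2"), k = 100,
                    r_threshold = 0.1, mi_threshold = 0.1, L = 100,
                    stride = 1, eval_stride = stride, hidden = c(64, 32),
                    dense = 32, dropout = 0.3, epochs = 50,
                    batch_size = 64, learning_rate = 1e-3,
                    validation_split = 0.1, patience = 5, seed = 1,
                    verbose = FALSE) {
  task <- match.arg(task)
  stopifnot(length(sessions) >= 2)
  subjects <- vapply(sessions, `[[`, character(1), "subject")
  if (anyDuplicated(subjects)) stop("subject ids must be distinct")
  if (any(vapply(sessions, function(s) nrow(s$x) == 0, logical(1))))
    stop("a session has no data")

  fold_rows <- list()
  confusion <- NULL
  selected <- list()
  scalers <- list()
  pooled_pred <- pooled_act <- NULL

  for (fi in seq_along(sessions)) {
    te <- sessions[[fi]]
    tr <- sessions[-fi]
    xtr <- do.call(rbind, lapply(tr, `[[`, "x"))

    if (task == "activity") {
      ytr <- unlist(lapply(tr, function(s) as.character(s$activity)))
      sel <- as.character(anova_f_select(xtr, ytr, k = k))
      sc <- fit_scaler(xtr[, sel, drop = FALSE], "zscore")
    } else {
      ytr <- unlist(lapply(tr, `[[`, "vo2"))
      sel <- as.character(corr_mi_select(xtr, ytr, r_threshold,
                                         mi_threshold))
      if (length(sel) < 2) {
        message("fewer than 2 features passed selection; using top-20 |r|")
        r <- abs(as.vector(cor(xtr, ytr)))
        sel <- colnames(xtr)[order(-r)[1:20]]
      }
      sc <- fit_scaler(xtr[, sel, drop = FALSE], "minmax")
    }
    selected[[te$subject]] <- sel
    scalers[[te$subject]] <- sc
    rm(xtr)

    seq_of <- function(s, strd) {
      xs <- apply_scaler(s$x[, sel, drop = FALSE], sc)
      make_sequences(xs, L = L, stride = strd, pad = "repeat")
    }
    tr_batches <- lapply(tr, seq_of, strd = stride)
    btr <- combine_seq_batches(tr_batches)
    tr_targets <- if (task == "activity")
      unlist(lapply(seq_along(tr), function(i)
        as.character(tr[[i]]$activity)[tr_batches[[i]]$index]))
    else
      unlist(lapply(seq_along(tr), function(i)
        tr[[i]]$vo2[tr_batches[[i]]$index]))
    if (task == "activity")
      tr_targets <- factor(tr_targets, levels = activity_codes())

    fit <- bilstm(btr, tr_targets,
                  task = if (task == "activity") "classification"
                         else "regression",
                  hidden = hidden, dense = dense, dropout = dropout,
                  epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate,
                  validation_split = validation_split, patience = patience,
                  seed = child_seed(seed, fi))

    bte <- seq_of(te, eval_stride)
    pred <- predict(fit, bte)

    if (task == "activity") {
      actual <- factor(as.character(te$activity)[bte$index],
                       levels = activity_codes())
      cm <- confusion_matrix(actual, pred, levels = activity_codes())
      m <- classification_metrics(cm)
      confusion <- if (is.null(confusion)) cm else confusion + cm
      fold_rows[[fi]] <- data.frame(
        subject = te$subject, n = length(actual), accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1)
    } else {
      actual <- te$vo2[bte$index]
      m <- regression_metrics(actual, pred)
      pooled_pred <- c(pooled_pred, pred)
      pooled_act <- c(pooled_act, actual)
      fold_rows[[fi]] <- data.frame(
        subject = te$subject, n = length(actual), r2 = m$r2, rmse = m$rmse)
    }
    if (verbose)
      message(sprintf("fold %d/%d (%s) done", fi, length(sessions),
                      te$subject))
  }

  folds <- do.call(rbind, fold_rows)
  aggregate <- if (task == "activity") {
    c(classification_metrics(confusion),
      list(mean_fold_accuracy = mean(folds$accuracy)))
  } else {
    c(regression_metrics(pooled_act, pooled_pred),
      list(mean_fold_r2 = mean(folds$r2)))
  }
  structure(list(task = task, folds = folds, aggregate = aggregate,
                 confusion = confusion, selected = selected,
                 scalers = scalers, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV (%s task, %d folds)\n",
              x$task, nrow(x$folds)))
  print(x$folds, row.names = FALSE, digits = 4)
  cat("aggregate:",
      paste(sprintf("%s=%.4f", names(x$aggregate),
                    unlist(x$aggregate)), collapse = ", "), "\n")
  invisible(x)
}
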