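# Per-segment fatigue features, the ten-classifier comparison, unseen-
# session evaluation, and actual-vs-predicted agreement testing.

#' Map a 0-10 fatigue rating to a fatigue level
#'
#' Rating ranges collapse to five levels: 0 -> None, 1-2 -> Low,
#' 3-5 -> Moderate, 6-7 -> High, 8-10 -> Very High.
#'
#' @param rating Integer rating(s) in [0, 10].
#' @return List with integer \code{level} (0-4) and \code{level_name}.
#' @examples
#' rof_to_level(3)$level_name  # "Moderate"
#' @export
rof_to_level <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 0) || any(rating > 10))
    stop("rating must be in [0, 10]")
  level <- findInterval(rating, c(1, 3, 6, 8))
  list(level = level, level_name = fatigue_levels()[level + 1L])
}

# segment boundaries (half-open [start, end) in 0-based seconds) per scheme
.segments <- function(n, scheme, activity = NULL) {
  wa <- windowed_average(rep(0, n), scheme, activity)
  wa[, c("start_s", "end_s", "n",
         if (scheme == "per-activity") "activity_id")]
}

.fatigue_stat_names <- as.vector(t(outer(c("aft", "hr", "hrr"),
                                         c("mean", "min", "max", "sd"),
                                         paste, sep = "_")))

#' Per-segment fatigue feature vectors
#'
#' Builds one row per segment (activity bout, 1-min or 2-min window) with
#' up to twelve features: mean, min, max and standard deviation of each of
#' AFT, heart rate and percent heart-rate reserve over the segment. Each
#' segment is labeled with the most recent fatigue rating at or before its
#' end, collapsed to a level via \code{\link{rof_to_level}}. Columns are
#' min-max normalized over the table unless a pre-fitted scaler is given
#' (held-out tables must reuse the training scaler).
#'
#' @param aft,hr,hrr Aligned per-second series of equal length.
#' @param scheme Segmentation: "per-activity", "1-min", "2-min" or "5-min".
#' @param activity Activity-code series (per-activity scheme).
#' @param rof data.frame(t_s, rating) of sparse fatigue ratings; every
#'   segment must have a rating at or before its end.
#' @param normalize Min-max normalize columns over this table.
#' @param scaler Optional \code{scaler_params} to apply instead of fitting.
#' @return Object of class \code{fatigue_features}: list with \code{x}
#'   (n x 12 matrix), \code{level} (factor of level names), \code{rating},
#'   \code{segments} (data.frame) and \code{scaler}.
#' @export
fatigue_features <- function(aft, hr, hrr, scheme = "per-activity",
                             activity = NULL, rof, normalize = TRUE,
                             scaler = NULL) {
  n <- length(aft)
  stopifnot(length(hr) == n, length(hrr) == n, nrow(rof) >= 1)
  seg <- .segments(n, scheme, activity)
  stats4 <- function(v) c(mean(v), min(v), max(v), sd(v))
  x <- t(vapply(seq_len(nrow(seg)), function(i) {
    idx <- (seg$start_s[i] + 1):seg$end_s[i]
    c(stats4(unclass(aft)[idx]), stats4(hr[idx]), stats4(hrr[idx]))
  }, numeric(12)))
  # constant segments have sd 0; a single-second segment's sd is NA -> 0
  x[is.na(x)] <- 0
  colnames(x) <- .fatigue_stat_names
  rating <- vapply(seg$end_s, function(e) {
    prior <- rof$rating[rof$t_s <= e]
    if (!length(prior)) return(NA_integer_)
    as.integer(prior[length(prior)])
  }, integer(1))
  if (any(is.na(rating)))
    stop("segment without any fatigue rating at or before its end")
  lv <- rof_to_level(rating)
  if (!is.null(scaler)) {
    x <- apply_scaler(x, scaler)
  } else if (normalize) {
    scaler <- fit_scaler(x, "minmax")
    x <- apply_scaler(x, scaler)
  }
  structure(list(x = x,
                 level = factor(lv$level_name, levels = fatigue_levels()),
                 rating = rating, segments = seg, scheme = scheme,
                 scaler = scaler),
            class = "fatigue_features")
}

#' @export
print.fatigue_features <- function(x, ...) {
  cat(sprintf("Fatigue feature table (%s): %d segments x %d features\n",
              x$scheme, nrow(x$x), ncol(x$x)))
  print(table(droplevels(x$level)))
  invisible(x)
}

#' Cohort per-activity fatigue feature table
#'
#' Stacks the per-activity fatigue features of every cohort session (one
#' row per participant x activity bout; 10 participants performing all 14
#' activities yield 140 rows), using each session's actual VO2 and heart
#' rate. Columns are min-max normalized over the combined table.
#'
#' @param sessions List of \code{\link{session_features}} objects.
#' @param mac A \code{mac_table}.
#' @param normalize Min-max normalize the stacked table.
#' @return A \code{fatigue_features} with an extra \code{subject} element.
#' @export
cohort_fatigue_table <- function(sessions, mac = mac_table(),
                                 normalize = TRUE) {
  parts <- lapply(sessions, function(s) {
    aft <- compute_aft(s$vo2, as.character(s$activity), mac, s$body_mass)
    hrr <- compute_hrr(s$hr, s$profile$resting_hr, s$profile$age)
    fatigue_features(aft, s$hr, hrr, "per-activity",
                     as.character(s$activity), s$rof, normalize = FALSE)
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  level <- factor(unlist(lapply(parts, function(p) as.character(p$level))),
                  levels = fatigue_levels())
  scaler <- NULL
  if (normalize) {
    scaler <- fit_scaler(x, "minmax")
    x <- apply_scaler(x, scaler)
  }
  structure(list(x = x, level = level,
                 rating = unlist(lapply(parts, `[[`, "rating")),
                 segments = do.call(rbind, lapply(parts, `[[`, "segments")),
                 subject = rep(vapply(sessions, `[[`, character(1),
                                      "subject"),
                               vapply(parts, function(p) nrow(p$x),
                                      integer(1))),
                 scheme = "per-activity", scaler = scaler),
            class = "fatigue_features")
}

#' Named feature subsets of the fatigue table
#'
#' The seven combinations compared in the classifier study: AFT, HR, %HRR
#' alone, the three pairs, and all twelve features.
#'
#' @return Named list of column-name vectors.
#' @export
fatigue_feature_subsets <- function() {
  grp <- function(p) paste(p, c("mean", "min", "max", "sd"), sep = "_")
  list("AFT" = grp("aft"), "HR" = grp("hr"), "HRR" = grp("hrr"),
       "AFT+HR" = c(grp("aft"), grp("hr")),
       "AFT+HRR" = c(grp("aft"), grp("hrr")),
       "HR+HRR" = c(grp("hr"), grp("hrr")),
       "AFT+HR+HRR" = c(grp("aft"), grp("hr"), grp("hrr")))
}

# ---- the ten classical classifiers ------------------------------------

# AdaBoost (SAMME) over shallow rpart trees; no boosting package ships
# with the environment, and the multi-class SAMME update is short.
.adaboost_fit <- function(x, y, M = 50, maxdepth = 2) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  n <- length(y)
  w <- rep(1 / n, n)
  df <- data.frame(x)
  df$.y <- y
  fits <- list(); alphas <- numeric(0)
  for (m in seq_len(M)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 4,
                          xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    fits[[length(fits) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-8) break
  }
  structure(list(fits = fits, alphas = alphas, levels = levels(y)),
            class = "adaboost_samme")
}

#' @export
predict.adaboost_samme <- function(object, newdata, ...) {
  df <- data.frame(newdata)
  votes <- matrix(0, nrow(df), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (m in seq_along(object$fits)) {
    p <- as.character(predict(object$fits[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(p, object$levels))] <-
      votes[cbind(seq_len(nrow(df)), match(p, object$levels))] +
      object$alphas[m]
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' Names of the ten fatigue classifiers
#' @return Character vector: RF, DT, NB, LDA, QDA, SVM, ADA, LR, KNN, MLP.
#' @export
classifier_names <- function()
  c("RF", "DT", "NB", "LDA", "QDA", "SVM", "ADA", "LR", "KNN", "MLP")

# fit one named classifier; returns a list(fit, predict(fit, x))
.fit_one <- function(model, x, y, seed = 1) {
  y <- droplevels(as.factor(y))
  df <- data.frame(x)
  df$.y <- y
  with_seed(seed, switch(
    model,
    RF = {
      fit <- randomForest::randomForest(x = data.frame(x), y = y)
      list(fit = fit, predict = function(nx)
        predict(fit, data.frame(nx)))
    },
    DT = {
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      list(fit = fit, predict = function(nx)
        predict(fit, data.frame(nx), type = "class"))
    },
    NB = {
      fit <- e1071::naiveBayes(x = data.frame(x), y = y)
      list(fit = fit, predict = function(nx)
        predict(fit, data.frame(nx)))
    },
    LDA = {
      fit <- MASS::lda(x, grouping = y)
      list(fit = fit, predict = function(nx)
        predict(fit, nx)$class)
    },
    QDA = {
      fit <- MASS::qda(x, grouping = y)
      list(fit = fit, predict = function(nx)
        predict(fit, nx)$class)
    },
    SVM = {
      fit <- e1071::svm(x = x, y = y)
      list(fit = fit, predict = function(nx) predict(fit, nx))
    },
    ADA = {
      fit <- .adaboost_fit(x, y)
      list(fit = fit, predict = function(nx) predict(fit, nx))
    },
    LR = {
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                            MaxNWts = 5000)
      list(fit = fit, predict = function(nx)
        predict(fit, data.frame(nx)))
    },
    KNN = {
      list(fit = list(x = x, y = y), predict = function(nx)
        class::knn(x, nx, y, k = 5))
    },
    MLP = {
      fit <- nnet::nnet(x, nnet::class.ind(y), softmax = TRUE, size = 8,
                        decay = 1e-3, maxit = 300, trace = FALSE)
      list(fit = fit, predict = function(nx) {
        pr <- predict(fit, nx)
        factor(colnames(pr)[max.col(pr, ties.method = "first")],
               levels = levels(y))
      })
    },
    stop("unknown model: ", model)))
}

#' Compare the ten classical fatigue classifiers
#'
#' Trains RF, DT, NB, LDA, QDA, SVM, AdaBoost, logistic regression, KNN
#' and MLP on each requested feature subset under stratified k-fold
#' cross-validation (library-default hyperparameters, fixed seed) and
#' reports fold-averaged accuracy and macro precision/recall/F1 plus the
#' pooled confusion matrix. The best model per subset is the one with the
#' highest accuracy, ties broken by F1. Models that fail on a fold (e.g.
#' a singular within-class covariance for QDA) are reported with NA
#' metrics rather than aborting the comparison.
#'
#' @param features A \code{fatigue_features} (or a plain feature matrix).
#' @param y Level labels (unused when \code{features} carries them).
#' @param subsets Named list of column subsets; default
#'   \code{\link{fatigue_feature_subsets}}.
#' @param folds Cross-validation folds (default 10).
#' @param models Classifier names to include.
#' @param seed Integer seed for fold assignment and stochastic learners.
#' @return Object of class \code{classifier_comparison}: per subset a list
#'   with \code{metrics} (data.frame per model), \code{confusion} (list),
#'   \code{best} (model name); plus the \code{cv} descriptor.
#' @export
compare_classifiers <- function(features, y = NULL,
                                subsets = fatigue_feature_subsets(),
                                folds = 10, models = classifier_names(),
                                seed = 1) {
  if (inherits(features, "fatigue_features")) {
    x <- features$x
    y <- droplevels(features$level)
  } else {
    x <- features
    y <- droplevels(as.factor(y))
  }
  if (nlevels(y) < 2) stop("need at least 2 classes")
  fold_id <- stratified_folds(y, folds, seed = seed)
  lev <- levels(y)

  out <- lapply(names(subsets), function(sn) {
    cols <- intersect(subsets[[sn]], colnames(x))
    xs <- x[, cols, drop = FALSE]
    metrics <- list(); confusions <- list()
    for (model in models) {
      per_fold <- matrix(NA_real_, folds, 4,
                         dimnames = list(NULL, c("accuracy", "precision",
                                                 "recall", "f1")))
      cm_pool <- matrix(0L, length(lev), length(lev),
                        dimnames = list(lev, lev))
      failed <- FALSE
      for (fi in seq_len(folds)) {
        tr <- fold_id != fi; te <- !tr
        if (!any(te)) next
        res <- tryCatch({
          cl <- .fit_one(model, xs[tr, , drop = FALSE], y[tr],
                         seed = child_seed(seed, fi))
          pred <- cl$predict(xs[te, , drop = FALSE])
          cm <- confusion_matrix(y[te], pred, levels = lev)
          list(cm = cm)
        }, error = function(e) e)
        if (inherits(res, "error")) { failed <- TRUE; next }
        per_fold[fi, ] <- unlist(classification_metrics(res$cm))
        cm_pool <- cm_pool + res$cm
      }
      metrics[[model]] <- colMeans(per_fold, na.rm = !failed)
      if (failed) metrics[[model]][] <- NA_real_
      confusions[[model]] <- cm_pool
    }
    mdf <- data.frame(model = names(metrics),
                      do.call(rbind, metrics), row.names = NULL)
    ok <- !is.na(mdf$accuracy)
    best <- if (any(ok))
      mdf$model[ok][order(-mdf$accuracy[ok], -mdf$f1[ok])][1]
    else NA_character_
    list(subset = sn, columns = cols, metrics = mdf,
         confusion = confusions, best = best)
  })
  names(out) <- names(subsets)
  structure(list(subsets = out,
                 cv = sprintf("stratified %d-fold, seed %d", folds, seed)),
            class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, ...) {
  cat("Classifier comparison (", x$cv, ")\n", sep = "")
  for (s in x$subsets) {
    cat(sprintf("\n-- features: %s (best: %s)\n", s$subset, s$best))
    print(s$metrics, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Train one fatigue classifier on a feature table
#'
#' @param features A \code{fatigue_features} table (training population).
#' @param model One of \code{\link{classifier_names}} (default "DT").
#' @param subset Column subset name or character vector (default "AFT").
#' @param seed Integer seed.
#' @return Object of class \code{fatigue_classifier} carrying the fit, the
#'   training scaler and the selected columns.
#' @export
fit_fatigue_classifier <- function(features, model = "DT", subset = "AFT",
                                   seed = 1) {
  stopifnot(inherits(features, "fatigue_features"))
  cols <- if (length(subset) == 1 && subset %in%
              names(fatigue_feature_subsets()))
    fatigue_feature_subsets()[[subset]] else subset
  y <- droplevels(features$level)
  cl <- .fit_one(model, features$x[, cols, drop = FALSE], y, seed = seed)
  structure(list(model = model, subset = subset, columns = cols,
                 fit = cl, levels = levels(y), scaler = features$scaler),
            class = "fatigue_classifier")
}

#' @export
predict.fatigue_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "fatigue_features")) newdata$x else newdata
  p <- object$fit$predict(x[, object$columns, drop = FALSE])
  factor(as.character(p), levels = fatigue_levels())
}

#' @export
print.fatigue_classifier <- function(x, ...) {
  cat(sprintf("Fatigue classifier: %s on [%s]\n", x$model,
              paste(x$columns, collapse = ", ")))
  invisible(x)
}

#' Evaluate a trained fatigue classifier on an unseen session
#'
#' For each windowing scheme, predicts fatigue levels from the
#' predicted-AFT feature table, reports accuracy, macro
#' precision/recall/F1 and the confusion matrix against the actual labels,
#' and regresses actual on predicted window-average AFT (reporting R^2
#' and RMSE) when the AFT pairs are supplied.
#'
#' @param classifier A \code{fatigue_classifier}.
#' @param tables Named list (scheme -> \code{fatigue_features}) built from
#'   the unseen session's predicted AFT, labeled with actual ratings.
#' @param aft_pairs Optional named list (scheme -> data.frame with columns
#'   \code{actual}, \code{predicted}) of window-average AFT values.
#' @return Object of class \code{unseen_report}: per scheme a list with
#'   \code{metrics}, \code{confusion}, \code{actual}, \code{predicted} and
#'   (if pairs given) \code{aft_r2}, \code{aft_rmse}.
#' @export
evaluate_unseen <- function(classifier, tables, aft_pairs = NULL) {
  stopifnot(length(tables) >= 1)
  out <- lapply(names(tables), function(sn) {
    tb <- tables[[sn]]
    if (nrow(tb$x) == 0) stop("scheme with zero segments: ", sn)
    pred <- predict(classifier, tb)
    lev <- fatigue_levels()
    cm <- confusion_matrix(tb$level, pred, levels = lev)
    keep <- rowSums(cm) > 0 | colSums(cm) > 0
    cm <- cm[keep, keep, drop = FALSE]
    res <- list(scheme = sn, metrics = classification_metrics(cm),
                confusion = cm, actual = tb$level, predicted = pred)
    if (!is.null(aft_pairs) && sn %in% names(aft_pairs)) {
      ap <- aft_pairs[[sn]]
      fit <- lm(actual ~ predicted, data = ap)
      res$aft_r2 <- summary(fit)$r.squared
      res$aft_rmse <- sqrt(mean((ap$actual - ap$predicted)^2))
    }
    res
  })
  names(out) <- names(tables)
  structure(out, class = "unseen_report")
}

#' @export
print.unseen_report <- function(x, ...) {
  for (s in x) {
    cat(sprintf("scheme %s: accuracy %.3f, F1 %.3f", s$scheme,
                s$metrics$accuracy, s$metrics$f1))
    if (!is.null(s$aft_r2))
      cat(sprintf(", AFT R2 %.3f RMSE %.4f", s$aft_r2, s$aft_rmse))
    cat("\n")
  }
  invisible(x)
}

#' Chi-squared test of actual vs predicted fatigue-level agreement
#'
#' Pearson chi-squared statistic (no continuity correction) on the r x c
#' contingency table of actual by predicted levels, with categories fixed
#' to the levels present in the pooled data; df = (r-1)(c-1).
#'
#' @param actual,predicted Level labels of equal length with at least two
#'   distinct levels each.
#' @return List: \code{statistic}, \code{df}, \code{p_value},
#'   \code{table}.
#' @export
chi_squared_agreement <- function(actual, predicted) {
  lev <- sort(unique(c(as.character(actual), as.character(predicted))))
  a <- factor(as.character(actual), levels = lev)
  p <- factor(as.character(predicted), levels = lev)
  tab <- table(actual = a, predicted = p)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table: need >= 2 levels on both margins")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}
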