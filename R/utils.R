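# Shared internal helpers: seeded evaluation, classification metrics.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed, kept within the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + stream * 12347L) %% 2147483647)
}

#' Confusion matrix with fixed level set
#'
#' @param actual,predicted Vectors coercible to factors.
#' @param levels Level set defining rows/columns; defaults to the union of
#'   levels present in either vector.
#' @return Integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, levels = NULL) {
  if (is.null(levels))
    levels <- sort(unique(c(as.character(actual), as.character(predicted))))
  a <- factor(as.character(actual), levels = levels)
  p <- factor(as.character(predicted), levels = levels)
  as.matrix(table(actual = a, predicted = p))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy plus macro-averaged precision, recall and F1. Per-class
#' precision/recall with an empty denominator are treated as 0 before
#' macro-averaging.
#'
#' @param cm Square confusion matrix (rows actual, columns predicted).
#' @return Named list: accuracy, precision, recall, f1.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  acc <- if (total > 0) sum(diag(cm)) / total else NA_real_
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # macro averages over classes that actually occur
  keep <- rowSums(cm) > 0 | colSums(cm) > 0
  list(accuracy = acc,
       precision = mean(prec[keep]),
       recall = mean(rec[keep]),
       f1 = mean(f1[keep]))
}

#' Regression metrics
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Named list: r2 (1 - SSres/SStot) and rmse.
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  ss_res <- sum((actual - predicted)^2)
  ss_tot <- sum((actual - mean(actual))^2)
  list(r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       rmse = sqrt(mean((actual - predicted)^2)))
}

# Stratified k-fold assignment. Returns an integer vector of fold ids.
# Classes with fewer members than folds are spread round-robin (logged).
stratified_folds <- function(y, k, seed = 1) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        message(sprintf(
          "stratification fallback: class '%s' has %d < %d members",
          cl, length(idx), k))
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
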