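# S3 front end of the compiled bidirectional LSTM.

#' Fit a bidirectional LSTM sequence model
#'
#' Two stacked bidirectional LSTM layers with dropout, a relu dense layer
#' and a linear output head, trained with Adam. Classification uses a
#' softmax output with categorical cross-entropy; regression a single
#' linear unit with mean squared error. Training is deterministic given
#' \code{seed} (single-threaded, fixed batch order). An optional validation
#' split drives early stopping on the validation loss.
#'
#' @param x Sequences: an N x L x F array or a \code{\link{make_sequences}}
#'   result.
#' @param y Targets, length N: a factor (classification) or numeric vector
#'   (regression).
#' @param task "classification" or "regression"; inferred from \code{y}
#'   when missing.
#' @param hidden Hidden sizes of the two BiLSTM layers, default c(64, 32).
#' @param dense Dense-layer width, default 32.
#' @param dropout Dropout rate after each BiLSTM block, default 0.3.
#' @param epochs Maximum training epochs, default 50.
#' @param batch_size Minibatch size, default 64.
#' @param learning_rate Adam step size, default 1e-3.
#' @param validation_split Fraction held out for early stopping,
#'   default 0.1 (0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return Object of class \code{bilstm} with elements \code{params}
#'   (weight matrices), \code{task}, \code{levels} (classification),
#'   \code{history}, \code{dims}, \code{call}.
#' @seealso \code{\link{predict.bilstm}}
#' @export
bilstm <- function(x, y, task = NULL, hidden = c(64, 32), dense = 32,
                   dropout = 0.3, epochs = 50, batch_size = 64,
                   learning_rate = 1e-3, validation_split = 0.1,
                   patience = 5, seed = 1, verbose = FALSE) {
  if (inherits(x, "seq_batch")) x <- x$x
  stopifnot(is.array(x), length(dim(x)) == 3, length(hidden) == 2)
  if (is.null(task))
    task <- if (is.factor(y) || is.character(y)) "classification"
            else "regression"
  task <- match.arg(task, c("classification", "regression"))
  N <- dim(x)[1]; L <- dim(x)[2]; F <- dim(x)[3]
  stopifnot(length(y) == N, N >= 2)

  lev <- NULL
  if (task == "classification") {
    y <- as.factor(y)
    lev <- levels(y)
    Y <- matrix(0, N, length(lev))
    Y[cbind(seq_len(N), as.integer(y))] <- 1
  } else {
    if (any(!is.finite(y))) stop("regression targets must be finite")
    Y <- matrix(as.numeric(y), ncol = 1)
  }
  out_dim <- ncol(Y)
  xc <- aperm(x, c(1, 3, 2))  # (N, F, L): slice t = design matrix at step t

  params <- .bilstm_init_cpp(F, hidden[1], hidden[2], dense, out_dim,
                             child_seed(seed, 17L))
  fit <- .bilstm_train_cpp(params, xc, Y, task, as.integer(epochs),
                           as.integer(batch_size), learning_rate, dropout,
                           validation_split, as.integer(patience),
                           child_seed(seed, 29L), isTRUE(verbose))
  if (any(!is.finite(unlist(fit$train_loss))))
    stop("training diverged (non-finite loss); lower learning_rate")
  structure(list(params = fit$params, task = task, levels = lev,
                 history = list(train = fit$train_loss,
                                validation = fit$val_loss),
                 dims = list(L = L, features = F, hidden = hidden,
                             dense = dense, output = out_dim),
                 config = list(dropout = dropout, epochs = epochs,
                               batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed),
                 feature_names = dimnames(x)[[3]], call = match.call()),
            class = "bilstm")
}

#' Predict from a fitted BiLSTM
#'
#' @param object A \code{bilstm} fit.
#' @param newdata N x L x F array or \code{seq_batch} with the same L and
#'   F the model was trained on.
#' @param type "response" (class labels / clipped regression values) or
#'   "prob" (class probabilities; classification only).
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return Factor of predicted classes, probability matrix, or numeric
#'   predictions (regression values are clipped below at 0: negative
#'   oxygen uptake is not physical).
#' @export
predict.bilstm <- function(object, newdata, type = c("response", "prob"),
                           batch_size = 256, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "seq_batch")) newdata <- newdata$x
  stopifnot(is.array(newdata), length(dim(newdata)) == 3,
            dim(newdata)[2] == object$dims$L,
            dim(newdata)[3] == object$dims$features)
  xc <- aperm(newdata, c(1, 3, 2))
  out <- .bilstm_predict_cpp(object$params, xc, object$task,
                             as.integer(batch_size))
  if (object$task == "classification") {
    colnames(out) <- object$levels
    if (type == "prob") return(out)
    factor(object$levels[max.col(out, ties.method = "first")],
           levels = object$levels)
  } else {
    pmax(0, as.numeric(out))
  }
}

#' @export
print.bilstm <- function(x, ...) {
  cat(sprintf(
    "BiLSTM %s model: L=%d, %d features, hidden %d/%d, %s\n",
    x$task, x$dims$L, x$dims$features, x$dims$hidden[1], x$dims$hidden[2],
    if (x$task == "classification")
      sprintf("%d classes", x$dims$output) else "1 output"))
  nt <- length(x$history$train)
  if (nt) cat(sprintf("  trained %d epochs, final loss %.5f\n", nt,
                      x$history$train[[nt]]))
  invisible(x)
}

#' @export
summary.bilstm <- function(object, ...) {
  np <- sum(vapply(object$params, length, numeric(1)))
  cat(sprintf("BiLSTM %s model with %d parameters\n", object$task, np))
  print(object)
  if (length(object$history$validation))
    cat(sprintf("  best validation loss %.5f\n",
                min(unlist(object$history$validation))))
  invisible(object)
}

#' @export
coef.bilstm <- function(object, ...) object$params

#' @export
plot.bilstm <- function(x, ...) {
  tr <- unlist(x$history$train)
  plot(seq_along(tr), tr, type = "b", xlab = "epoch", ylab = "loss", ...)
  vl <- unlist(x$history$validation)
  if (length(vl)) {
    graphics::lines(seq_along(vl), vl, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}
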