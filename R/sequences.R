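# Sliding-window sequence construction for the recurrent models.

#' Build fixed-length sequences from a per-second feature matrix
#'
#' Sliding windows of \code{L} rows with the given stride over one
#' session's feature matrix (sequences never span sessions). With
#' \code{pad = "repeat"} the first \code{L - 1} seconds are covered by
#' left-padding with the first row, so every second from the first stride
#' position onwards receives a window ending at it; with \code{pad =
#' "none"} only complete windows are produced, giving
#' \code{max(0, floor((T - L) / stride) + 1)} sequences. The prediction
#' target of a sequence is taken at its final step, whose row index is
#' returned in \code{index}.
#'
#' @param x Numeric T x F matrix for a single session (non-empty).
#' @param L Sequence length in steps (default 100).
#' @param stride Step between consecutive window ends (default 1).
#' @param pad "repeat" (default) or "none".
#' @return Object of class \code{seq_batch}: list with \code{x} (array
#'   N x L x F), \code{index} (end-row of each window) and \code{L}.
#' @export
make_sequences <- function(x, L = 100L, stride = 1L,
                           pad = c("repeat", "none")) {
  pad <- match.arg(pad)
  if (!is.matrix(x) || nrow(x) == 0) stop("x must be a non-empty matrix")
  T <- nrow(x); F <- ncol(x)
  ends <- if (pad == "repeat") seq(1L, T, by = stride)
          else if (T < L) integer(0) else seq(L, T, by = stride)
  ends <- as.integer(ends)
  N <- length(ends)
  out <- array(0, dim = c(N, L, F),
               dimnames = list(NULL, NULL, colnames(x)))
  for (n in seq_len(N)) {
    rows <- (ends[n] - L + 1L):ends[n]
    rows[rows < 1L] <- 1L
    out[n, , ] <- x[rows, , drop = FALSE]
  }
  structure(list(x = out, index = ends, L = L), class = "seq_batch")
}

#' @export
print.seq_batch <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("Sequence batch: %d sequences x %d steps x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# rbind-combine seq_batch objects from several sessions; indices get a
# session id column attached.
combine_seq_batches <- function(batches) {
  stopifnot(length(batches) >= 1)
  L <- batches[[1]]$L
  F <- dim(batches[[1]]$x)[3]
  Ns <- vapply(batches, function(b) dim(b$x)[1], integer(1))
  out <- array(0, dim = c(sum(Ns), L, F))
  at <- 0L
  for (b in batches) {
    n <- dim(b$x)[1]
    if (n > 0) out[(at + 1):(at + n), , ] <- b$x
    at <- at + n
  }
  structure(list(x = out,
                 index = unlist(lapply(batches, `[[`, "index")),
                 session = rep(seq_along(batches), Ns), L = L),
            class = "seq_batch")
}
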