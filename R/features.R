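# Per-second statistical features and the two feature-selection procedures.

.stat_names <- c("mean", "sd", "var", "min", "max", "range", "median",
                 "rms", "mav", "iqr", "skew", "kurt", "zc", "wl", "ssc",
                 "energy", "domfreq")
.channel_names <- c(paste0("emg", 1:8),
                    "ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")

#' Names of the 289 per-window features
#'
#' 17 statistics per channel over 17 channels (8 EMG + 9 IMU), named
#' \code{<channel>_<stat>}. The statistics, in order: mean, standard
#' deviation (n-1), variance, min, max, range, median, RMS, mean absolute
#' value, interquartile range (type-7 quantiles), skewness (m3/m2^1.5),
#' excess kurtosis (m4/m2^2 - 3), zero-crossing count (strict sign
#' products), waveform length (sum of absolute first differences),
#' slope-sign-change count, signal energy (sum of squares), and dominant
#' frequency (periodogram bin with maximal power, DC excluded, in Hz).
#'
#' @return Character vector of length 289, in stable column order.
#' @export
feature_names <- function() {
  as.vector(t(outer(.channel_names, .stat_names, paste, sep = "_")))
}

#' Extract the 289 features of one synchronized window
#'
#' @param window One element of a \code{\link{synchronize}} result: a list
#'   with \code{emg_block} (200 x 8) and \code{imu_block} (50 x 9);
#'   all samples must be finite.
#' @param emg_rate,imu_rate Sampling rates in Hz.
#' @return Named numeric vector of length 289.
#' @export
extract_window_features <- function(window, emg_rate = 200, imu_rate = 50) {
  eb <- window$emg_block; ib <- window$imu_block
  if (!is.matrix(eb) || nrow(eb) != emg_rate || ncol(eb) != 8)
    stop("emg_block must be a ", emg_rate, " x 8 matrix")
  if (!is.matrix(ib) || nrow(ib) != imu_rate || ncol(ib) != 9)
    stop("imu_block must be a ", imu_rate, " x 9 matrix")
  if (any(!is.finite(eb)) || any(!is.finite(ib)))
    stop("non-finite samples in window")
  v <- c(.window_stats_cpp(eb, emg_rate), .window_stats_cpp(ib, imu_rate))
  stats::setNames(as.numeric(v), feature_names())
}

#' Per-second feature matrix for a whole session
#'
#' Fast path over \code{\link{extract_window_features}}: computes the
#' T x 289 feature matrix for every complete one-second window of a
#' session, together with the aligned per-second targets.
#'
#' @param session A \code{session_data}.
#' @return List of class \code{session_features}: \code{x} (T x 289
#'   matrix with stable column names), \code{activity} (factor over the 14
#'   codes), \code{vo2}, \code{hr} (numeric), \code{rof} (data.frame),
#'   \code{subject} (participant id), \code{body_mass}, \code{profile}.
#' @export
session_features <- function(session) {
  stopifnot(inherits(session, "session_data"))
  er <- session$config$emg_rate; ir <- session$config$imu_rate
  x <- .session_features_cpp(session$emg, session$imu, er, ir)
  T <- min(nrow(x), length(session$vo2), length(session$hr),
           length(session$activity))
  x <- x[seq_len(T), , drop = FALSE]
  colnames(x) <- feature_names()
  structure(list(x = x,
                 activity = factor(session$activity[seq_len(T)],
                                   levels = activity_codes()),
                 vo2 = session$vo2[seq_len(T)], hr = session$hr[seq_len(T)],
                 rof = session$rof, subject = session$profile$participant_id,
                 body_mass = session$profile$body_mass,
                 profile = session$profile),
            class = "session_features")
}

#' @export
print.session_features <- function(x, ...) {
  cat(sprintf("Session features: %s, %d windows x %d features\n",
              x$subject, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' One-way ANOVA F scores of feature columns against a class label
#'
#' For each column, the between-class over within-class variance ratio
#' F = (SSB / (k-1)) / (SSW / (n-k)). Columns with zero within- and
#' between-class variance score 0.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels (factor or coercible), length nrow(x); every
#'   class must have at least 2 rows.
#' @return Named numeric vector of F scores per column.
#' @export
anova_f_scores <- function(x, y) {
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  n <- nrow(x)
  if (k < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 rows")
  gm <- colMeans(x)
  ssb <- numeric(ncol(x)); ssw <- numeric(ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - gm)^2
    ssw <- ssw + colSums(sweep(xi, 2, mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f) & ssb == 0] <- 0  # constant columns
  stats::setNames(f, colnames(x))
}

#' Select the top-k features by ANOVA F score
#'
#' Ranks columns by the one-way ANOVA F statistic of feature against the
#' activity label and returns the \code{k} highest-scoring column names
#' (ties broken by column order). With \code{k} equal to the column count
#' this is a pure ranking. Default \code{k = 100} as used for the activity
#' recognition feature set.
#'
#' @param x Feature matrix with column names.
#' @param y Class labels.
#' @param k Number of columns to keep (<= ncol(x)).
#' @return Character vector of selected column names, with the F scores
#'   attached as the \code{scores} attribute.
#' @export
anova_f_select <- function(x, y, k = 100) {
  stopifnot(k >= 1, k <= ncol(x))
  f <- anova_f_scores(x, y)
  ord <- order(-f, seq_along(f))  # ties keep column order
  sel <- colnames(x)[sort(ord[seq_len(k)])]
  structure(sel, scores = f[sel])
}

# Plug-in mutual information (nats) between x and y after equal-frequency
# discretization into `bins` bins each.
.mutual_information <- function(x, y, bins = 16) {
  qx <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 7))
  qy <- unique(quantile(y, probs = seq(0, 1, length.out = bins + 1),
                        type = 7))
  bx <- cut(x, breaks = qx, include.lowest = TRUE)
  by <- cut(y, breaks = qy, include.lowest = TRUE)
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

#' Select features by Pearson correlation and mutual information
#'
#' Keeps the columns whose absolute Pearson correlation with the continuous
#' target exceeds \code{r_threshold} AND whose estimated mutual information
#' (plug-in estimate over a 16-bin equal-frequency discretization, natural
#' log) exceeds \code{mi_threshold}. Both thresholds default to 0.1, the
#' setting used for the oxygen-uptake feature set; the selected count is
#' data-dependent. Zero-variance columns are excluded with a message.
#'
#' @param x Feature matrix with column names.
#' @param y Continuous target, length nrow(x).
#' @param r_threshold,mi_threshold Selection thresholds.
#' @param bins Bins for the MI discretization.
#' @return Character vector of selected names with \code{r} and \code{mi}
#'   attributes.
#' @export
corr_mi_select <- function(x, y, r_threshold = 0.1, mi_threshold = 0.1,
                           bins = 16) {
  stopifnot(length(y) == nrow(x))
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    message(sprintf("excluding %d zero-variance column(s)", sum(sds == 0)))
  usable <- which(sds > 0)
  r <- as.vector(cor(x[, usable, drop = FALSE], y))
  mi <- vapply(usable, function(j) .mutual_information(x[, j], y, bins),
               numeric(1))
  keep <- abs(r) > r_threshold & mi > mi_threshold
  sel <- colnames(x)[usable[keep]]
  structure(sel, r = stats::setNames(r[keep], sel),
            mi = stats::setNames(mi[keep], sel))
}

#' Fit a column scaler on training rows
#'
#' \code{minmax} maps the training minimum to 0 and maximum to 1 (used for
#' the oxygen-uptake model); \code{zscore} maps the training mean to 0 and
#' standard deviation to 1 (used for the activity model). Held-out rows
#' transformed with a fitted scaler may fall outside [0, 1]. Zero-range or
#' zero-sd columns are mapped to 0 with a message.
#'
#' @param x Training feature matrix.
#' @param mode "minmax" or "zscore".
#' @return Object of class \code{scaler_params}.
#' @export
fit_scaler <- function(x, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  if (mode == "minmax") {
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    rng <- hi - lo
    if (any(rng == 0))
      message(sprintf("%d zero-range column(s) mapped to 0", sum(rng == 0)))
    p <- list(mode = mode, center = lo, scale = ifelse(rng == 0, Inf, rng))
  } else {
    mu <- colMeans(x); s <- apply(x, 2, sd)
    if (any(s == 0))
      message(sprintf("%d zero-sd column(s) mapped to 0", sum(s == 0)))
    p <- list(mode = mode, center = mu, scale = ifelse(s == 0, Inf, s))
  }
  p$columns <- colnames(x)
  structure(p, class = "scaler_params")
}

#' Apply a fitted scaler
#'
#' @param x Feature matrix with the columns the scaler was fitted on.
#' @param params A \code{scaler_params} from \code{\link{fit_scaler}}.
#' @return Transformed matrix of the same shape.
#' @export
apply_scaler <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  if (!is.null(params$columns) && !is.null(colnames(x)))
    stopifnot(identical(colnames(x), params$columns))
  sweep(sweep(x, 2, params$center), 2, params$scale, `/`)
}
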