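# 289-feature extraction, selection procedures and scaling.

test_that("a window yields exactly 289 named, finite features", {
  s <- tiny_session(seed = 41, duration_s = c(2, 2),
                    acts = c("WALK", "HAM"), rof_interval_s = 2)
  w <- synchronize(s)[[1]]
  f <- extract_window_features(w)
  expect_length(f, 289)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_error(extract_window_features(list(
    emg_block = w$emg_block[1:100, ], imu_block = w$imu_block)), "200")
})

test_that("the null signal has null amplitude statistics", {
  w <- list(emg_block = matrix(0, 200, 8), imu_block = matrix(0, 50, 9))
  f <- extract_window_features(w)
  for (st in c("mean", "sd", "rms", "energy", "zc", "wl", "ssc",
               "mav", "domfreq"))
    expect_true(all(f[grepl(paste0("_", st, "$"), names(f))] == 0),
                info = st)
})

test_that("a pure sinusoid recovers its RMS and dominant frequency", {
  A <- 2.5
  tt <- (0:199) / 200
  w <- list(emg_block = matrix(A * sin(2 * pi * 10 * tt), 200, 8),
            imu_block = matrix(sin(2 * pi * 5 * (0:49) / 50), 50, 9))
  f <- extract_window_features(w)
  expect_lt(abs(f[["emg1_rms"]] - A / sqrt(2)) / (A / sqrt(2)), 0.01)
  expect_equal(unname(f[["emg3_domfreq"]]), 10)
  expect_equal(unname(f[["ax_domfreq"]]), 5)
})

test_that("every window statistic matches the straight-loop oracle", {
  set.seed(42)
  n_instances <- 0
  for (rep in 1:10) {
    eb <- matrix(rnorm(200 * 8, sd = runif(1, 0.1, 3)), 200, 8)
    ib <- matrix(rnorm(50 * 9) + runif(1, -2, 2), 50, 9)
    f <- extract_window_features(list(emg_block = eb, imu_block = ib))
    for (ch in 1:8) {
      o <- oracle_channel_stats(eb[, ch], 200)
      got <- f[paste0("emg", ch, "_",
                      c("mean", "sd", "var", "min", "max", "range",
                        "median", "rms", "mav", "iqr", "skew", "kurt",
                        "zc", "wl", "ssc", "energy", "domfreq"))]
      expect_equal(unname(got), unname(o), tolerance = 1e-9)
      n_instances <- n_instances + 1
    }
    imu_ch <- c("ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")
    for (ch in 1:9) {
      o <- oracle_channel_stats(ib[, ch], 50)
      got <- f[paste0(imu_ch[ch], "_",
                      c("mean", "sd", "var", "min", "max", "range",
                        "median", "rms", "mav", "iqr", "skew", "kurt",
                        "zc", "wl", "ssc", "energy", "domfreq"))]
      expect_equal(unname(got), unname(o), tolerance = 1e-9)
      n_instances <- n_instances + 1
    }
  }
  expect_gte(n_instances, 100)
})

test_that("ANOVA F scores equal the hand-computed variance ratio", {
  # 2-class toy, 3 rows per class
  x <- cbind(a = c(1, 2, 3, 7, 8, 9), b = c(5, 5, 5, 5, 5, 5),
             c = rnorm(6))
  y <- rep(c("u", "v"), each = 3)
  f <- anova_f_scores(x, y)
  expect_equal(unname(f["a"]), oracle_anova_f(x[, "a"], y),
               tolerance = 1e-12)
  # cross-check against the standard linear-model ANOVA
  expect_equal(unname(f["a"]),
               unname(summary(aov(x[, "a"] ~ factor(y)))[[1]]$`F value`[1]),
               tolerance = 1e-9)
  # constant column never outranks a discriminative one
  expect_identical(unname(f["b"]), 0)
  sel <- anova_f_select(x, y, k = 2)
  expect_false("b" %in% sel)
  expect_true("a" %in% sel)
  # k = ncol returns everything; selection is a ranking, not a filter
  expect_setequal(as.character(anova_f_select(x, y, k = 3)),
                  colnames(x))
  expect_error(anova_f_scores(x[1:3, ], y[1:3]), "2 classes")
  expect_error(anova_f_scores(x[c(1, 4, 5), ], y[c(1, 4, 5)]), "2 rows")
})

test_that("default ANOVA selection keeps 100 features", {
  set.seed(43)
  x <- matrix(rnorm(60 * 289), 60, 289,
              dimnames = list(NULL, feature_names()))
  y <- rep(letters[1:3], each = 20)
  x[y == "a", 1:20] <- x[y == "a", 1:20] + 2
  expect_length(anova_f_select(x, y), 100)
})

test_that("correlation + mutual-information selection behaves at both ends", {
  set.seed(44)
  n <- 5000
  y <- rnorm(n)
  x <- cbind(same = y, indep = rnorm(n), weak = 0.05 * y + rnorm(n))
  sel <- corr_mi_select(x, y)
  expect_true("same" %in% sel)
  expect_false("indep" %in% sel)
  expect_gte(attr(sel, "r")[["same"]], 0.999)
  # thresholds default to 0.1 and act as a conjunction
  sel2 <- corr_mi_select(x, y, r_threshold = 0, mi_threshold = 10)
  expect_length(sel2, 0)
  # zero-variance columns are excluded with a note
  x2 <- cbind(x, const = 1)
  expect_message(corr_mi_select(x2, y), "zero-variance")
})

test_that("scalers match a brute-force per-column transform", {
  set.seed(45)
  xtr <- matrix(rnorm(40 * 5, mean = 5, sd = 2), 40, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  xte <- matrix(rnorm(10 * 5, mean = 5, sd = 2), 10, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  mm <- fit_scaler(xtr, "minmax")
  tr <- apply_scaler(xtr, mm)
  expect_equal(unname(apply(tr, 2, min)), rep(0, 5))
  expect_equal(unname(apply(tr, 2, max)), rep(1, 5))
  te <- apply_scaler(xte, mm)
  manual <- sapply(1:5, function(j)
    (xte[, j] - min(xtr[, j])) / (max(xtr[, j]) - min(xtr[, j])))
  expect_equal(unname(te), unname(manual), tolerance = 1e-12)

  zs <- fit_scaler(xtr, "zscore")
  trz <- apply_scaler(xtr, zs)
  expect_equal(unname(colMeans(trz)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(trz, 2, sd)), rep(1, 5), tolerance = 1e-12)
  manualz <- sapply(1:5, function(j)
    (xte[, j] - mean(xtr[, j])) / sd(xtr[, j]))
  expect_equal(unname(apply_scaler(xte, zs)), unname(manualz),
               tolerance = 1e-12)

  # zero-range columns map to 0 instead of dividing by zero
  x0 <- cbind(xtr, k = 7)
  expect_message(s0 <- fit_scaler(x0, "minmax"), "zero-range")
  expect_true(all(apply_scaler(x0, s0)[, "k"] == 0))
})

test_that("feature names and order are stable across sessions", {
  a <- session_features(tiny_session(seed = 46, duration_s = c(2, 2),
                                     acts = c("CC", "IC"),
                                     rof_interval_s = 2))
  b <- session_features(tiny_session(seed = 47, duration_s = c(3, 2),
                                     acts = c("WRE", "DG"),
                                     rof_interval_s = 2))
  expect_identical(colnames(a$x), colnames(b$x))
  expect_identical(colnames(a$x), feature_names())
})
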