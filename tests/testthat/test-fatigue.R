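# Fatigue labels, per-segment features, classifier panel, agreement test.

test_that("ratings collapse to the five levels exactly as specified", {
  expected <- c(0, 1, 1, 2, 2, 2, 3, 3, 4, 4, 4)
  got <- rof_to_level(0:10)
  expect_identical(got$level, as.integer(expected))
  expect_identical(rof_to_level(0)$level_name, "None")
  expect_identical(rof_to_level(3)$level_name, "Moderate")
  expect_identical(rof_to_level(8)$level_name, "Very High")
  expect_error(rof_to_level(11), "0, 10")
  expect_error(rof_to_level(-1), "0, 10")
})

test_that("fatigue feature vectors have the documented 12-dim layout", {
  set.seed(71)
  n <- 360
  aft <- runif(n, 0.1, 0.5)
  hr <- runif(n, 70, 150)
  hrr <- runif(n, 0, 0.8)
  act <- rep(c("WALK", "CC", "HAM"), each = 120)
  rof <- data.frame(t_s = c(120, 240, 360), rating = c(1L, 4L, 6L))
  ft <- fatigue_features(aft, hr, hrr, "per-activity", act, rof)
  expect_identical(dim(ft$x), c(3L, 12L))
  expect_identical(colnames(ft$x),
                   c("aft_mean", "aft_min", "aft_max", "aft_sd",
                     "hr_mean", "hr_min", "hr_max", "hr_sd",
                     "hrr_mean", "hrr_min", "hrr_max", "hrr_sd"))
  expect_identical(as.character(ft$level),
                   c("Low", "Moderate", "High"))
  # normalization bounds
  expect_true(all(ft$x >= 0 & ft$x <= 1))
  # AFT-only subset has length 4
  expect_length(fatigue_feature_subsets()$AFT, 4)

  # constant segment: min = max = mean, sd = 0 (checked unnormalized)
  ftc <- fatigue_features(rep(0.3, 120), rep(100, 120), rep(0.4, 120),
                          "2-min", rof = data.frame(t_s = 120,
                                                    rating = 2L),
                          normalize = FALSE)
  expect_equal(unname(ftc$x[1, c("aft_mean", "aft_min", "aft_max")]),
               rep(0.3, 3))
  expect_equal(unname(ftc$x[1, "aft_sd"]), 0)

  # a segment with no rating at or before its end is an error
  expect_error(fatigue_features(aft, hr, hrr, "1-min", act,
                                data.frame(t_s = 400, rating = 1L)),
               "without any fatigue rating")
})

test_that("chi-squared agreement equals the brute-force statistic", {
  # hand-built diagonal 2x2 table
  actual <- rep(c("Low", "High"), each = 10)
  res <- chi_squared_agreement(actual, actual)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_equal(res$statistic, oracle_chisq(res$table))
  # 4 actual x 4 predicted levels give df = 9
  set.seed(72)
  a4 <- sample(fatigue_levels()[2:5], 200, TRUE)
  p4 <- sample(fatigue_levels()[2:5], 200, TRUE)
  r4 <- chi_squared_agreement(a4, p4)
  expect_equal(r4$df, 9)
  expect_equal(r4$statistic, oracle_chisq(r4$table), tolerance = 1e-9)
  expect_error(chi_squared_agreement(rep("Low", 5), rep("Low", 5)),
               "degenerate")
})

test_that("shuffled predictions give approximately uniform p-values", {
  set.seed(73)
  pv <- replicate(40, {
    a <- sample(c("Low", "Moderate", "High"), 120, TRUE)
    chi_squared_agreement(a, sample(a))$p_value
  })
  # under independence p is approximately U(0,1): KS check, loose bound
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 1e-3)
})

test_that("the classifier panel nails separable data and honors folds", {
  set.seed(74)
  n <- 60
  y <- rep(c("Low", "High"), each = n / 2)
  x <- cbind(aft_mean = c(rnorm(n / 2, 0.2, 0.01),
                          rnorm(n / 2, 0.5, 0.01)),
             aft_min = c(rnorm(n / 2, 0.15, 0.01),
                         rnorm(n / 2, 0.45, 0.01)),
             aft_max = runif(n), aft_sd = runif(n))
  cmp <- compare_classifiers(x, y, subsets = list(AFT = colnames(x)),
                             folds = 5, models = c("DT", "KNN", "LDA"),
                             seed = 1)
  m <- cmp$subsets$AFT$metrics
  expect_equal(m$accuracy[m$model == "DT"], 1.0)
  expect_true(cmp$subsets$AFT$best %in% c("DT", "KNN", "LDA"))
  # pooled confusion marginals reconcile with sample count
  expect_equal(sum(cmp$subsets$AFT$confusion$DT), n)
})

test_that("fold assignment partitions rows with stratification", {
  y <- factor(rep(c("a", "b", "c"), times = c(30, 20, 10)))
  f <- aftmon:::stratified_folds(y, 10, seed = 4)
  expect_length(f, 60)
  expect_true(all(f %in% 1:10))
  # every row lands in exactly one fold; class "a" spreads 3 per fold
  expect_identical(as.integer(table(f[y == "a"])), rep(3L, 10))
})

test_that("label-shuffled tables score near majority-class prevalence", {
  set.seed(75)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("aft_", c("mean", "min",
                                                     "max", "sd"))))
  y <- sample(c("Low", "Moderate"), n, TRUE, prob = c(0.6, 0.4))
  cmp <- compare_classifiers(x, y, subsets = list(AFT = colnames(x)),
                             folds = 5, models = "DT", seed = 2)
  acc <- cmp$subsets$AFT$metrics$accuracy[1]
  prev <- max(table(y)) / n
  expect_lt(abs(acc - prev), 4 * sqrt(prev * (1 - prev) / n) + 0.05)
})

test_that("accuracy always equals the confusion-matrix trace ratio", {
  set.seed(76)
  for (rep in 1:10) {
    lev <- letters[1:sample(2:5, 1)]
    a <- sample(lev, 100, TRUE)
    p <- sample(lev, 100, TRUE)
    cm <- confusion_matrix(a, p)
    expect_equal(classification_metrics(cm)$accuracy,
                 sum(a == p) / 100, tolerance = 1e-12)
    expect_equal(unname(rowSums(cm)),
                 unname(as.numeric(table(factor(a, sort(unique(c(a, p))))))))
  }
})

test_that("the SAMME booster learns a separable two-class problem", {
  set.seed(77)
  n <- 100
  x <- cbind(u = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), v = rnorm(n))
  y <- factor(rep(c("a", "b"), each = n / 2))
  fit <- aftmon:::.adaboost_fit(x, y)
  expect_gt(mean(predict(fit, x) == y), 0.95)
})

test_that("unseen-session evaluation is exact on identical predictions", {
  set.seed(78)
  n <- 14400  # 240 one-minute segments
  aft <- runif(n, 0.1, 0.5)
  rof <- data.frame(t_s = seq(60, n, 60),
                    rating = rep(c(1L, 4L, 6L, 9L), length.out = n / 60))
  tb <- fatigue_features(aft, runif(n, 80, 150), runif(n), "1-min",
                         rof = rof)
  # a classifier that predicts the truth: train on the table itself with
  # a tree given perfectly informative features
  tb2 <- tb
  tb2$x <- cbind(tb$x,
                 aft_mean = as.numeric(as.integer(tb$level)))[, -1]
  colnames(tb2$x)[ncol(tb2$x)] <- "aft_mean"
  clf <- fit_fatigue_classifier(tb2, model = "DT", subset = "AFT")
  # lm warns about the (intentionally) perfect self-fit
  rep <- suppressWarnings(
    evaluate_unseen(clf, list("1-min" = tb2),
                    list("1-min" = data.frame(actual = tb$x[, 1],
                                              predicted = tb$x[, 1]))))
  expect_equal(rep$`1-min`$metrics$accuracy, 1)
  cm <- rep$`1-min`$confusion
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  # self-regression of AFT is a perfect fit
  expect_equal(rep$`1-min`$aft_r2, 1)
  expect_equal(rep$`1-min`$aft_rmse, 0)
})
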