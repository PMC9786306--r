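# AFT, %HRR, windowed averages and the exposure flag.

test_that("AFT arithmetic follows the unit-reconciled ratio", {
  mt <- mac_table()
  # absolute VO2 equal to the activity's MAC gives AFT = 1 exactly
  for (act in c("WALK", "IBDL", "HAM")) {
    mac <- mt$mac[[mt$category[[act]]]]
    vo2 <- mac * 1000 / 80
    expect_equal(as.numeric(compute_aft(vo2, act, mt, 80)), 1)
  }
  # worked example: 11.2 mL/kg/min, 75 kg, walking
  a <- compute_aft(11.2, "WALK", mt, 75)
  expect_equal(as.numeric(a), (11.2 * 75 / 1000) / 2.946, tolerance = 1e-12)
  expect_equal(round(as.numeric(a), 4), 0.2851)
  expect_equal(as.numeric(compute_aft(0, "WALK", mt, 75)), 0)
  expect_error(compute_aft(10, "XXX", mt, 75), "unmapped")
})

test_that("AFT is linear in VO2 and inverse in MAC", {
  mt <- mac_table()
  vo2 <- c(5, 10, 20)
  act <- c("WALK", "CC", "GUDVL")
  base <- as.numeric(compute_aft(vo2, act, mt, 75))
  expect_equal(as.numeric(compute_aft(2 * vo2, act, mt, 75)), 2 * base)
  mt2 <- mt
  mt2$mac <- 2 * mt$mac
  expect_equal(as.numeric(compute_aft(vo2, act, mt2, 75)), base / 2)
})

test_that("%HRR hits its anchors and the published example", {
  expect_equal(compute_hrr(96, 96, 29), 0)          # resting
  expect_equal(compute_hrr(191, 96, 29), 1)         # 220 - 29
  expect_equal(compute_hrr(143.5, 96, 29), 0.5)
  # not clipped: out-of-range values surface data problems
  expect_lt(compute_hrr(90, 96, 29), 0)
  expect_error(compute_hrr(100, 130, 95), "exceed")
})

test_that("windowed averages follow the tumbling-window definition", {
  x <- rep(3.3, 500)
  for (sch in c("per-second", "1-min", "2-min", "5-min"))
    expect_true(all(windowed_average(x, sch)$value == 3.3))
  act <- rep(c("A", "B"), c(200, 300))
  expect_true(all(windowed_average(x, "per-activity", act)$value == 3.3))

  y <- rnorm(240)
  w <- windowed_average(y, "2-min")
  expect_identical(nrow(w), 2L)
  expect_equal(w$value, c(mean(y[1:120]), mean(y[121:240])))
  expect_false(any(w$partial))

  # trailing partial window keeps its true length and is flagged
  y2 <- rnorm(150)
  w2 <- windowed_average(y2, "2-min")
  expect_identical(w2$n, c(120L, 30L))
  expect_identical(w2$partial, c(FALSE, TRUE))
  expect_equal(w2$value[2], mean(y2[121:150]))
  expect_error(windowed_average(numeric(0), "1-min"), "empty")
})

test_that("per-activity averages equal a group-by-segment oracle", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    nseg <- sample(2:6, 1)
    act <- rep(sample(LETTERS[1:5], nseg, replace = TRUE),
               times = sample(5:40, nseg, replace = TRUE))
    x <- rnorm(length(act))
    w <- windowed_average(x, "per-activity", act)
    # brute-force segment walk
    vals <- numeric(0); labs <- character(0); seg_start <- 1
    for (i in seq_along(act)) {
      if (i == length(act) || act[i + 1] != act[i]) {
        vals <- c(vals, mean(x[seg_start:i]))
        labs <- c(labs, act[i])
        seg_start <- i + 1
      }
    }
    expect_equal(w$value, vals)
    expect_identical(w$activity_id, labs)
  }
})

test_that("windowed averaging commutes with scalar multiplication", {
  set.seed(62)
  x <- rnorm(400)
  act <- rep(c("A", "B", "C", "A"), each = 100)
  for (sch in c("1-min", "2-min", "per-activity")) {
    w1 <- windowed_average(5 * x, sch, act)$value
    w2 <- 5 * windowed_average(x, sch, act)$value
    expect_equal(w1, w2, tolerance = 1e-12)
  }
})

test_that("the 33% exposure flag is a strict exceedance", {
  expect_false(niosh_flag(0.33))
  expect_true(niosh_flag(0.36))    # High-level mean exceeds the limit
  expect_false(niosh_flag(0.2203)) # Low-level mean does not
  expect_identical(niosh_flag(c(0.1, 0.34)), c(FALSE, TRUE))
  expect_error(niosh_flag(NaN), "finite")
})

test_that("long-bout per-activity AFT approaches the analytic target", {
  p <- participant_profile("L", 30, 75, 175, 60)
  cat <- activity_catalog()
  s <- simulate_session(p, activity_schedule(c("WALK", "CDB"), c(1800, 1800)),
                        cat, sim_config(seed = 63, vo2_noise_sd = 0))
  aft <- compute_aft(s$vo2, s$activity, mac_table(), 75)
  w <- windowed_average(unclass(aft), "per-activity", s$activity)
  mt <- mac_table()
  for (i in 1:2) {
    actv <- w$activity_id[i]
    target <- cat$steady_state_vo2[[actv]] * 75 / 1000 /
      mt$mac[[mt$category[[actv]]]]
    expect_lt(abs(w$value[i] - target) / target, 0.02)
  }
})
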