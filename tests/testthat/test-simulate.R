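# Session generator: kinetics, banding, stream structure, determinism.

test_that("VO2 step response follows the first-order closed form", {
  expect_equal(vo2_step_response(5, 20, 35, 0), 5)
  expect_equal(vo2_step_response(5, 20, 35, 1e6), 20, tolerance = 1e-6)
  # one time constant covers 1 - e^-1 of the step
  expect_equal(vo2_step_response(5, 20, 35, 35),
               5 + 15 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(vo2_step_response(5, 20, 35, 35), 2), 14.48)
  # monotone from v0 towards target
  tt <- seq(0, 300, by = 1)
  expect_true(all(diff(vo2_step_response(5, 20, 35, tt)) > 0))
  expect_true(all(diff(vo2_step_response(25, 10, 35, tt)) < 0))
  expect_error(vo2_step_response(5, 20, 0, 1), "tau")
  expect_error(vo2_step_response(5, 20, 35, -1), "non-negative")
})

test_that("AFT banding maps level means and boundaries correctly", {
  expect_equal(rof_label_from_aft(0.2203)$level, 1L)      # Low mean
  expect_equal(rof_label_from_aft(0.2891)$level, 2L)      # Moderate mean
  expect_equal(rof_label_from_aft(0.3600)$level, 3L)      # High mean
  expect_equal(rof_label_from_aft(0.4363)$level, 4L)      # Very High mean
  expect_equal(rof_label_from_aft(0)$level, 0L)
  expect_equal(rof_label_from_aft(0)$rating, 0L)
  # cut points at midpoints of consecutive level means
  mid_lm <- (0.2203 + 0.2891) / 2
  expect_equal(rof_label_from_aft(mid_lm - 1e-9)$level, 1L)
  expect_equal(rof_label_from_aft(mid_lm)$level, 2L)
  expect_equal(rof_label_from_aft(0.11015)$level, 1L)
  expect_equal(rof_label_from_aft(0.11015 - 1e-9)$level, 0L)
  # ratings collapse back to the same level
  for (a in c(0, 0.15, 0.3, 0.36, 0.5)) {
    lab <- rof_label_from_aft(a)
    expect_equal(rof_to_level(lab$rating)$level, lab$level)
  }
  expect_error(rof_label_from_aft(-0.1))
  expect_error(rof_label_from_aft(1.6))
})

test_that("empty schedule yields empty streams, not an error", {
  p <- participant_profile("E", 30, 75, 175, 60)
  s <- simulate_session(p, activity_schedule(character(0), numeric(0)))
  expect_identical(nrow(s$emg), 0L)
  expect_identical(nrow(s$imu), 0L)
  expect_length(s$vo2, 0)
  expect_length(s$hr, 0)
  expect_identical(nrow(s$rof), 0L)
})

test_that("unknown activities are rejected", {
  p <- participant_profile("E", 30, 75, 175, 60)
  expect_error(simulate_session(p, activity_schedule("NOPE", 10)),
               "unknown activity")
})

test_that("a long steady bout converges to the activity's VO2 target", {
  p <- participant_profile("W", 30, 75, 175, 60)
  cat <- activity_catalog()
  s <- simulate_session(p, activity_schedule("WALK", 600), cat,
                        sim_config(seed = 3, vo2_noise_sd = 0))
  target <- unname(cat$steady_state_vo2["WALK"])
  expect_lt(abs(s$vo2[600] - target) / target, 0.01)
})

test_that("stream lengths are rate-consistent after truncation", {
  s <- tiny_session(seed = 5, duration_s = c(10.6, 7.9), rof_interval_s = 5,
                    acts = c("WALK", "CC"))
  T <- length(s$vo2)
  expect_identical(T, 18L)  # floor(18.5)
  expect_identical(nrow(s$emg), 200L * T)
  expect_identical(nrow(s$imu), 50L * T)
  expect_length(s$hr, T)
  expect_length(s$activity, T)
})

test_that("simulation is bit-reproducible for a fixed config", {
  a <- tiny_session(seed = 9)
  b <- tiny_session(seed = 9)
  expect_identical(a, b)
  c <- tiny_session(seed = 10)
  expect_false(identical(a$emg, c$emg))
})

test_that("VO2 trace is continuous across activity transitions", {
  s <- tiny_session(seed = 6, duration_s = c(60, 60, 60), vo2_noise_sd = 0)
  cat <- activity_catalog()
  cfg <- sim_config()
  # per-second kinetics step bound: (1 - e^(-1/tau)) * largest gap
  gap <- diff(range(c(cfg$vo2_rest, cat$steady_state_vo2)))
  bound <- (1 - exp(-1 / cfg$vo2_tau)) * gap
  expect_true(all(abs(diff(s$vo2)) <= bound + 1e-9))
})

test_that("heart rate is clipped to the physiologic range and VO2 >= 0", {
  s <- tiny_session(seed = 7)
  expect_true(all(s$vo2 >= 0))
  expect_true(all(s$hr >= s$profile$resting_hr - 1e-9))
  expect_true(all(s$hr <= s$profile$max_hr + 1e-9))
})

test_that("interval-average AFT stays inside the emitting rating's band", {
  # one long bout per band; the trailing-window mean must land in the band
  # whose rating the generator emitted
  p <- participant_profile("C", 30, 75, 175, 60)
  s <- simulate_session(p,
    activity_schedule(c("HAM", "WALK", "IALJ", "CDB", "GUDVL"),
                      rep(600, 5)),
    activity_catalog(), sim_config(seed = 21, rof_interval_s = 300))
  aft <- compute_aft(s$vo2, s$activity, mac_table(), 75)
  cuts <- c(0, 0.11015, 0.2547, 0.32455, 0.39815, Inf)
  for (i in seq_len(nrow(s$rof))) {
    t <- s$rof$t_s[i]
    m <- mean(aft[max(1, t - 300 + 1):t])
    lev <- rof_to_level(s$rof$rating[i])$level
    expect_gte(m, cuts[lev + 1])
    expect_lt(m, cuts[lev + 2])
  }
})

test_that("cohort simulation perturbs targets but keeps schedules valid", {
  profs <- cohort_profiles(3, seed = 2)
  sessions <- simulate_cohort(profs, sim_config(seed = 4),
                              duration_s = 20)
  expect_length(sessions, 3)
  for (s in sessions) {
    expect_setequal(unique(s$schedule$activity_id), activity_codes())
    expect_length(s$vo2, 14 * 20)
  }
  # distinct subjects see distinct noise
  expect_false(identical(sessions[[1]]$vo2, sessions[[2]]$vo2))
})
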