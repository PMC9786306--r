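# Seeded generator of labeled wearable-physiology sessions.

#' Simulation configuration
#'
#' Collects the generator's tunable constants. Sampling rates default to the
#' wearable suite emulated throughout the package (EMG 200 Hz, IMU 50 Hz,
#' physiology 1 Hz). Oxygen-uptake dynamics follow first-order on-kinetics
#' with time constant \code{vo2_tau}; heart rate is linear in VO2 with AR(1)
#' measurement noise.
#'
#' @param seed Integer master seed.
#' @param emg_rate,imu_rate,physio_rate Sampling rates in Hz.
#' @param vo2_tau VO2 kinetics time constant in seconds (> 0, default 35).
#' @param vo2_rest Resting oxygen uptake in mL/kg/min (default 3.5).
#' @param hr_slope Heart-rate gain in bpm per mL/kg/min of VO2 (default 5).
#' @param vo2_noise_sd Measurement noise sd on VO2, mL/kg/min.
#' @param hr_noise_sd Stationary sd of the AR(1) heart-rate noise, bpm.
#' @param hr_noise_rho AR(1) coefficient of the heart-rate noise.
#' @param emg_noise_sd Additive EMG sensor noise floor, a.u.
#' @param imu_noise_sd Additive IMU sensor noise, per-axis units.
#' @param rof_interval_s Seconds between fatigue-rating samples
#'   (300 for training-style sessions, 60 for evaluation-style ones).
#' @param rof_memory_s Length of the trailing workload window a rating
#'   integrates (default 300 s): perceived fatigue reflects the last few
#'   minutes of work, not only the interval since the previous rating.
#' @param participant_vo2_sd Relative between-participant sd applied to the
#'   steady-state VO2 targets when simulating a cohort.
#' @param participant_emg_sd Relative between-participant sd applied to the
#'   per-channel EMG gains when simulating a cohort.
#' @return Object of class \code{sim_config} (a named list).
#' @export
sim_config <- function(seed = 1L, emg_rate = 200L, imu_rate = 50L,
                       physio_rate = 1L, vo2_tau = 35, vo2_rest = 3.5,
                       hr_slope = 5, vo2_noise_sd = 0.5, hr_noise_sd = 2,
                       hr_noise_rho = 0.9, emg_noise_sd = 0.05,
                       imu_noise_sd = 0.1, rof_interval_s = 300L,
                       rof_memory_s = 300L,
                       participant_vo2_sd = 0.05,
                       participant_emg_sd = 0.1) {
  stopifnot(vo2_tau > 0, emg_rate > 0, imu_rate > 0, physio_rate == 1,
            rof_interval_s > 0, rof_memory_s > 0, vo2_rest >= 0,
            hr_noise_rho >= 0, hr_noise_rho < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' First-order oxygen-uptake step response
#'
#' Closed-form first-order on-kinetics: starting from \code{v0} and stepping
#' towards \code{target}, the response after \code{t} seconds is
#' \code{target + (v0 - target) * exp(-t / tau)}. Used by the session
#' generator to make VO2 activity-dependent with physiologic transients.
#'
#' @param v0 Initial VO2 (mL/kg/min).
#' @param target Steady-state VO2 the activity drives towards (mL/kg/min).
#' @param tau Time constant in seconds (> 0).
#' @param t Elapsed time in seconds (>= 0), vectorized.
#' @return VO2 at time \code{t}, mL/kg/min.
#' @examples
#' vo2_step_response(5, 20, 35, 35)  # one time constant: 5 + 15*(1 - e^-1)
#' @export
vo2_step_response <- function(v0, target, tau, t) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  target + (v0 - target) * exp(-t / tau)
}

# Fatigue-level band cut points on the AFT scale: midpoints of consecutive
# empirical per-level AFT means (Low 22.03%, Moderate 28.91%, High 36.00%,
# Very High 43.63%), with a None band below half the Low mean.
.aft_level_cuts <- c(none = 0.2203 / 2,
                     low = (0.2203 + 0.2891) / 2,
                     moderate = (0.2891 + 0.3600) / 2,
                     high = (0.3600 + 0.4363) / 2)

# Representative (lower-median) rating for each level's 0-10 rating range.
.level_ratings <- c(0L, 1L, 4L, 6L, 9L)

#' Fatigue level names
#' @return Character vector of the five level names, index = level + 1.
#' @export
fatigue_levels <- function() c("None", "Low", "Moderate", "High", "Very High")

#' Map an average AFT to a fatigue rating and level
#'
#' Bands the (typically 5-minute) average aerobic fatigue threshold into the
#' five fatigue levels using cut points at the midpoints of the empirical
#' per-level AFT means (0.11015, 0.2547, 0.32455, 0.39815), then reports the
#' representative 0-10 rating of the level's rating range (0, 1, 4, 6, 9).
#' Used by the generator to derive subjective ratings from workload.
#'
#' @param aft_avg Average AFT as a fraction; values in [0, 1.5] accepted.
#' @return List with integer \code{rating} (0-10), integer \code{level}
#'   (0-4) and \code{level_name}. Vectorized over \code{aft_avg}.
#' @examples
#' rof_label_from_aft(0.2203)  # Low
#' rof_label_from_aft(0.4363)  # Very High
#' @export
rof_label_from_aft <- function(aft_avg) {
  if (any(!is.finite(aft_avg)) || any(aft_avg < 0))
    stop("aft_avg must be finite and non-negative")
  if (any(aft_avg > 1.5)) stop("aft_avg above 1.5 is implausible")
  level <- findInterval(aft_avg, .aft_level_cuts)
  list(rating = .level_ratings[level + 1L], level = level,
       level_name = fatigue_levels()[level + 1L])
}

# Band-limited (20-95 Hz at 200 Hz sampling) unit-variance noise carrier.
.emg_carrier <- function(n, rate) {
  if (n == 0) return(numeric(0))
  ny <- rate / 2
  bf <- signal::butter(4, c(20, min(95, 0.95 * ny)) / ny, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Simulate one labeled wearable session
#'
#' Generates the full multi-rate stream bundle for one participant working
#' through an activity schedule: VO2 follows piecewise first-order kinetics
#' towards each activity's steady-state target (plus measurement noise,
#' floored at 0); heart rate is linear in the noise-free VO2 with AR(1)
#' noise, clipped to [resting, 220 - age]; EMG channels are band-limited
#' zero-mean noise scaled by the activity's per-channel activation; IMU axes
#' combine a gravity offset, an activity-specific sinusoid and noise, with
#' slowly varying orientation channels; fatigue ratings are emitted every
#' \code{rof_interval_s} seconds from the trailing \code{rof_memory_s}
#' average AFT. Streams are
#' truncated to whole seconds. Fully reproducible given \code{config$seed}.
#'
#' @param profile A \code{participant_profile}.
#' @param schedule An \code{activity_schedule}; an empty schedule yields
#'   empty streams.
#' @param catalog An \code{activity_catalog}; every scheduled activity must
#'   exist in it.
#' @param config A \code{sim_config}.
#' @return Object of class \code{session_data}: list with \code{emg}
#'   (200T x 8 matrix), \code{imu} (50T x 9), \code{vo2}, \code{hr},
#'   \code{activity} (length-T vectors at 1 Hz), \code{rof} (data.frame
#'   t_s, rating), \code{profile}, \code{schedule}, \code{config}.
#' @export
simulate_session <- function(profile, schedule,
                             catalog = activity_catalog(),
                             config = sim_config()) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(schedule, "activity_schedule"),
            inherits(catalog, "activity_catalog"),
            inherits(config, "sim_config"))
  unknown <- setdiff(schedule$activity_id, catalog$activities)
  if (length(unknown))
    stop("unknown activity_id: ", paste(unknown, collapse = ", "))

  er <- config$emg_rate; ir <- config$imu_rate
  imu_axes <- c("ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")

  # per-second activity index; distributes fractional durations so that
  # the label vector length equals floor(total seconds)
  sec_counts <- diff(floor(c(0, cumsum(schedule$duration_s))))
  act_sec <- rep(seq_len(nrow(schedule)), times = sec_counts)
  T <- length(act_sec)
  activity <- schedule$activity_id[act_sec]

  if (T == 0) {
    return(structure(list(
      emg = matrix(numeric(0), 0, 8, dimnames = list(NULL, paste0("emg", 1:8))),
      imu = matrix(numeric(0), 0, 9, dimnames = list(NULL, imu_axes)),
      vo2 = numeric(0), hr = numeric(0), activity = character(0),
      rof = data.frame(t_s = numeric(0), rating = integer(0)),
      profile = profile, schedule = schedule, config = config),
      class = "session_data"))
  }

  with_seed(config$seed, {
    # --- oxygen uptake: piecewise first-order kinetics at 1 Hz
    targets <- catalog$steady_state_vo2[activity]
    decay <- exp(-1 / config$vo2_tau)
    vo2_true <- numeric(T)
    v <- config$vo2_rest
    for (t in seq_len(T)) {
      v <- targets[t] + (v - targets[t]) * decay
      vo2_true[t] <- v
    }
    vo2 <- pmax(0, vo2_true + rnorm(T, 0, config$vo2_noise_sd))

    # --- heart rate: linear in VO2 + AR(1) noise, clipped
    innov_sd <- config$hr_noise_sd * sqrt(1 - config$hr_noise_rho^2)
    ar <- as.numeric(stats::filter(rnorm(T, 0, innov_sd),
                                   config$hr_noise_rho, method = "recursive"))
    hr <- profile$resting_hr +
      config$hr_slope * (vo2_true - config$vo2_rest) + ar
    hr <- pmin(pmax(hr, profile$resting_hr), profile$max_hr)

    # --- EMG: band-limited noise scaled per second by activation
    emg <- matrix(0, T * er, 8, dimnames = list(NULL, paste0("emg", 1:8)))
    act_env <- catalog$emg_activation[activity, , drop = FALSE]
    for (ch in 1:8) {
      env <- rep(act_env[, ch], each = er)
      emg[, ch] <- .emg_carrier(T * er, er) * env +
        rnorm(T * er, 0, config$emg_noise_sd)
    }

    # --- IMU: gravity offset + activity sinusoid + noise; orientation
    #     channels are a slow AR(1) drift around an activity-specific level
    imu <- matrix(0, T * ir, 9, dimnames = list(NULL, imu_axes))
    tt <- (seq_len(T * ir) - 1) / ir
    f_env <- rep(catalog$motion_freq[activity], each = ir)
    phase <- cumsum(2 * pi * f_env / ir)  # continuous phase across bouts
    amp_env <- catalog$motion_amp[activity, , drop = FALSE]
    grav <- c(0, 0, 9.81)
    for (ax in 1:6) {
      env <- rep(amp_env[, ax], each = ir)
      base <- if (ax <= 3) grav[ax] else 0
      imu[, ax] <- base + env * sin(phase + ax) +
        rnorm(T * ir, 0, config$imu_noise_sd)
    }
    for (ax in 7:9) {
      drift <- as.numeric(stats::filter(rnorm(T * ir, 0, 0.02), 0.995,
                                        method = "recursive"))
      imu[, ax] <- 0.1 * rep(amp_env[, ax], each = ir) + drift +
        rnorm(T * ir, 0, config$imu_noise_sd / 2)
    }

    # --- fatigue ratings from interval-average AFT
    aft <- compute_aft(vo2, activity, mac = mac_table(),
                       body_mass = profile$body_mass)
    times <- if (T >= config$rof_interval_s)
      seq(config$rof_interval_s, T, by = config$rof_interval_s)
    else numeric(0)
    rating <- vapply(times, function(s) {
      idx <- max(1, s - config$rof_memory_s + 1):s
      rof_label_from_aft(min(1.5, mean(aft[idx])))$rating
    }, integer(1))
    rof <- data.frame(t_s = as.numeric(times), rating = rating)

    structure(list(emg = emg, imu = imu, vo2 = vo2, hr = hr,
                   activity = activity, rof = rof, profile = profile,
                   schedule = schedule, config = config),
              class = "session_data")
  })
}

#' @export
print.session_data <- function(x, ...) {
  T <- length(x$vo2)
  cat(sprintf(
    "Wearable session: %s, %d s (%.1f min), %d activity bouts, %d ratings\n",
    x$profile$participant_id, T, T / 60, nrow(x$schedule), nrow(x$rof)))
  invisible(x)
}

#' Participant-specific perturbation of an activity catalog
#'
#' Emulates between-worker variability: steady-state VO2 targets are
#' jittered multiplicatively per activity (relative sd
#' \code{config$participant_vo2_sd}, fitness differences) and EMG channel
#' gains per channel (\code{config$participant_emg_sd}, electrode
#' placement). Applied to every simulated worker, including held-out
#' evaluation participants, so that no session is generated from the
#' pristine population catalog.
#'
#' @param catalog Base \code{activity_catalog}.
#' @param config A \code{sim_config} providing the two relative sds.
#' @param seed Integer seed for this participant's draw.
#' @return A perturbed \code{activity_catalog}.
#' @export
participant_catalog <- function(catalog, config = sim_config(), seed = 1) {
  with_seed(seed, {
    catalog$steady_state_vo2 <- catalog$steady_state_vo2 *
      pmax(0.5, rnorm(length(catalog$steady_state_vo2), 1,
                      config$participant_vo2_sd))
    gains <- pmax(0.5, rnorm(8, 1, config$participant_emg_sd))
    catalog$emg_activation <- sweep(catalog$emg_activation, 2, gains, `*`)
  })
  catalog
}

#' Simulate a cohort of labeled sessions
#'
#' One session per participant, each with a randomized own-order schedule
#' and participant-specific perturbations of the activity catalog:
#' steady-state VO2 targets are jittered multiplicatively (relative sd
#' \code{config$participant_vo2_sd}) and per-channel EMG gains by
#' \code{config$participant_emg_sd}, emulating fitness and electrode-
#' placement variability between workers.
#'
#' @param profiles List of \code{participant_profile} objects (e.g. from
#'   \code{cohort_profiles}).
#' @param config A \code{sim_config}; its seed drives all randomness.
#' @param catalog Base \code{activity_catalog}.
#' @param duration_s Seconds per activity in each participant's schedule.
#' @return List of \code{session_data}, one per profile.
#' @export
simulate_cohort <- function(profiles, config = sim_config(),
                            catalog = activity_catalog(),
                            duration_s = 300) {
  stopifnot(length(profiles) >= 1)
  lapply(seq_along(profiles), function(i) {
    seed_i <- child_seed(config$seed, i)
    cat_i <- participant_catalog(catalog, config,
                                 child_seed(config$seed, 1000L + i))
    sched <- training_schedule(duration_s = duration_s, randomize = TRUE,
                               seed = child_seed(config$seed, 2000L + i))
    cfg_i <- config
    cfg_i$seed <- seed_i
    simulate_session(profiles[[i]], sched, cat_i, cfg_i)
  })
}
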