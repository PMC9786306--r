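# Activity catalog, MAC table and session schedules for scaffold building.

#' Activity codes of the scaffold-building task set
#'
#' The fourteen scaffold-building activities used throughout the package,
#' in canonical order: walking (WALK), carrying/positioning scaffold frames
#' (CPSF), carrying leveling jacks (CLJ), inserting/adjusting leveling jacks
#' (IALJ), carrying crossbars (CC), installing crossbars (IC), hammering
#' (HAM), wrenching (WRE), carrying/dragging baseboards (CDB), installing
#' baseboards on different levels (IBDL), carrying guardrails (CG), dragging
#' guardrails (DG), installing guardrails (IG), and going up/down a vertical
#' ladder (GUDVL).
#'
#' @return Character vector of the 14 activity codes.
#' @export
activity_codes <- function() {
  c("WALK", "CPSF", "CLJ", "IALJ", "CC", "IC", "HAM",
    "WRE", "CDB", "IBDL", "CG", "DG", "IG", "GUDVL")
}

#' Maximum aerobic capacity (MAC) table
#'
#' Activity-specific maximum aerobic capacity constants (L/min) for four
#' construction activity categories, together with the mapping from each of
#' the 14 scaffold activity codes to its category. The MAC value is the
#' denominator of the aerobic fatigue threshold: AFT = absolute VO2 (L/min)
#' divided by the MAC of the activity being performed. Hammering, wrenching
#' and dragging share the Combined category.
#'
#' @return Object of class \code{mac_table}: a list with \code{mac}
#'   (named numeric, L/min per category) and \code{category} (named
#'   character, activity code to category).
#' @examples
#' mt <- mac_table()
#' mt$mac[["Walking"]]
#' mt$category[["HAM"]]
#' @export
mac_table <- function() {
  mac <- c(Walking = 2.946, Carrying = 2.552, Lifting = 2.816,
           Combined = 2.304)
  category <- c(
    WALK = "Walking",
    CPSF = "Carrying", CLJ = "Carrying", CC = "Carrying",
    CDB = "Carrying", CG = "Carrying",
    IBDL = "Lifting",
    IALJ = "Combined", IC = "Combined", HAM = "Combined",
    WRE = "Combined", DG = "Combined", IG = "Combined",
    GUDVL = "Combined")
  structure(list(mac = mac, category = category[activity_codes()]),
            class = "mac_table")
}

#' @export
print.mac_table <- function(x, ...) {
  cat("Activity-specific maximum aerobic capacity (L/min)\n")
  for (cat_ in names(x$mac)) {
    acts <- names(x$category)[x$category == cat_]
    cat(sprintf("  %-9s %5.3f  [%s]\n", cat_, x$mac[[cat_]],
                paste(acts, collapse = ", ")))
  }
  invisible(x)
}

# Nominal steady-state AFT per activity used to calibrate the generator.
# Chosen so that per-activity AFT means span the empirical fatigue-level
# bands (GUDVL highest, HAM lowest; CPSF/CDB/IBDL/GUDVL above the 33%
# occupational exposure limit). These are generator calibration constants,
# not physiological claims.
.nominal_aft <- c(
  WALK = 0.22, CPSF = 0.36, CLJ = 0.27, IALJ = 0.29, CC = 0.25,
  IC = 0.30, HAM = 0.18, WRE = 0.21, CDB = 0.38, IBDL = 0.35,
  CG = 0.24, DG = 0.28, IG = 0.31, GUDVL = 0.46)

# Reference body mass (kg) used to express calibrated VO2 targets per kg.
.reference_mass <- 75

#' Activity catalog for the session generator
#'
#' Per-activity generator settings: the MAC category, the steady-state
#' oxygen-uptake target (mL/kg/min) each activity drives VO2 towards, the
#' per-channel EMG activation pattern in [0, 1], and the IMU motion profile
#' (dominant movement frequency in Hz plus per-axis amplitude). VO2 targets
#' are calibrated so that, for a reference 75-kg worker, per-activity AFT
#' means span the five fatigue-level bands with the ladder climb (GUDVL)
#' highest and hammering (HAM) lowest. EMG activation and IMU amplitude
#' patterns are distinct per activity and scale with activity intensity, so
#' that the streams carry both activity identity and workload information.
#'
#' @param intensity_scale Multiplier applied to all steady-state VO2
#'   targets (default 1). Values must be positive.
#' @return Object of class \code{activity_catalog}: a list with
#'   \code{activities} (character), \code{category}, \code{steady_state_vo2}
#'   (named numeric, mL/kg/min), \code{emg_activation} (14 x 8 matrix),
#'   \code{motion_freq} (named numeric, Hz) and \code{motion_amp}
#'   (14 x 9 matrix).
#' @export
activity_catalog <- function(intensity_scale = 1) {
  stopifnot(is.numeric(intensity_scale), intensity_scale > 0)
  acts <- activity_codes()
  mt <- mac_table()
  n <- length(acts)
  aft <- .nominal_aft[acts]
  vo2 <- aft * mt$mac[mt$category[acts]] * 1000 / .reference_mass *
    intensity_scale
  names(vo2) <- acts
  rel <- aft / max(aft)  # intensity in (0, 1]

  # Distinct per-activity channel patterns from a discrete harmonic basis:
  # rows are near-orthogonal, so activities are separable, while the overall
  # level scales with intensity, so amplitude carries workload information.
  emg <- matrix(0, n, 8, dimnames = list(acts, paste0("emg", 1:8)))
  for (i in seq_len(n)) {
    w <- 0.5 + 0.5 * cos(2 * pi * (i - 1) * (seq_len(8) + 1) / n)
    emg[i, ] <- pmin(1, 0.12 + 0.8 * rel[i] * w)
  }

  imu_axes <- c("ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")
  amp <- matrix(0, n, 9, dimnames = list(acts, imu_axes))
  for (i in seq_len(n)) {
    w <- 0.5 + 0.5 * sin(2 * pi * (i - 1) * (seq_len(9) + 2) / n)
    amp[i, ] <- (0.3 + 2.7 * rel[i]) * (0.25 + 0.75 * w)
  }
  # Dominant movement frequency: spread over 0.6-3.4 Hz in an order
  # decorrelated from intensity.
  freq <- 0.6 + 2.8 * ((seq_len(n) * 5) %% n) / (n - 1)
  names(freq) <- acts

  structure(list(activities = acts, category = mt$category[acts],
                 steady_state_vo2 = vo2, emg_activation = emg,
                 motion_freq = freq, motion_amp = amp),
            class = "activity_catalog")
}

#' @export
print.activity_catalog <- function(x, ...) {
  cat(sprintf("Activity catalog: %d activities\n", length(x$activities)))
  df <- data.frame(activity = x$activities,
                   category = unname(x$category),
                   vo2_target = round(unname(x$steady_state_vo2), 2),
                   motion_freq = round(unname(x$motion_freq), 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Participant profile
#'
#' Anthropometrics and resting heart rate for one participant. Maximum
#' heart rate is estimated as 220 - age and must exceed the resting rate.
#'
#' @param participant_id Character id.
#' @param age Age in years (positive integer-ish).
#' @param body_mass Body mass in kg (> 0).
#' @param height Height in cm (> 0).
#' @param resting_hr Resting heart rate in bpm (> 0, below 220 - age).
#' @return Object of class \code{participant_profile} with an added
#'   \code{max_hr} field.
#' @examples
#' participant_profile("P01", age = 29, body_mass = 75, height = 168,
#'                     resting_hr = 96)
#' @export
participant_profile <- function(participant_id, age, body_mass, height,
                                resting_hr) {
  stopifnot(is.character(participant_id), length(participant_id) == 1,
            age > 0, body_mass > 0, height > 0, resting_hr > 0)
  max_hr <- 220 - age
  if (max_hr <= resting_hr)
    stop("estimated maximum heart rate (220 - age) must exceed resting_hr")
  structure(list(participant_id = participant_id, age = age,
                 body_mass = body_mass, height = height,
                 resting_hr = resting_hr, max_hr = max_hr),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "Participant %s: %g y, %g kg, %g cm, resting HR %g bpm (max %g)\n",
    x$participant_id, x$age, x$body_mass, x$height, x$resting_hr, x$max_hr))
  invisible(x)
}

#' Generate a cohort of participant profiles
#'
#' Draws \code{n} profiles around the study cohort descriptors
#' (age 27 +/- 1.7 y, mass 76.7 +/- 8.25 kg, height 171.7 +/- 4.13 cm),
#' with resting heart rate around 70 +/- 8 bpm.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return List of \code{participant_profile} objects.
#' @export
cohort_profiles <- function(n = 10, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      participant_profile(
        participant_id = sprintf("P%02d", i),
        age = round(rnorm(1, 27, 1.7)),
        body_mass = round(rnorm(1, 76.7, 8.25), 1),
        height = round(rnorm(1, 171.7, 4.13), 1),
        resting_hr = round(rnorm(1, 70, 8)))
    })
  })
}

#' Activity schedule
#'
#' An ordered list of (activity, duration) entries describing one session.
#'
#' @param activity_id Character vector of activity codes.
#' @param duration_s Positive durations in seconds, same length.
#' @return Object of class \code{activity_schedule}: a data.frame with
#'   columns \code{activity_id} and \code{duration_s}.
#' @export
activity_schedule <- function(activity_id, duration_s) {
  stopifnot(length(activity_id) == length(duration_s))
  if (length(duration_s) && any(duration_s <= 0))
    stop("durations must be positive")
  structure(data.frame(activity_id = as.character(activity_id),
                       duration_s = as.numeric(duration_s),
                       stringsAsFactors = FALSE),
            class = c("activity_schedule", "data.frame"))
}

#' Total duration of a schedule in seconds
#' @param schedule An \code{activity_schedule}.
#' @return Numeric total of the entry durations.
#' @export
schedule_duration <- function(schedule) sum(schedule$duration_s)

#' Training-style schedule: every activity for a fixed duration
#'
#' Mirrors the data-collection protocol in which each participant performs
#' all fourteen activities for five minutes each, in randomized order.
#'
#' @param duration_s Seconds per activity (default 300).
#' @param randomize Shuffle activity order (default TRUE).
#' @param seed Integer seed used when randomizing.
#' @return An \code{activity_schedule}.
#' @export
training_schedule <- function(duration_s = 300, randomize = TRUE, seed = 1) {
  acts <- activity_codes()
  if (randomize) acts <- with_seed(seed, sample(acts))
  activity_schedule(acts, rep(duration_s, length(acts)))
}

#' Evaluation-session schedule
#'
#' The fixed ~85-minute single-worker evaluation session bundled with the
#' package: fifteen activity bouts covering all fourteen activities, with
#' leveling-jack, baseboard, and guardrail installation performed for about
#' ten minutes (they bundle two sub-tasks) and the ladder climb cut short at
#' 1.40 min by exhaustion. Durations sum to 84.82 min; the simulator
#' truncates streams to whole seconds.
#'
#' @return An \code{activity_schedule} with 15 entries.
#' @export
evaluation_schedule <- function() {
  mins <- c(3.27, 4.98, 4.95, 10.03, 5.00, 5.02, 5.02, 5.00, 4.97, 5.02,
            10.10, 5.02, 5.02, 10.02, 1.40)
  acts <- c("WALK", "CG", "CLJ", "IALJ", "CPSF", "HAM", "WRE", "CC",
            "CPSF", "IC", "CDB", "IBDL", "DG", "IG", "GUDVL")
  activity_schedule(acts, mins * 60)
}
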