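# Stream CSV persistence and multi-rate synchronization.

.emg_csv_names <- c("t_s", paste0("ch", 1:8))
.imu_csv_names <- c("t_s", "ax", "ay", "az", "gx", "gy", "gz",
                    "ox", "oy", "oz")
.physio_csv_names <- c("t_s", "vo2_mlkgmin", "hr_bpm", "activity_id")
.rof_csv_names <- c("t_s", "rating")

#' Write a session to per-stream CSV files
#'
#' Writes \code{emg.csv} (t_s + ch1..ch8), \code{imu.csv} (t_s + 9 axes),
#' \code{physio.csv} (t_s, vo2_mlkgmin, hr_bpm, activity_id),
#' \code{rof.csv} (t_s, rating) and a \code{manifest.json} recording the
#' participant profile, schedule and simulation seed. Timestamps are
#' seconds as floats; numeric values keep full double precision.
#'
#' @param session A \code{session_data}.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  er <- session$config$emg_rate; ir <- session$config$imu_rate
  ne <- nrow(session$emg); ni <- nrow(session$imu)

  emg <- data.frame(t_s = (seq_len(ne) - 1) / er, session$emg)
  names(emg) <- .emg_csv_names
  imu <- data.frame(t_s = (seq_len(ni) - 1) / ir, session$imu)
  names(imu) <- .imu_csv_names
  physio <- data.frame(t_s = as.numeric(seq_along(session$vo2) - 1),
                       vo2_mlkgmin = session$vo2, hr_bpm = session$hr,
                       activity_id = session$activity)
  paths <- c(emg = file.path(dir, "emg.csv"),
             imu = file.path(dir, "imu.csv"),
             physio = file.path(dir, "physio.csv"),
             rof = file.path(dir, "rof.csv"),
             manifest = file.path(dir, "manifest.json"))
  data.table::fwrite(emg, paths[["emg"]])
  data.table::fwrite(imu, paths[["imu"]])
  data.table::fwrite(physio, paths[["physio"]])
  data.table::fwrite(stats::setNames(session$rof, .rof_csv_names),
                     paths[["rof"]])
  manifest <- list(
    profile = unclass(session$profile),
    schedule = list(activity_id = session$schedule$activity_id,
                    duration_s = session$schedule$duration_s),
    config = unclass(session$config))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

.read_stream <- function(path, expected) {
  if (!file.exists(path)) stop("missing stream file: ", path)
  x <- data.table::fread(path, data.table = FALSE)
  if (!identical(names(x), expected))
    stop(sprintf("schema mismatch in %s: expected [%s], found [%s]",
                 basename(path), paste(expected, collapse = ","),
                 paste(names(x), collapse = ",")))
  x
}

#' Read a session from per-stream CSV files
#'
#' Inverse of \code{\link{write_session}}: validates each stream's header
#' against the documented schema and reconstructs a \code{session_data}.
#' Round-tripping preserves values to at least 9 significant digits (full
#' double precision with the default writers).
#'
#' @param dir Directory containing the stream CSVs and manifest.
#' @return A \code{session_data}.
#' @export
read_session <- function(dir) {
  emg <- .read_stream(file.path(dir, "emg.csv"), .emg_csv_names)
  imu <- .read_stream(file.path(dir, "imu.csv"), .imu_csv_names)
  physio <- .read_stream(file.path(dir, "physio.csv"), .physio_csv_names)
  rof <- .read_stream(file.path(dir, "rof.csv"), .rof_csv_names)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  profile <- do.call(participant_profile,
                     man$profile[c("participant_id", "age", "body_mass",
                                   "height", "resting_hr")])
  schedule <- activity_schedule(man$schedule$activity_id,
                                man$schedule$duration_s)
  config <- do.call(sim_config, man$config)
  emg_m <- as.matrix(emg[, -1, drop = FALSE])
  colnames(emg_m) <- paste0("emg", 1:8)
  imu_m <- as.matrix(imu[, -1, drop = FALSE])
  structure(list(emg = emg_m, imu = imu_m,
                 vo2 = physio$vo2_mlkgmin, hr = physio$hr_bpm,
                 activity = as.character(physio$activity_id),
                 rof = data.frame(t_s = as.numeric(rof$t_s),
                                  rating = as.integer(rof$rating)),
                 profile = profile, schedule = schedule, config = config),
            class = "session_data")
}

# floor-of-timestamp bucketing used for irregular-timestamp alignment
second_bucket <- function(t) as.integer(floor(t))

#' Synchronize multi-rate streams into per-second windows
#'
#' Aligns the 200 Hz EMG block, 50 Hz IMU block and 1 Hz physiology of a
#' session into per-second windows: window \code{t} covers the half-open
#' interval [t, t+1) seconds (0-based). Windows with incomplete high-rate
#' blocks are dropped, so the window count equals the floor of the shortest
#' stream duration. Each window carries the most recent fatigue rating at
#' or before its start, or NA before the first rating.
#'
#' @param session A \code{session_data}.
#' @return Object of class \code{synced_session}: a list of windows, each
#'   with \code{t_s}, \code{emg_block} (200 x 8), \code{imu_block}
#'   (50 x 9), \code{vo2}, \code{hr}, \code{activity_id},
#'   \code{rof_rating}.
#' @export
synchronize <- function(session) {
  stopifnot(inherits(session, "session_data"))
  er <- session$config$emg_rate; ir <- session$config$imu_rate
  T <- min(floor(nrow(session$emg) / er), floor(nrow(session$imu) / ir),
           length(session$vo2), length(session$hr),
           length(session$activity))
  rof <- session$rof
  windows <- vector("list", T)
  for (t in seq_len(T)) {
    prior <- rof$rating[rof$t_s <= (t - 1)]
    windows[[t]] <- list(
      t_s = t - 1L,
      emg_block = session$emg[((t - 1) * er + 1):(t * er), , drop = FALSE],
      imu_block = session$imu[((t - 1) * ir + 1):(t * ir), , drop = FALSE],
      vo2 = session$vo2[t], hr = session$hr[t],
      activity_id = session$activity[t],
      rof_rating = if (length(prior)) prior[length(prior)] else NA_integer_)
  }
  structure(windows, class = "synced_session")
}

#' @export
print.synced_session <- function(x, ...) {
  cat(sprintf("Synchronized session: %d one-second windows\n", length(x)))
  invisible(x)
}

#' Bucket irregular sample timestamps into whole seconds
#'
#' Assigns every sample to the half-open second [t, t+1) containing its
#' timestamp and keeps the maximal run of consecutive seconds from 0 in
#' which the stream delivers its full nominal block, dropping incomplete
#' seconds. Used when aligning streams whose timestamps are not exactly
#' periodic.
#'
#' @param t Numeric sample timestamps in seconds (must be non-decreasing).
#' @param rate Nominal samples per second.
#' @return List with \code{second} (per-sample bucket index) and
#'   \code{complete} (integer vector of seconds, starting at 0, forming
#'   the maximal complete prefix).
#' @export
bucket_samples <- function(t, rate) {
  if (is.unsorted(t)) stop("timestamps must be non-decreasing")
  sec <- second_bucket(t)
  if (length(sec) && any(sec < 0)) stop("timestamps must be non-negative")
  counts <- if (length(sec)) tabulate(sec + 1L) else integer(0)
  n_prefix <- 0L
  while (n_prefix < length(counts) && counts[n_prefix + 1L] == rate)
    n_prefix <- n_prefix + 1L
  list(second = sec,
       complete = if (n_prefix > 0) 0:(n_prefix - 1L) else integer(0))
}
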