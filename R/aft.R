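# Aerobic fatigue threshold, percent heart-rate reserve, windowed averages.

#' Aerobic fatigue threshold from a VO2 stream
#'
#' AFT_t = absolute VO2 (L/min) / MAC of the activity performed at t.
#' VO2 streams are measured per unit body mass (mL/kg/min) while MAC values
#' are absolute (L/min), so the numerator is converted through body mass:
#' AFT_t = (vo2_t * body_mass / 1000) / MAC(category(activity_t)).
#'
#' @param vo2 Numeric VO2 series at 1 Hz, mL/kg/min.
#' @param activity Character activity-code series, same length.
#' @param mac A \code{mac_table}.
#' @param body_mass Body mass in kg (> 0).
#' @param provenance "actual" or "predicted" (metadata flag).
#' @param participant_id Optional id carried as metadata.
#' @return Numeric AFT series (dimensionless fraction) of class
#'   \code{aft_series} with attributes \code{provenance} and
#'   \code{participant_id}.
#' @examples
#' mt <- mac_table()
#' compute_aft(11.2, "WALK", mt, body_mass = 75)  # 0.84/2.946 = 0.2851
#' @export
compute_aft <- function(vo2, activity, mac = mac_table(), body_mass,
                        provenance = c("actual", "predicted"),
                        participant_id = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(vo2) == length(activity), body_mass > 0)
  unmapped <- setdiff(unique(activity), names(mac$category))
  if (length(unmapped))
    stop("unmapped activity code: ", paste(unmapped, collapse = ", "))
  denom <- mac$mac[mac$category[activity]]
  aft <- (vo2 * body_mass / 1000) / unname(denom)
  structure(aft, class = "aft_series", provenance = provenance,
            participant_id = participant_id)
}

#' @export
print.aft_series <- function(x, ...) {
  cat(sprintf("AFT series (%s): %d s, mean %.4f, max %.4f\n",
              attr(x, "provenance"), length(x),
              mean(unclass(x)), max(unclass(x))))
  invisible(x)
}

#' @export
plot.aft_series <- function(x, ...) {
  plot(seq_along(x), unclass(x), type = "l", xlab = "time (s)",
       ylab = "AFT", ...)
  abline(h = 0.33, lty = 2)
  invisible(x)
}

#' Percent heart-rate reserve
#'
#' \%HRR_t = (HR_t - resting) / (max - resting) with maximum heart rate
#' estimated as 220 - age. Values are not clipped: out-of-range results
#' flag data problems rather than being hidden.
#'
#' @param hr Working heart-rate series, bpm.
#' @param resting_hr Resting heart rate, bpm.
#' @param age Age in years; 220 - age must exceed \code{resting_hr}.
#' @return Numeric \%HRR series as fractions.
#' @examples
#' compute_hrr(143.5, resting_hr = 96, age = 29)  # 0.5
#' @export
compute_hrr <- function(hr, resting_hr, age) {
  denom <- (220 - age) - resting_hr
  if (denom <= 0) stop("220 - age must exceed resting_hr")
  (hr - resting_hr) / denom
}

#' Windowed averages of a per-second series
#'
#' Non-overlapping tumbling windows anchored at t = 0 for the fixed-width
#' schemes; the per-activity scheme averages over contiguous same-activity
#' segments. A trailing partial window is emitted with its actual length
#' and flagged \code{partial}.
#'
#' @param x Numeric per-second series (non-empty).
#' @param scheme One of "per-second", "1-min", "2-min", "5-min",
#'   "per-activity".
#' @param activity Activity-code series (required for "per-activity").
#' @return data.frame with columns \code{window}, \code{start_s},
#'   \code{end_s} (half-open, 0-based seconds), \code{n}, \code{value},
#'   \code{partial}, and \code{activity_id} for the per-activity scheme.
#' @export
windowed_average <- function(x, scheme = c("per-second", "1-min", "2-min",
                                           "5-min", "per-activity"),
                             activity = NULL) {
  scheme <- match.arg(scheme)
  n <- length(x)
  if (n == 0) stop("empty series")
  if (scheme == "per-activity") {
    if (is.null(activity) || length(activity) != n)
      stop("per-activity scheme needs an activity series of matching length")
    r <- rle(as.character(activity))
    end <- cumsum(r$lengths)
    start <- c(0, end[-length(end)])
    data.frame(window = seq_along(r$lengths), start_s = start, end_s = end,
               n = r$lengths,
               value = vapply(seq_along(r$lengths), function(i)
                 mean(x[(start[i] + 1):end[i]]), numeric(1)),
               partial = FALSE, activity_id = r$values,
               stringsAsFactors = FALSE)
  } else {
    w <- switch(scheme, "per-second" = 1L, "1-min" = 60L,
                "2-min" = 120L, "5-min" = 300L)
    if (n < w && n < 1) stop("series shorter than one window")
    start <- seq(0L, n - 1L, by = w)
    end <- pmin(start + w, n)
    data.frame(window = seq_along(start), start_s = start, end_s = end,
               n = end - start,
               value = vapply(seq_along(start), function(i)
                 mean(x[(start[i] + 1):end[i]]), numeric(1)),
               partial = (end - start) < w)
  }
}

#' Occupational oxygen-uptake exposure flag
#'
#' TRUE iff the average AFT strictly exceeds the 33\% occupational
#' exposure limit for average oxygen uptake over a workday.
#'
#' @param aft_avg Average AFT fraction(s); must be finite.
#' @return Logical vector.
#' @examples
#' niosh_flag(c(0.33, 0.36))  # FALSE TRUE
#' @export
niosh_flag <- function(aft_avg) {
  if (any(!is.finite(aft_avg))) stop("aft_avg must be finite")
  aft_avg > 0.33
}
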