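#' Split a flight recording into between-coin segments
#'
#' Segment boundaries are the interpolated times at which the flight
#' trajectory crosses each coin's vertical plane (the plane through the
#' coin center perpendicular to the ideal-path tangent at that coin).
#' A course with n coins yields n - 1 segments.
#'
#' @param trial A flight [trial_recording()] with position data.
#' @param course The [coin_course()] flown.
#' @param ideal Optional precomputed [catmull_rom_path()].
#' @return A list of `flight_segment` objects with elements `head`,
#'   `torso` (sliced [angle_series()]), `duration` (s), `coin_from`,
#'   `coin_to`, `error` (crossing error at the terminal coin, m),
#'   `missed`, `valid` and `reason`.
#' @export
split_segments <- function(trial, course, ideal = NULL) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.null(trial$position))
    stop("split_segments needs a flight trial with position data",
         call. = FALSE)
  ideal <- ideal %||% catmull_rom_path(course)
  t <- trial$head$t
  cr <- plane_crossings(trial$position, t, course, ideal)
  if (cr$missed[1])
    stop("data error: trajectory never reaches the first coin plane",
         call. = FALSE)
  n <- nrow(cr)
  segs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    t0 <- cr$time[i]; t1 <- cr$time[i + 1L]
    hd <- slice_series(trial$head, t0, t1)
    tr <- slice_series(trial$torso, t0, t1)
    valid <- TRUE; reason <- NA_character_
    if (t1 - t0 <= 0 || is.null(hd) || is.null(tr)) {
      valid <- FALSE; reason <- "degenerate"
    }
    segs[[i]] <- structure(
      list(head = hd, torso = tr, duration = t1 - t0,
           coin_from = i, coin_to = i + 1L,
           error = cr$error[i + 1L], missed = cr$missed[i + 1L],
           valid = valid, reason = reason),
      class = "flight_segment")
  }
  segs
}

#' Flag segments containing sample-to-sample discontinuities
#'
#' A segment is invalidated when any consecutive-sample absolute angular
#' change on any axis of either the head or the torso trace exceeds the
#' threshold (strictly; a jump of exactly the threshold is kept). Such
#' jumps arise from interference with the inertial sensors.
#'
#' @param segment A `flight_segment` from [split_segments()].
#' @param threshold Rejection threshold in degrees (default 20).
#' @return The segment with `valid`/`reason` updated.
#' @export
reject_discontinuities <- function(segment, threshold = 20) {
  if (!isTRUE(segment$valid)) return(segment)
  jump <- function(s) max(abs(diff(s$pitch)), abs(diff(s$roll)),
                          abs(diff(s$yaw)))
  if (max(jump(segment$head), jump(segment$torso)) > threshold) {
    segment$valid <- FALSE
    segment$reason <- "discontinuity"
  }
  segment
}
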