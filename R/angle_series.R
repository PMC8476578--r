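#' Uniformly sampled Euler-angle series for one body segment
#'
#' An `angle_series` holds a pitch/roll/yaw trace (intrinsic Tait-Bryan
#' angles, degrees, zeroed at the self-selected neutral pose) on a strictly
#' increasing, uniform time grid. Sign convention: positive pitch =
#' flexion (down-steer), positive roll = right lateral flexion, positive
#' yaw = right axial rotation.
#'
#' @param t Time stamps in seconds; strictly increasing, uniform step
#'   (constant within 1e-9). The nominal acquisition step is 0.068 s.
#' @param pitch,roll,yaw Angle traces in degrees, same length as `t`.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(t, pitch, roll, yaw) {
  t <- as.numeric(t); pitch <- as.numeric(pitch)
  roll <- as.numeric(roll); yaw <- as.numeric(yaw)
  n <- length(t)
  if (n < 2L)
    stop("angle_series needs at least 2 samples", call. = FALSE)
  if (length(pitch) != n || length(roll) != n || length(yaw) != n)
    stop("t, pitch, roll, yaw must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(pitch) || anyNA(roll) || anyNA(yaw))
    stop("angle_series does not accept missing values", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9)
    stop("time grid is not uniform (step varies by more than 1e-9 s)",
         call. = FALSE)
  structure(list(t = t, pitch = pitch, roll = roll, yaw = yaw),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples, step %.4g s, duration %.3f s\n",
              n_samples(x), sample_step(x), duration(x)))
  invisible(x)
}

#' Number of samples of an angle series
#' @param x An `angle_series`.
#' @export
n_samples <- function(x) length(x$t)

#' Sample step (seconds) of an angle series
#' @param x An `angle_series`.
#' @export
sample_step <- function(x) (x$t[length(x$t)] - x$t[1]) / (length(x$t) - 1)

#' Duration (seconds) of an angle series
#' @param x An `angle_series`.
#' @export
duration <- function(x) x$t[length(x$t)] - x$t[1]

## Slice an angle_series to samples with t in [t0, t1] (closed window).
slice_series <- function(x, t0, t1) {
  idx <- which(x$t >= t0 - 1e-12 & x$t <= t1 + 1e-12)
  if (length(idx) < 2L) return(NULL)
  angle_series(x$t[idx], x$pitch[idx], x$roll[idx], x$yaw[idx])
}

## One trace of an angle_series by axis name, or the combined lateral
## axis used by the steering mapping (mean of roll and yaw).
axis_trace <- function(x, axis = c("pitch", "roll", "yaw", "lateral")) {
  axis <- match.arg(axis)
  if (axis == "lateral") (x$roll + x$yaw) / 2 else x[[axis]]
}

#' Paired head/torso recording of one trial
#'
#' Bundles the head and torso [angle_series()] of one trial on a shared
#' time grid, the 3D flight trajectory (flight trials only) and the trial
#' metadata.
#'
#' @param head,torso [angle_series()] objects sharing one time grid.
#' @param position Optional n x 3 matrix of flight positions in meters on
#'   the same grid; present if and only if `meta$study == "flight"`.
#' @param meta Named list; recognised fields: `participant_id`,
#'   `age_group` (one of `"6"`, `"8-9"`, `"10"`, `"adult"`), `control`
#'   (`"head"` or `"torso"`), `phase` (`"Before"`, `"Training"`,
#'   `"After"`, `"DayAfter"`), `study` (`"flight"` or `"jar"`), and
#'   free-form extras such as `course_id`.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(head, torso, position = NULL, meta = list()) {
  stopifnot(inherits(head, "angle_series"), inherits(torso, "angle_series"))
  if (n_samples(head) != n_samples(torso) ||
      max(abs(head$t - torso$t)) > 1e-9)
    stop("head and torso must share one time grid", call. = FALSE)
  meta$study <- meta$study %||% if (is.null(position)) "jar" else "flight"
  if (!meta$study %in% c("flight", "jar"))
    stop("meta$study must be 'flight' or 'jar'", call. = FALSE)
  if (meta$study == "flight") {
    if (is.null(position))
      stop("flight trials require a position trajectory", call. = FALSE)
    position <- as.matrix(position)
    if (nrow(position) != n_samples(head) || ncol(position) != 3L)
      stop("position must be an n x 3 matrix on the trial time grid",
           call. = FALSE)
    colnames(position) <- c("x", "y", "z")
  } else if (!is.null(position)) {
    stop("jar trials must not carry a position trajectory", call. = FALSE)
  }
  if (!is.null(meta$control) && !meta$control %in% CONTROLS)
    stop("unknown control: ", meta$control, call. = FALSE)
  if (!is.null(meta$phase) && !meta$phase %in% PHASES)
    stop("unknown phase: ", meta$phase, call. = FALSE)
  structure(list(head = head, torso = torso, position = position,
                 meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<trial_recording> %s, %d samples (%.1f s)\n",
              m$study %||% "?", n_samples(x$head), duration(x$head)))
  cat(sprintf("  participant: %s | age: %s | control: %s | phase: %s\n",
              m$participant_id %||% "?", m$age_group %||% "?",
              m$control %||% "?", m$phase %||% "?"))
  invisible(x)
}
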