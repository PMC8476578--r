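#' One joint-angle-reproduction (JAR) trial
#'
#' @param target_angle Target orientation in degrees: -15, 0 or +15.
#' @param body_part Tested body part, `"head"` or `"torso"`.
#' @param condition `"Feedback"`, `"NoFeedback"` or `"Forward"`.
#' @param head,torso [angle_series()] of the trial (nominally 4 s; at
#'   least 1.5 s so the final-window metrics are computable).
#' @param meta Optional metadata list (`participant_id`, `age_group`).
#' @return An object of class `jar_trial`.
#' @export
jar_trial <- function(target_angle, body_part, condition, head, torso,
                      meta = list()) {
  if (!target_angle %in% JAR_TARGETS)
    stop("target_angle must be one of ",
         paste(JAR_TARGETS, collapse = ", "), call. = FALSE)
  body_part <- match.arg(body_part, CONTROLS)
  if (!condition %in% JAR_CONDITIONS)
    stop("unknown condition: ", condition, call. = FALSE)
  stopifnot(inherits(head, "angle_series"), inherits(torso, "angle_series"))
  if (max(abs(head$t - torso$t)) > 1e-9)
    stop("head and torso must share one time grid", call. = FALSE)
  if (duration(head) < 1.5)
    stop("trial too short: final-window metrics need >= 1.5 s",
         call. = FALSE)
  structure(list(target_angle = target_angle, body_part = body_part,
                 condition = condition, head = head, torso = torso,
                 meta = meta),
            class = "jar_trial")
}

#' @export
print.jar_trial <- function(x, ...) {
  cat(sprintf("<jar_trial> %s, target %+g deg, %s, %.1f s\n",
              x$body_part, x$target_angle, x$condition,
              duration(x$head)))
  invisible(x)
}

## Trace of the tested (or stated) body part on the task-relevant axis.
## The default axis is the lateral combination used by the steering
## mapping (mean of roll and yaw); "pitch" selects the sagittal axis.
jar_trace <- function(trial, part = trial$body_part, axis = "lateral") {
  axis_trace(trial[[part]], axis)
}

## Mean over the final `window` seconds of a trace on grid t.
final_window_mean <- function(t, x, window = 1.5) {
  idx <- which(t >= t[length(t)] - window - 1e-9)
  mean(x[idx])
}

#' Final orientation of a JAR trial
#'
#' Mean of the tested body part's task-relevant axis over the final
#' 1.5 s of the trial (samples whose time stamp falls inside the
#' closing window).
#'
#' @param trial A [jar_trial()].
#' @param axis Task-relevant axis: `"lateral"` (the steering
#'   combination of roll and yaw, default) or `"pitch"`.
#' @param window Averaging window in seconds (default 1.5).
#' @return Final orientation in degrees.
#' @export
final_orientation <- function(trial, axis = "lateral", window = 1.5) {
  if (duration(trial$head) < window)
    stop("trial shorter than the final window", call. = FALSE)
  final_window_mean(trial$head$t, jar_trace(trial, axis = axis), window)
}

#' Per-trial JAR metrics
#'
#' Computes the final orientation, the signed error with respect to the
#' target (positive = final position exceeding the target), the
#' overshoot (maximal excursion beyond the target in the target's
#' direction; 0 if the target is never exceeded), and the number of
#' oscillations around the final angle (sign changes of
#' angle - final after first entry into a +/- 1 degree band around the
#' final angle). For torso trials the head-related decoupling measures
#' are added: the head anchoring index over the whole trial, the final
#' head-torso angular difference (negative = head angle smaller than
#' torso angle) and the head alignment error (final head angle minus
#' target).
#'
#' @param trial A [jar_trial()].
#' @param axis Task-relevant axis (see [final_orientation()]).
#' @param band Settling band for the oscillation count, degrees.
#' @return List of class `jar_metrics`.
#' @export
jar_metrics <- function(trial, axis = "lateral", band = 1) {
  t <- trial$head$t
  x <- jar_trace(trial, axis = axis)
  fin <- final_window_mean(t, x, 1.5)
  target <- trial$target_angle
  dir <- if (target != 0) sign(target) else sign(fin)
  over <- if (dir == 0) 0 else max(0, max(dir * (x - target)))
  inband <- which(abs(x - fin) <= band)
  osc <- 0L
  if (length(inband)) {
    s <- sign(x[inband[1]:length(x)] - fin)
    s <- s[s != 0]
    if (length(s) > 1L) osc <- sum(diff(s) != 0)
  }
  out <- list(final_angle = fin, signed_error = fin - target,
              overshoot = over, oscillation_count = osc,
              head_ai = NA_real_, head_torso_final_diff = NA_real_,
              head_alignment_error = NA_real_)
  if (trial$body_part == "torso") {
    hd <- axis_trace(trial$head, axis)
    tr <- axis_trace(trial$torso, axis)
    out$head_ai <- anchoring_index(hd, tr)
    fin_h <- final_window_mean(t, hd, 1.5)
    fin_t <- final_window_mean(t, tr, 1.5)
    out$head_torso_final_diff <- fin_h - fin_t
    out$head_alignment_error <- fin_h - target
  }
  class(out) <- "jar_metrics"
  out
}

#' Per-condition JAR summary across trials
#'
#' Computes [jar_metrics()] for every trial and averages per participant
#' x body part x condition. Lateral targets are pooled by mirroring:
#' the sign-dependent metrics of -15 degree trials (signed error, final
#' angle, head-torso difference, head alignment error) are sign-flipped
#' before averaging. Repetition counts are checked against the study
#' protocol (5 per orientation with Feedback, 10 otherwise) and
#' deviations reported with a warning.
#'
#' @param trials List of [jar_trial()]s carrying `meta$participant_id`.
#' @param axis Task-relevant axis (see [final_orientation()]).
#' @param check_protocol Validate repetition counts (default TRUE).
#' @return List with `trials` (per-trial metric data.frame) and
#'   `summary` (per participant x body part x condition means).
#' @export
jar_condition_summary <- function(trials, axis = "lateral",
                                  check_protocol = TRUE) {
  rows <- lapply(trials, function(tr) {
    m <- jar_metrics(tr, axis = axis)
    flip <- if (tr$target_angle < 0) -1 else 1
    data.frame(participant_id = tr$meta$participant_id %||% NA_character_,
               age_group = tr$meta$age_group %||% NA_character_,
               body_part = tr$body_part, condition = tr$condition,
               target = tr$target_angle,
               final_angle = m$final_angle,
               signed_error = flip * m$signed_error,
               overshoot = m$overshoot,
               oscillation_count = m$oscillation_count,
               head_ai = m$head_ai,
               head_torso_final_diff = flip * m$head_torso_final_diff,
               head_alignment_error = flip * m$head_alignment_error)
  })
  per_trial <- do.call(rbind, rows)
  if (check_protocol) {
    missing_cond <- setdiff(JAR_CONDITIONS, unique(per_trial$condition))
    if (length(missing_cond))
      stop("condition(s) absent from the trial set: ",
           paste(missing_cond, collapse = ", "), call. = FALSE)
    expected <- c(Feedback = 5, NoFeedback = 10, Forward = 10)
    cnt <- stats::aggregate(final_angle ~ participant_id + body_part +
                              condition + target,
                            per_trial, length)
    bad <- cnt$final_angle != expected[cnt$condition]
    if (any(bad))
      warning(sprintf("%d participant/condition/target cell(s) deviate from the 5/10/10 protocol",
                      sum(bad)), call. = FALSE)
  }
  num <- c("signed_error", "overshoot", "oscillation_count", "head_ai",
           "head_torso_final_diff", "head_alignment_error")
  agg <- stats::aggregate(per_trial[num],
                          per_trial[c("participant_id", "age_group",
                                      "body_part", "condition")],
                          function(v) mean(v, na.rm = TRUE))
  list(trials = per_trial, summary = agg)
}
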