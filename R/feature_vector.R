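#' Catalog of the 50 descriptive kinematic variables
#'
#' Names, human-readable labels and a priori functional category of each
#' variable of the descriptive battery. Categories (`error`, `head`,
#' `torso`, `coordination`, `trajectory`) drive the functional clustering
#' of PCA-selected variables.
#'
#' @return A data.frame with columns `name`, `label`, `category`.
#' @export
feature_catalog <- function() {
  axes <- c("pitch", "roll", "yaw")
  pairs <- c("pitch_pitch", "roll_roll", "yaw_yaw", "roll_yaw", "yaw_roll")
  name <- c("error_mean", "error_median", "error_max", "path_ratio",
            "time",
            paste0("head_amp_", axes),
            paste0("torso_amp_", axes),
            paste0("torso_speed_mean_", axes),
            paste0("torso_speed_max_", axes),
            "torso_speed_mean_norm", "torso_speed_max_norm",
            paste0("corr_", pairs),
            paste0("ai_", axes),
            paste0("xcorr_time_", pairs),
            paste0("dtw_", axes),
            paste0("sal_", axes),
            paste0("peaks_head_", axes),
            paste0("peaks_torso_", axes),
            paste0("peaks_bird_", axes),
            paste0("speed_ratio_", axes))
  category <- c(rep("error", 5),
                rep("head", 3), rep("torso", 11),
                rep("coordination", 16),
                rep("torso", 3), rep("head", 3), rep("torso", 3),
                rep("trajectory", 3), rep("torso", 3))
  data.frame(name = sprintf("var%02d_%s", seq_along(name), name),
             label = name, category = category)
}

## Euler-like orientation of the flight ("bird") from the trajectory:
## azimuth (yaw) and elevation (pitch) of the velocity vector, and a
## coordinated-turn bank angle (roll) from the turn rate,
## tan(bank) = v * d(azimuth)/dt / g.
bird_angles <- function(position, dt) {
  v <- diff(position) / dt
  spd <- sqrt(rowSums(v^2))
  spd[spd == 0] <- 1e-12
  az <- atan2(v[, 2], v[, 1])
  el <- asin(pmax(-1, pmin(1, v[, 3] / spd)))
  az_u <- az
  if (length(az_u) > 1) {
    w <- c(0, cumsum(round(-diff(az) / (2 * pi))))
    az_u <- az + 2 * pi * w
  }
  turn_rate <- c(0, diff(az_u) / dt)
  bank <- atan(spd * turn_rate / 9.81)
  list(pitch = rad2deg(el), roll = rad2deg(bank), yaw = rad2deg(az_u))
}

## The 50-variable battery for one valid segment (path-ratio slot NA;
## filled at the sequence level). Returns a named numeric vector.
segment_features <- function(seg, position_slice, dt,
                             dtw_length = 64L, peak_prominence = 1,
                             sal_fc = 10, sal_amp_th = 0.05,
                             bird_on = "heading") {
  hd <- seg$head; tr <- seg$torso
  axes <- c("pitch", "roll", "yaw")
  pairs <- list(c("pitch", "pitch"), c("roll", "roll"), c("yaw", "yaw"),
                c("roll", "yaw"), c("yaw", "roll"))
  out <- setNames(rep(NA_real_, 50), feature_catalog()$name)
  out[1:3] <- c(seg$error, seg$error, seg$error)  # summarized per sequence
  out[5] <- seg$duration
  out[6:8] <- vapply(axes, function(a) iqr_amplitude(hd[[a]]), 0)
  out[9:11] <- vapply(axes, function(a) iqr_amplitude(tr[[a]]), 0)
  sp <- angular_speed_stats(tr)
  out[12:14] <- sp$mean[axes]; out[15:17] <- sp$max[axes]
  out[18] <- sp$mean["norm"]; out[19] <- sp$max["norm"]
  out[20:24] <- vapply(pairs, function(p)
    head_torso_correlation(hd[[p[1]]], tr[[p[2]]]), 0)
  out[25:27] <- vapply(axes, function(a)
    anchoring_index(hd[[a]], tr[[a]]), 0)
  out[28:32] <- vapply(pairs, function(p)
    xcorr_peak_time(hd[[p[1]]], tr[[p[2]]], dt), 0)
  out[33:35] <- vapply(axes, function(a)
    dtw_distance(hd[[a]], tr[[a]], dtw_length), 0)
  rates <- lapply(axes, function(a) abs(diff(tr[[a]])) / dt)
  out[36:38] <- vapply(rates, function(r)
    if (length(r) >= 8L) spectral_arc_length(r, dt, fc = sal_fc,
                                             amp_th = sal_amp_th)
    else NA_real_, 0)
  out[39:41] <- vapply(axes, function(a)
    count_peaks(hd[[a]], dt, peak_prominence), 0)
  out[42:44] <- vapply(axes, function(a)
    count_peaks(tr[[a]], dt, peak_prominence), 0)
  if (!is.null(position_slice) && nrow(position_slice) >= 4L) {
    if (bird_on == "heading") {
      ba <- bird_angles(position_slice, dt)
      out[45:47] <- vapply(axes, function(a)
        count_peaks(ba[[a]], dt, peak_prominence), 0)
    } else {
      out[45:47] <- vapply(1:3, function(j)
        count_peaks(position_slice[, j], dt, peak_prominence), 0)
    }
  }
  out[48:50] <- vapply(axes, function(a) speed_ratio(tr[[a]], dt), 0)
  out
}

#' Compute the per-sequence feature vector of a flight trial
#'
#' Splits the trial into between-coin segments, applies the
#' discontinuity rejection rule, computes the 50-variable descriptive
#' battery on each valid segment and averages arithmetically over the
#' sequence, ignoring per-segment values that are undefined (e.g.
#' correlations of flat traces). The error summaries (mean / median /
#' max over per-coin crossing errors) and the path ratio are computed
#' once at the sequence level; the travelled path is clipped to the
#' window between the first and last coin-plane crossings.
#'
#' @param trial A flight [trial_recording()].
#' @param course The [coin_course()] flown.
#' @param ideal Optional precomputed [catmull_rom_path()].
#' @param reject_threshold Discontinuity rejection threshold in degrees.
#' @param include_missed Include missed-coin closest-approach errors in
#'   the error summaries (default TRUE).
#' @param dtw_length,peak_prominence,sal_fc,sal_amp_th Feature
#'   parameters, see the individual feature functions.
#' @param bird_on Compute the flight ("bird") peak counts on the
#'   trajectory's `"heading"` angles (default) or on its `"position"`
#'   components.
#' @return An object of class `feature_vector`: list with `values`
#'   (named numeric, 50 variables), `status` (`"ok"` or `"rejected"`),
#'   `n_segments`, `n_rejected`, `meta`.
#' @export
feature_vector <- function(trial, course, ideal = NULL,
                           reject_threshold = 20, include_missed = TRUE,
                           dtw_length = 64L, peak_prominence = 1,
                           sal_fc = 10, sal_amp_th = 0.05,
                           bird_on = c("heading", "position")) {
  bird_on <- match.arg(bird_on)
  ideal <- ideal %||% catmull_rom_path(course)
  segs <- split_segments(trial, course, ideal)
  segs <- lapply(segs, reject_discontinuities, threshold = reject_threshold)
  valid <- vapply(segs, function(s) isTRUE(s$valid), TRUE)
  n_rej <- sum(!valid)
  cat_names <- feature_catalog()$name
  if (!any(valid)) {
    return(structure(list(values = setNames(rep(NA_real_, 50), cat_names),
                          status = "rejected", n_segments = length(segs),
                          n_rejected = n_rej, meta = trial$meta),
                     class = "feature_vector"))
  }
  dt <- sample_step(trial$head)
  t <- trial$head$t
  cr <- plane_crossings(trial$position, t, course, ideal)
  mat <- vapply(segs[valid], function(s) {
    idx <- which(t >= s$head$t[1] - 1e-12 & t <= s$head$t[length(s$head$t)] + 1e-12)
    segment_features(s, trial$position[idx, , drop = FALSE], dt,
                     dtw_length, peak_prominence, sal_fc, sal_amp_th,
                     bird_on)
  }, numeric(50))
  vals <- rowMeans(mat, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  # sequence-level error summaries over per-coin crossing errors
  err <- cr$error[-1]
  if (!include_missed) err <- err[!cr$missed[-1]]
  vals[1] <- mean(err); vals[2] <- median(err); vals[3] <- max(err)
  # sequence-level path ratio, clipped between first and last crossings
  inwin <- which(t >= cr$time[1] & t <= cr$time[nrow(cr)])
  vals[4] <- path_ratio(trial$position[inwin, , drop = FALSE], ideal)
  names(vals) <- cat_names
  structure(list(values = vals, status = "ok",
                 n_segments = length(segs), n_rejected = n_rej,
                 meta = trial$meta),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s: %d segments (%d rejected)\n",
              x$status, x$n_segments, x$n_rejected))
  invisible(x)
}

#' Feature table over a set of flight trials
#'
#' @param trials List of flight [trial_recording()]s; each trial's
#'   `meta$course_id` selects its course from `courses`.
#' @param courses Either a single [coin_course()] used for every trial
#'   or a named list of courses keyed by `course_id`.
#' @param ... Passed on to [feature_vector()].
#' @return A data.frame with metadata columns (`participant_id`,
#'   `age_group`, `control`, `phase`, `status`, `n_rejected`) and one
#'   column per variable.
#' @export
feature_table <- function(trials, courses, ...) {
  single <- inherits(courses, "coin_course")
  ideals <- if (single) catmull_rom_path(courses) else
    lapply(courses, catmull_rom_path)
  rows <- lapply(trials, function(tr) {
    if (single) { crs <- courses; idl <- ideals }
    else {
      cid <- tr$meta$course_id
      if (is.null(cid) || is.null(courses[[cid]]))
        stop("trial has no course_id matching `courses`", call. = FALSE)
      crs <- courses[[cid]]; idl <- ideals[[cid]]
    }
    fv <- feature_vector(tr, crs, idl, ...)
    m <- tr$meta
    cbind(data.frame(participant_id = m$participant_id %||% NA_character_,
                     age_group = m$age_group %||% NA_character_,
                     control = m$control %||% NA_character_,
                     phase = m$phase %||% NA_character_,
                     status = fv$status, n_rejected = fv$n_rejected),
          as.data.frame(as.list(fv$values)))
  })
  do.call(rbind, rows)
}
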