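#' Interquartile-range amplitude of an angle trace
#'
#' Q3 - Q1 of the samples, using linear-interpolation (type-7) quantiles.
#'
#' @param x Numeric angle trace (degrees), at least 4 samples.
#' @return Amplitude in degrees.
#' @export
iqr_amplitude <- function(x) {
  if (length(x) < 4L)
    stop("degenerate segment: need at least 4 samples", call. = FALSE)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Mean and maximum angular speed per axis and for the 3D rate norm
#'
#' Finite-difference rates |delta angle| / delta t per axis; the norm is
#' the per-sample Euclidean norm of the three signed axis rates.
#'
#' @param series An [angle_series()] with at least 2 samples.
#' @return List with numeric vectors `mean` and `max`, each named
#'   `pitch`, `roll`, `yaw`, `norm` (degrees/s).
#' @export
angular_speed_stats <- function(series) {
  if (n_samples(series) < 2L)
    stop("degenerate segment: need at least 2 samples", call. = FALSE)
  dt <- sample_step(series)
  r <- cbind(pitch = diff(series$pitch), roll = diff(series$roll),
             yaw = diff(series$yaw)) / dt
  nrm <- sqrt(rowSums(r^2))
  a <- abs(r)
  list(mean = c(colMeans(a), norm = mean(nrm)),
       max = c(apply(a, 2, max), norm = max(nrm)))
}

#' Absolute head-torso correlation for an axis pair
#'
#' @param head,torso Numeric angle traces of equal length (>= 3).
#' @param use_rates Correlate the finite-difference rates instead of
#'   the angle positions (default FALSE).
#' @return |Pearson r| in \[0, 1\], or `NA` when either trace has zero
#'   variance.
#' @export
head_torso_correlation <- function(head, torso, use_rates = FALSE) {
  if (length(head) != length(torso) || length(head) < 3L)
    stop("traces must have equal length >= 3", call. = FALSE)
  if (use_rates) { head <- diff(head); torso <- diff(torso) }
  if (sd(head) == 0 || sd(torso) == 0) return(NA_real_)
  abs(cor(head, torso))
}

#' Head anchoring index
#'
#' Delta sigma = (sigma_r - sigma_a) / (sigma_r + sigma_a), where
#' sigma_a is the standard deviation of the head angles in space and
#' sigma_r that of the head angles relative to the torso (head - torso).
#' +1 means the head is perfectly stabilized to external space, -1 that
#' it is rigidly locked to the torso.
#'
#' @param head_abs Head angle trace in space (degrees).
#' @param torso Torso angle trace on the same axis and grid.
#' @return Value in \[-1, 1\], or `NA` when both SDs are zero.
#' @export
anchoring_index <- function(head_abs, torso) {
  sa <- sd(head_abs)
  sr <- sd(head_abs - torso)
  if (sa + sr == 0) return(NA_real_)
  (sr - sa) / (sr + sa)
}

#' Lag of the peak of the head-torso cross-correlation
#'
#' Pearson-style per-lag normalized cross-correlation over the
#' overlapping samples, searched over +/- `max_lag` samples (default
#' half the segment length). Negative values mean the head is moving
#' ahead of the torso. Ties are broken toward the smallest |lag|.
#'
#' @param head,torso Numeric traces of equal length; mean-centered
#'   internally.
#' @param dt Sample step in seconds.
#' @param max_lag Maximum lag magnitude in samples.
#' @return Peak lag in seconds, or `NA` for flat signals.
#' @export
xcorr_peak_time <- function(head, torso, dt = SAMPLE_PERIOD,
                            max_lag = NULL) {
  n <- length(head)
  if (length(torso) != n) stop("traces must have equal length",
                               call. = FALSE)
  if (sd(head) == 0 || sd(torso) == 0) return(NA_real_)
  h <- head - mean(head); tt <- torso - mean(torso)
  K <- max_lag %||% floor(n / 2)
  best_r <- -Inf; best_k <- NA_integer_
  for (k in -K:K) {
    if (k >= 0) { a <- h[seq_len(n - k)]; b <- tt[seq_len(n - k) + k] }
    else        { a <- h[seq_len(n + k) - k]; b <- tt[seq_len(n + k)] }
    if (length(a) < 3L || sd(a) == 0 || sd(b) == 0) next
    r <- cor(a, b)
    if (r > best_r + 1e-12 ||
        (abs(r - best_r) <= 1e-12 && abs(k) < abs(best_k))) {
      best_r <- r; best_k <- k
    }
  }
  if (is.na(best_k)) return(NA_real_)
  -best_k * dt
}

#' Dynamic time warping distance between head and torso traces
#'
#' Both traces are linearly resampled to `target_length` points (keeping
#' the number of points constant across sequences), then aligned with
#' classic unconstrained DTW using the symmetric step pattern and
#' absolute-difference local cost. The cumulative path cost is returned.
#'
#' @param head,torso Numeric traces (non-empty).
#' @param target_length Common resampled length (>= 2, default 64).
#' @return Non-negative cumulative alignment cost.
#' @export
dtw_distance <- function(head, torso, target_length = 64L) {
  if (target_length < 2L)
    stop("target_length must be >= 2", call. = FALSE)
  if (!length(head) || !length(torso))
    stop("empty trace", call. = FALSE)
  rs <- function(x) {
    if (length(x) == 1L) rep(x, target_length)
    else approx(seq_along(x), x, n = target_length)$y
  }
  dtw_cost_cpp(rs(head), rs(torso))
}

#' Spectral arc length (SAL) smoothness of a speed profile
#'
#' Arc length of the normalized Fourier magnitude spectrum of the speed
#' profile: the profile is zero-padded (4 levels beyond the next power
#' of two), the magnitude spectrum is normalized by its DC value, cut at
#' `fc` Hz, and further restricted by an adaptive amplitude threshold;
#' the negated arc length of the remaining spectrum is returned. More
#' negative values indicate jerkier movement.
#'
#' @param speed Non-negative speed profile (degrees/s), >= 8 samples.
#' @param dt Sample step in seconds.
#' @param padlevel Zero-padding levels beyond the next power of two.
#' @param fc Cutoff frequency in Hz.
#' @param amp_th Adaptive amplitude threshold on the normalized spectrum.
#' @return SAL (dimensionless, <= 0), or `NA` for an all-zero profile.
#' @export
spectral_arc_length <- function(speed, dt = SAMPLE_PERIOD, padlevel = 4L,
                                fc = 10, amp_th = 0.05) {
  if (length(speed) < 8L)
    stop("need at least 8 samples", call. = FALSE)
  if (all(speed == 0)) return(NA_real_)
  fs <- 1 / dt
  nfft <- 2^(ceiling(log2(length(speed))) + padlevel)
  M <- Mod(fft(c(speed, rep(0, nfft - length(speed)))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  M <- M / max(M)
  sel <- which(f <= fc)
  f <- f[sel]; M <- M[sel]
  inx <- which(M >= amp_th)
  if (length(inx) < 2L) return(0)
  keep <- inx[1]:inx[length(inx)]
  f <- f[keep]; M <- M[keep]
  frange <- f[length(f)] - f[1]
  if (frange <= 0) return(0)
  -sum(sqrt((diff(f) / frange)^2 + diff(M)^2))
}

## Local-maximum prominences of a trace (simple scalar implementation:
## prominence = peak height minus the higher of the two valley minima
## separating it from higher ground on each side).
peak_prominences <- function(x) {
  n <- length(x)
  peaks <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(peaks)) return(numeric(0))
  vapply(peaks, function(i) {
    lo <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lo <- min(lo, x[j]) }
    left <- lo
    lo <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; lo <- min(lo, x[j]) }
    x[i] - max(left, lo)
  }, numeric(1))
}

#' Time-normalized number of peaks of an angle trace
#'
#' Local maxima with prominence of at least `prominence` degrees,
#' divided by the trace duration.
#'
#' @param x Numeric trace (>= 3 samples).
#' @param dt Sample step in seconds.
#' @param prominence Minimum peak prominence in degrees (default 1,
#'   above sensor noise).
#' @return Peaks per second (>= 0).
#' @export
count_peaks <- function(x, dt = SAMPLE_PERIOD, prominence = 1) {
  if (length(x) < 3L)
    stop("need at least 3 samples", call. = FALSE)
  sum(peak_prominences(x) >= prominence) / ((length(x) - 1) * dt)
}

#' Ratio of mean to maximum angular speed
#'
#' A value close to 1 indicates a smooth, constant-rate movement; lower
#' values indicate jerkier movement.
#'
#' @param x Numeric angle trace.
#' @param dt Sample step in seconds.
#' @return Value in (0, 1\], or `NA` when the trace never moves.
#' @export
speed_ratio <- function(x, dt = SAMPLE_PERIOD) {
  r <- abs(diff(x)) / dt
  m <- max(r)
  if (m == 0) return(NA_real_)
  mean(r) / m
}
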