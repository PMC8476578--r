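# Shared fixtures built in code.

DT <- 0.068

# straight course along +x (no randomness)
straight_course <- function(n_coins = 6L, spacing = 58) {
  coins <- cbind(x = spacing * (seq_len(n_coins) - 1), y = 0, z = 30)
  coin_course(coins, rep("forward", n_coins - 1L))
}

make_series <- function(pitch, roll = pitch, yaw = pitch, dt = DT) {
  n <- length(pitch)
  angle_series((seq_len(n) - 1) * dt, pitch, roll, yaw)
}

# constant-speed straight flight trial down the +x axis
straight_flight_trial <- function(course = straight_course(),
                                  speed = 12, dt = DT,
                                  offset = c(0, 0, 0)) {
  total <- max(course$coins[, 1]) + 10
  n <- ceiling(total / speed / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  pos <- cbind(speed * t - 5, rep(0, n), rep(30, n))
  pos <- sweep(pos, 2, offset, "+")
  a <- make_series(2 * sin(2 * pi * 0.4 * t), 3 * sin(2 * pi * 0.3 * t),
                   2 * cos(2 * pi * 0.5 * t), dt)
  b <- make_series(1 * sin(2 * pi * 0.4 * t + 0.4),
                   2 * sin(2 * pi * 0.3 * t + 0.2),
                   1 * cos(2 * pi * 0.5 * t + 0.1), dt)
  trial_recording(a, b, pos, meta = list(study = "flight"))
}

# a bare flight_segment for feature-level tests
make_segment <- function(head, torso, error = 1, duration = NULL) {
  structure(list(head = head, torso = torso,
                 duration = duration %||% coordkin::duration(head),
                 coin_from = 1L, coin_to = 2L, error = error,
                 missed = FALSE, valid = TRUE, reason = NA_character_),
            class = "flight_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive DTW oracle: enumerate every monotone warping path
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(n, m)
}
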