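#' Coin course of the steering task
#'
#' Ordered 3D coin positions with per-span maneuver labels. Consecutive
#' coins are a fixed distance apart (58 m in the study protocol); the
#' first coin has a 1 m diameter and coins following a catch are enlarged
#' to 2 m.
#'
#' @param coins n x 3 matrix of coin positions (m).
#' @param maneuvers Character vector of length n - 1 with values in
#'   `"forward"`, `"right"`, `"left"`, `"ascent"`, `"descent"`.
#' @param coin_diameters Coin diameters in meters (default 1 m for the
#'   first coin, 2 m afterwards).
#' @param speed Constant flight speed in m/s.
#' @param spacing Nominal consecutive-coin distance in meters.
#' @return An object of class `coin_course`.
#' @export
coin_course <- function(coins, maneuvers,
                        coin_diameters = NULL,
                        speed = FLIGHT_SPEED,
                        spacing = COIN_SPACING) {
  coins <- as.matrix(coins)
  n <- nrow(coins)
  if (n < 2L || ncol(coins) != 3L)
    stop("coins must be an n x 3 matrix with n >= 2", call. = FALSE)
  d <- sqrt(rowSums((coins[-1, , drop = FALSE] -
                     coins[-n, , drop = FALSE])^2))
  if (any(abs(d - spacing) > 1e-6))
    stop(sprintf("consecutive coin distance must be %g m (within 1e-6)",
                 spacing), call. = FALSE)
  maneuvers <- as.character(maneuvers)
  if (length(maneuvers) != n - 1L)
    stop("need one maneuver label per span (n_coins - 1)", call. = FALSE)
  ok <- maneuvers %in% c("forward", "right", "left", "ascent", "descent")
  if (!all(ok))
    stop("unknown maneuver label(s): ",
         paste(unique(maneuvers[!ok]), collapse = ", "), call. = FALSE)
  coin_diameters <- coin_diameters %||% c(1, rep(2, n - 1L))
  if (length(coin_diameters) != n)
    stop("need one diameter per coin", call. = FALSE)
  colnames(coins) <- c("x", "y", "z")
  structure(list(coins = coins, maneuvers = maneuvers,
                 coin_diameters = as.numeric(coin_diameters),
                 speed = speed, spacing = spacing),
            class = "coin_course")
}

#' @export
print.coin_course <- function(x, ...) {
  cat(sprintf("<coin_course> %d coins, spacing %g m, speed %g m/s\n",
              nrow(x$coins), x$spacing, x$speed))
  invisible(x)
}

#' Generate a reproducible coin course
#'
#' Alternates straight forward spans with one of four directional
#' maneuvers (right turn, left turn, ascent, descent) drawn at random,
#' reproducing the course structure of the steering task. Cumulative
#' azimuth is kept within +/- 45 degrees and elevation within +/- 18
#' degrees so the steering mapping stays inside a realistic body-angle
#' range (a maneuver that would exceed the bound is mirrored).
#'
#' @param n_coins Number of coins (>= 4).
#' @param seed Integer seed; the same seed yields an identical course.
#' @param spacing Consecutive-coin distance in meters.
#' @param turn_step Azimuth change of a turn maneuver (degrees).
#' @param climb_step Elevation change of an ascent/descent (degrees).
#' @return A [coin_course()].
#' @export
generate_course <- function(n_coins, seed = 1L, spacing = COIN_SPACING,
                            turn_step = 20, climb_step = 12) {
  if (n_coins < 4L)
    stop("a course needs at least 4 coins", call. = FALSE)
  set.seed(seed)
  az <- 0; el <- 0
  coins <- matrix(0, n_coins, 3)
  coins[1, ] <- c(0, 0, 30)
  maneuvers <- character(n_coins - 1L)
  for (i in seq_len(n_coins - 1L)) {
    mv <- if (i %% 2L == 1L) "forward" else
      sample(c("right", "left", "ascent", "descent"), 1L)
    # mirror a maneuver that would push the heading out of bounds
    if (mv == "right" && az - turn_step < -45) mv <- "left"
    if (mv == "left"  && az + turn_step >  45) mv <- "right"
    if (mv == "ascent"  && el + climb_step >  18) mv <- "descent"
    if (mv == "descent" && el - climb_step < -18) mv <- "ascent"
    az <- az + switch(mv, left = turn_step, right = -turn_step, 0)
    el <- el + switch(mv, ascent = climb_step, descent = -climb_step, 0)
    u <- c(cos(deg2rad(el)) * cos(deg2rad(az)),
           cos(deg2rad(el)) * sin(deg2rad(az)),
           sin(deg2rad(el)))
    coins[i + 1L, ] <- coins[i, ] + spacing * u
    maneuvers[i] <- mv
  }
  coin_course(coins, maneuvers, spacing = spacing)
}

## Evaluate one centripetal Catmull-Rom span (Barry-Goldman pyramid)
## at parameter values tau in [t1, t2]. P is a 4 x 3 matrix, tk length 4.
cr_span <- function(P, tk, tau) {
  lerp <- function(A, B, ta, tb) {
    w <- (tau - ta) / (tb - ta)
    outer(1 - w, A) + outer(w, B)
  }
  A1 <- lerp(P[1, ], P[2, ], tk[1], tk[2])
  A2 <- lerp(P[2, ], P[3, ], tk[2], tk[3])
  A3 <- lerp(P[3, ], P[4, ], tk[3], tk[4])
  w12 <- (tau - tk[1]) / (tk[3] - tk[1])
  B1 <- (1 - w12) * A1 + w12 * A2
  w23 <- (tau - tk[2]) / (tk[4] - tk[2])
  B2 <- (1 - w23) * A2 + w23 * A3
  w <- (tau - tk[2]) / (tk[3] - tk[2])
  (1 - w) * B1 + w * B2
}

#' Ideal path through a coin course (centripetal Catmull-Rom spline)
#'
#' Builds the dense ideal path interpolating every coin with a centripetal
#' (alpha = 0.5) Catmull-Rom spline. Endpoints are handled with reflected
#' phantom points (P0' = 2 P1 - P2), which keeps the centripetal knot
#' spacing non-degenerate.
#'
#' @param course A [coin_course()] with at least 4 coins.
#' @param samples_per_span Number of polyline samples per coin-to-coin
#'   span (>= 2).
#' @return An object of class `ideal_path` with elements `points` (dense
#'   polyline, m), `arc_length` (cumulative meters), `coin_index` (row of
#'   `points` at each coin) and `tangents` (unit tangent at each coin).
#' @export
catmull_rom_path <- function(course, samples_per_span = 20L) {
  stopifnot(inherits(course, "coin_course"))
  coins <- course$coins
  n <- nrow(coins)
  if (n < 4L) stop("catmull_rom_path needs at least 4 coins", call. = FALSE)
  if (samples_per_span < 2L)
    stop("samples_per_span must be >= 2", call. = FALSE)
  P <- rbind(2 * coins[1, ] - coins[2, ], coins,
             2 * coins[n, ] - coins[n - 1, ])
  alpha <- 0.5
  tk <- c(0, cumsum(sqrt(sqrt(rowSums(diff(P)^2)))^(2 * alpha)))
  pts <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kn <- tk[i:(i + 3L)]
    tau <- seq(kn[2], kn[3], length.out = samples_per_span + 1L)
    if (i < n - 1L) tau <- tau[-(samples_per_span + 1L)]
    pts[[i]] <- cr_span(P[i:(i + 3L), , drop = FALSE], kn, tau)
  }
  points <- do.call(rbind, pts)
  seg <- sqrt(rowSums(diff(points)^2))
  coin_index <- c(seq(1L, by = samples_per_span, length.out = n - 1L),
                  nrow(points))
  tangents <- t(vapply(seq_len(n), function(i) {
    k <- coin_index[i]
    a <- max(1L, k - 1L); b <- min(nrow(points), k + 1L)
    v <- points[b, ] - points[a, ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  structure(list(points = points, arc_length = c(0, cumsum(seg)),
                 coin_index = coin_index, tangents = tangents,
                 course = course),
            class = "ideal_path")
}

#' @export
print.ideal_path <- function(x, ...) {
  cat(sprintf("<ideal_path> %d points, %.1f m through %d coins\n",
              nrow(x$points), max(x$arc_length), nrow(x$course$coins)))
  invisible(x)
}

## Locate, for every coin, the crossing of the vertical plane through the
## coin center perpendicular to the ideal-path tangent at that coin.
## Returns a data.frame with one row per coin: interpolated crossing time,
## in-plane distance to the coin center, and a missed flag (closest
## approach used when the plane is never crossed).
plane_crossings <- function(position, t, course, ideal = NULL) {
  position <- as.matrix(position)
  ideal <- ideal %||% catmull_rom_path(course)
  n_coins <- nrow(course$coins)
  out <- data.frame(coin = seq_len(n_coins), time = NA_real_,
                    error = NA_real_, missed = FALSE)
  start <- 1L
  for (i in seq_len(n_coins)) {
    ctr <- course$coins[i, ]
    nrm <- ideal$tangents[i, ]
    s <- drop(position %*% nrm) - sum(ctr * nrm)
    k <- NA_integer_
    if (s[start] >= 0) {
      # already at/beyond the plane at the start of the search window
      out$error[i] <- {
        v <- position[start, ] - ctr
        sqrt(sum((v - sum(v * nrm) * nrm)^2))
      }
      out$time[i] <- t[start]
      next
    }
    if (start < nrow(position)) {
      for (j in start:(nrow(position) - 1L)) {
        if (s[j] < 0 && s[j + 1L] >= 0) { k <- j; break }
      }
    }
    if (is.na(k)) {
      rng <- start:nrow(position)
      j <- rng[which.min(abs(s[rng]))]
      v <- position[j, ] - ctr
      out$error[i] <- sqrt(sum((v - sum(v * nrm) * nrm)^2))
      out$time[i] <- t[j]
      out$missed[i] <- TRUE
      start <- j
    } else {
      f <- -s[k] / (s[k + 1L] - s[k])
      p <- position[k, ] + f * (position[k + 1L, ] - position[k, ])
      out$error[i] <- sqrt(sum((p - ctr)^2))
      out$time[i] <- t[k] + f * (t[k + 1L] - t[k])
      start <- k + 1L
    }
  }
  # boundary times must be non-decreasing for segmentation
  out$time <- cummax(out$time)
  out
}

#' In-plane distance to a coin center at the plane crossing
#'
#' The crossing plane is the vertical plane through the coin center,
#' perpendicular to the ideal-path tangent at that coin. The trajectory
#' is linearly interpolated between samples; if the plane is never
#' crossed the distance at the closest approach is returned and flagged.
#'
#' @param trajectory n x 3 matrix of flight positions (m).
#' @param course A [coin_course()].
#' @param coin_index Which coin (1-based).
#' @param ideal Optional precomputed [catmull_rom_path()] of `course`.
#' @param t Optional time stamps (defaults to sample index).
#' @param in_plane Measure the distance within the crossing plane
#'   (default). `FALSE` measures the full 3D distance to the coin
#'   center, which differs only for missed coins evaluated at the
#'   closest approach.
#' @return Unsigned distance in meters, with attribute `missed`.
#' @export
crossing_error <- function(trajectory, course, coin_index,
                           ideal = NULL, t = NULL, in_plane = TRUE) {
  trajectory <- as.matrix(trajectory)
  t <- t %||% seq_len(nrow(trajectory))
  cr <- plane_crossings(trajectory, t, course, ideal)
  err <- cr$error[coin_index]
  if (!in_plane && cr$missed[coin_index]) {
    # closest-approach point in 3D rather than its in-plane projection
    j <- which.min(abs(t - cr$time[coin_index]))
    err <- sqrt(sum((trajectory[j, ] - course$coins[coin_index, ])^2))
  }
  structure(err, missed = cr$missed[coin_index])
}

#' Ratio of travelled path length to ideal path length
#'
#' @param trajectory n x 3 matrix of flight positions (m).
#' @param ideal An [catmull_rom_path()] result (or any object with an
#'   `arc_length` element).
#' @return Dimensionless ratio (> 0); 1 for a trajectory identical to
#'   the ideal path.
#' @export
path_ratio <- function(trajectory, ideal) {
  trajectory <- as.matrix(trajectory)
  travelled <- sum(sqrt(rowSums(diff(trajectory)^2)))
  len <- max(ideal$arc_length)
  if (len <= 0) stop("ideal path has zero length", call. = FALSE)
  travelled / len
}

#' Write / read a coin course as JSON
#' @param course A [coin_course()].
#' @param path File path.
#' @rdname course_io
#' @export
write_course <- function(course, path) {
  obj <- list(coins = unname(apply(course$coins, 1, as.numeric,
                                   simplify = FALSE)),
              maneuvers = course$maneuvers,
              coin_diameters = course$coin_diameters,
              speed = course$speed, spacing = course$spacing)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname course_io
#' @export
read_course <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coin_course(as.matrix(obj$coins), obj$maneuvers,
              obj$coin_diameters, obj$speed, obj$spacing)
}
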