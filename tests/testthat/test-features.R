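test_that("iqr_amplitude uses linear-interpolation quantiles", {
  expect_equal(iqr_amplitude(rep(3, 10)), 0)
  expect_equal(iqr_amplitude(0:100), 50)
  x <- rnorm(40)
  expect_equal(iqr_amplitude(x + 17.3), iqr_amplitude(x),
               tolerance = 1e-12)
  expect_error(iqr_amplitude(1:3), "at least 4")
})

test_that("angular speeds match closed forms", {
  n <- 80; t <- (0:(n - 1)) * DT
  const <- make_series(rep(4, n))
  st <- angular_speed_stats(const)
  expect_equal(unname(st$mean), rep(0, 4))
  expect_equal(unname(st$max), rep(0, 4))
  ramp <- make_series(5 * t)
  st2 <- angular_speed_stats(ramp)
  expect_equal(unname(st2$mean[1:3]), rep(5, 3), tolerance = 1e-9)
  expect_equal(unname(st2$max[1:3]), rep(5, 3), tolerance = 1e-9)
  # norm of three identical 5 deg/s ramps
  expect_equal(unname(st2$max["norm"]), 5 * sqrt(3), tolerance = 1e-9)
  # sinusoid A sin(2 pi f t): max rate 2 pi f A within 2% at 68 ms
  A <- 10; f <- 0.5
  nn <- 3000; tt <- (0:(nn - 1)) * DT
  sine <- make_series(A * sin(2 * pi * f * tt))
  st3 <- angular_speed_stats(sine)
  expect_equal(unname(st3$max[1]), 2 * pi * f * A, tolerance = 0.02)
})

test_that("head-torso correlation is the absolute Pearson r", {
  x <- sin((1:100) / 7)
  expect_equal(head_torso_correlation(x, x), 1)
  expect_equal(head_torso_correlation(x, -x), 1)
  n <- 200
  ph <- 2 * pi * (0:(n - 1)) / n  # whole periods
  expect_lt(head_torso_correlation(sin(ph), cos(ph)), 1e-6)
  expect_true(is.na(head_torso_correlation(rep(1, 10), x[1:10])))
})

test_that("anchoring index hits its analytic fixtures and bounds", {
  set.seed(7)
  torso <- cumsum(rnorm(200))
  head_fixed <- rep(2, 200)
  expect_equal(anchoring_index(head_fixed, torso), 1)      # sigma_a = 0
  expect_equal(anchoring_index(torso + 5, torso), -1)      # sigma_r = 0
  # sigma_a = sigma_r: head - torso = -head when torso = 2 * head
  h <- rnorm(300)
  expect_equal(anchoring_index(h, 2 * h), 0, tolerance = 1e-12)
  # invariance to a shared constant offset
  a <- rnorm(150); b <- rnorm(150)
  expect_equal(anchoring_index(a + 11, b + 11), anchoring_index(a, b),
               tolerance = 1e-9)
  expect_true(is.na(anchoring_index(rep(0, 10), rep(0, 10))))
})

test_that("cross-correlation peak time recovers known lags with the stated sign", {
  n <- 120; t <- (0:(n - 1)) * DT
  x <- sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 0.7 * t)
  expect_equal(xcorr_peak_time(x, x), 0)
  # torso delayed by 5 samples relative to the head: head leads, -0.34 s
  torso <- c(rep(x[1], 5), x[1:(n - 5)])
  expect_equal(xcorr_peak_time(x, torso), -5 * DT, tolerance = 1e-9)
  # swapping the inputs flips the sign
  expect_equal(xcorr_peak_time(torso, x), 5 * DT, tolerance = 1e-9)
  expect_true(is.na(xcorr_peak_time(rep(0, 50), x[1:50])))
})

test_that("DTW equals the exhaustive warping-path oracle on small traces", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 1, 2), 3), 0)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2, 2), 3),
               dtw_oracle(c(0, 1, 2), c(0, 2, 2)))
  set.seed(3)
  for (i in 1:30) {
    len <- sample(2:6, 1)
    a <- sample(0:2, len, replace = TRUE)
    b <- sample(0:2, len, replace = TRUE)
    expect_identical(dtw_distance(a, b, len), dtw_oracle(a, b))
  }
})

test_that("DTW is symmetric and resampling to own length is exact", {
  set.seed(5)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(dtw_distance(a, b, 30), dtw_distance(b, a, 30))
  # resampling a length-n trace to target n leaves it unchanged
  expect_equal(dtw_distance(a, a, 30), 0)
  expect_error(dtw_distance(a, b, 1), ">= 2")
})

test_that("spectral arc length behaves as a smoothness metric", {
  dt <- DT
  t <- (0:149) * dt
  pulse <- exp(-((t - 3) / 0.7)^2)
  two <- pulse + exp(-((t - 7) / 0.5)^2)
  s1 <- spectral_arc_length(pulse, dt)
  s2 <- spectral_arc_length(two, dt)
  expect_lt(s1, 0); expect_lt(s2, 0)
  expect_gt(abs(s2), abs(s1))            # two pulses are jerkier
  # amplitude scaling leaves SAL unchanged (DC normalization)
  expect_equal(spectral_arc_length(5 * pulse, dt), s1, tolerance = 1e-9)
  # a slower copy has (approximately) the same SAL
  t2 <- (0:299) * dt
  slow <- exp(-((t2 - 6) / 1.4)^2)
  expect_equal(spectral_arc_length(slow, dt), s1, tolerance = 0.15)
  expect_true(is.na(spectral_arc_length(rep(0, 20), dt)))
})

test_that("peak counting is prominence-gated and time-normalized", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(count_peaks(seq(0, 5, length.out = 300), 0.01), 0)
  # 1 Hz sinusoid over 10 s: about 1 peak per second
  expect_equal(count_peaks(5 * sin(2 * pi * t), 0.01), 1.0,
               tolerance = 0.1)
  # sub-threshold ripple on a ramp is suppressed
  ripple <- t + 0.1 * sin(2 * pi * 3 * t)
  expect_equal(count_peaks(ripple, 0.01), 0)
})

test_that("speed ratio matches its closed forms", {
  n <- 2000
  # constant-rate ramp: exactly 1
  expect_equal(speed_ratio(seq(0, 50, length.out = n), DT), 1)
  # half-period sinusoidal rate: mean |sin| / max = 2 / pi within 1%
  th <- seq(0, pi, length.out = n)
  x <- -cos(th)   # derivative proportional to sin(th) >= 0
  expect_equal(speed_ratio(x, DT), 2 / pi, tolerance = 0.01)
  expect_true(is.na(speed_ratio(rep(2, 10), DT)))
  set.seed(8)
  for (i in 1:20) expect_lte(speed_ratio(rnorm(50), DT), 1)
})

test_that("feature_vector composes the per-variable trivial cases", {
  co <- generate_course(8, seed = 63)  # course with lateral maneuvers
  cfg <- synth_config(seed = 62, coupling = 1, head_comp_gain = 0,
                      noise_sd = 0, control = "torso")
  tr <- simulate_flight_trial(cfg, co)
  fv <- feature_vector(tr, co)
  v <- fv$values
  expect_identical(fv$status, "ok")
  expect_equal(unname(v["var21_corr_roll_roll"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["var33_dtw_pitch"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["var34_dtw_roll"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["var26_ai_roll"]), -1, tolerance = 1e-9)
  # determinism: repeated calls bit-identical
  expect_identical(fv$values, feature_vector(tr, co)$values)
})

test_that("feature vector bounds hold on randomized synthetic trials", {
  co <- generate_course(4, seed = 71)
  set.seed(72)
  n_trials <- 150
  for (i in seq_len(n_trials)) {
    cfg <- synth_config(seed = 72000 + i,
                        coupling = runif(1),
                        overshoot_gain = runif(1, 0.8, 1.6),
                        head_comp_gain = runif(1, 0, 0.5),
                        noise_sd = runif(1, 0, 3),
                        lag_tau = runif(1, 0.1, 0.8),
                        control = sample(c("head", "torso"), 1))
    v <- feature_vector(simulate_flight_trial(cfg, co), co)$values
    ai <- v[c("var25_ai_pitch", "var26_ai_roll", "var27_ai_yaw")]
    expect_true(all(is.na(ai) | (ai >= -1 & ai <= 1)))
    cr <- v[sprintf("var%02d_corr_%s", 20:24,
                    c("pitch_pitch", "roll_roll", "yaw_yaw",
                      "roll_yaw", "yaw_roll"))]
    expect_true(all(is.na(cr) | (cr >= 0 & cr <= 1)))
    sr <- v[c("var48_speed_ratio_pitch", "var49_speed_ratio_roll",
              "var50_speed_ratio_yaw")]
    expect_true(all(is.na(sr) | (sr > 0 & sr <= 1)))
    dtw <- v[c("var33_dtw_pitch", "var34_dtw_roll", "var35_dtw_yaw")]
    expect_true(all(dtw >= 0))
    expect_gt(v["var04_path_ratio"], 0)
  }
})
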