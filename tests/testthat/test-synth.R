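test_that("the generator is deterministic and validates its parameters", {
  co <- generate_course(5, seed = 51)
  cfg <- synth_config(seed = 52, control = "torso")
  expect_identical(simulate_flight_trial(cfg, co),
                   simulate_flight_trial(cfg, co))
  expect_identical(simulate_jar_trial(cfg, 15, "Forward", "head"),
                   simulate_jar_trial(cfg, 15, "Forward", "head"))
  expect_error(synth_config(coupling = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(lag_tau = 0), "unstable")
  expect_error(synth_config(overshoot_gain = -1), "> 0")
  expect_error(simulate_jar_trial(cfg, 30, "Feedback"), "target")
  expect_error(simulate_jar_trial(cfg, 15, "Nope"), "condition")
})

test_that("rigid coupling propagates through the feature pipeline", {
  co <- generate_course(6, seed = 53)
  cfg <- synth_config(seed = 54, coupling = 1, head_comp_gain = 0,
                      noise_sd = 0, control = "torso")
  tr <- simulate_flight_trial(cfg, co)
  expect_equal(tr$head$roll, tr$torso$roll, tolerance = 1e-12)
  v <- feature_vector(tr, co)$values
  expect_equal(unname(v["var21_corr_roll_roll"]), 1, tolerance = 1e-9)
  expect_equal(unname(v["var35_dtw_yaw"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["var27_ai_yaw"]), -1, tolerance = 1e-9)
})

test_that("perfect tracking yields near-zero errors and unit path ratio", {
  co <- generate_course(6, seed = 55)
  cfg <- synth_config(seed = 56, overshoot_gain = 1, lag_tau = 0.02,
                      noise_sd = 0, control = "torso")
  v <- feature_vector(simulate_flight_trial(cfg, co), co)$values
  expect_lt(unname(v["var01_error_mean"]), 0.5)
  expect_equal(unname(v["var04_path_ratio"]), 1, tolerance = 0.02)
})

test_that("mean crossing error increases strictly with the overshoot gain", {
  co <- generate_course(6, seed = 57)
  means <- vapply(c(1.0, 1.3, 1.6), function(g) {
    errs <- vapply(1:8, function(s) {
      cfg <- synth_config(seed = 570 + s, overshoot_gain = g,
                          noise_sd = 1, lag_tau = 0.3,
                          control = "torso")
      unname(feature_vector(simulate_flight_trial(cfg, co),
                            co)$values["var01_error_mean"])
    }, 0)
    mean(errs)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("JAR trials encode the overshoot-gain arithmetic", {
  cfg <- synth_config(seed = 58, overshoot_gain = 1.2, noise_sd = 0)
  # feedback closes the loop
  mfb <- jar_metrics(simulate_jar_trial(cfg, 15, "Feedback", "torso"))
  expect_equal(mfb$signed_error, 0, tolerance = 1e-9)
  # no feedback: torso overshoots by (g - 1) * target
  mnf <- jar_metrics(simulate_jar_trial(cfg, 15, "NoFeedback", "torso"))
  expect_equal(mnf$signed_error, 3, tolerance = 1e-9)
  # decoupled head stays near vertical
  cfg0 <- synth_config(seed = 59, coupling = 0, head_comp_gain = 0,
                       noise_sd = 0, overshoot_gain = 1)
  m0 <- jar_metrics(simulate_jar_trial(cfg0, 15, "NoFeedback", "torso"))
  expect_equal(m0$head_alignment_error, -15, tolerance = 1e-6)
})

test_that("a single-participant cohort follows the full study protocol", {
  ch <- simulate_cohort(n_per_group = c(`10` = 1L), seed = 60,
                        jar_reps = c(Feedback = 1L, NoFeedback = 1L,
                                     Forward = 1L))
  # 2 controls x 5 sequences with the protocol coin counts
  expect_length(ch$flight, 10)
  counts <- vapply(ch$courses, function(co) nrow(co$coins), 0L)
  expect_identical(unname(counts), c(26L, 50L, 50L, 18L, 26L))
  expect_identical(ch$protocol$phase,
                   c("Before", "Training", "Training", "After",
                     "DayAfter"))
  # 2 body parts x 3 conditions x 3 targets x 1 repetition
  expect_length(ch$jar, 18)
  expect_identical(nrow(ch$truth), 1L)
})

test_that("cohorts are reproducible and sized like the study groups", {
  args <- list(n_per_group = c(`6` = 2L, adult = 2L), seed = 61,
               protocol = data.frame(phase = "Before", n_coins = 6L),
               jar_reps = c(Feedback = 1L, NoFeedback = 2L,
                            Forward = 1L))
  ch1 <- do.call(simulate_cohort, args)
  ch2 <- do.call(simulate_cohort, args)
  expect_identical(ch1, ch2)
  expect_identical(formals(simulate_cohort)$n_per_group,
                   quote(c(`6` = 9L, `8-9` = 12L, `10` = 11L,
                           adult = 13L)))
})

test_that("parameter recovery is monotone in coupling and linear in gain", {
  proto <- data.frame(phase = "Before", n_coins = 6L)
  cs <- seq(0.1, 0.9, by = 0.2)
  gp <- lapply(cs, function(cc) list(coupling = cc, overshoot_gain = 1.2,
                                     head_comp_gain = 0, sd = 0))
  names(gp) <- as.character(seq_along(cs))
  npg <- setNames(rep(1L, length(cs)), names(gp))
  # noiseless sweep: only the coordination structure varies
  ch <- suppressWarnings(
    simulate_cohort(npg, gp, seed = 62, protocol = proto,
                    jar_reps = c(Feedback = 1L, NoFeedback = 3L,
                                 Forward = 1L),
                    noise_sd = 0, gaze_sd = 0.5))
  pr <- parameter_recovery(ch)
  ord <- order(pr$table$coupling)
  expect_true(all(diff(pr$table$coupling_hat[ord]) > 0))
  # NoFeedback signed error is linear in (g - 1) * |target|
  gs <- c(1.0, 1.2, 1.4)
  errs <- vapply(gs, function(g) {
    cfg <- synth_config(seed = 63, overshoot_gain = g, noise_sd = 0)
    jar_metrics(simulate_jar_trial(cfg, 15, "NoFeedback",
                                   "torso"))$signed_error
  }, 0)
  expect_equal(errs, (gs - 1) * 15, tolerance = 1e-9)
})

test_that("recovery collapses when the coordination structure is switched off", {
  # full compensation (h = c) cancels the torso contribution to the head
  # trace, so the nominal coupling leaves no signature in the data
  proto <- data.frame(phase = "Before", n_coins = 5L)
  cs <- seq(0.1, 0.9, by = 0.1)
  gp <- lapply(cs, function(cc) list(coupling = cc, overshoot_gain = 1,
                                     head_comp_gain = cc, sd = 0))
  names(gp) <- as.character(seq_along(cs))
  npg <- setNames(rep(1L, length(cs)), names(gp))
  ch <- suppressWarnings(
    simulate_cohort(npg, gp, seed = 64, protocol = proto,
                    jar_reps = c(Feedback = 1L, NoFeedback = 1L,
                                 Forward = 1L),
                    noise_sd = 2))
  pr <- parameter_recovery(ch)
  expect_lt(abs(pr$spearman["coupling"]), 0.7)
})
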