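test_that("normality screening keeps normal samples and transforms skewed ones", {
  set.seed(201)
  x <- rnorm(100)
  r <- screen_and_transform(x)
  expect_false(r$transformed)
  expect_identical(r$x, x)
  y <- exp(rnorm(100))
  r2 <- screen_and_transform(y)
  expect_true(r2$transformed)
  # the ML lambda of a log-normal sample is near 0 and the transformed
  # sample passes the same screen
  expect_lt(abs(r2$lambda), 0.3)
  expect_gt(nortest::ad.test(r2$x)$p.value, 0.05)
  # the recorded lambda/shift reproduce the transform
  z <- ((y + r2$shift)^r2$lambda - 1) / r2$lambda
  if (abs(r2$lambda) < 1e-8) z <- log(y + r2$shift)
  expect_equal(r2$x, z, tolerance = 1e-12)
  expect_error(screen_and_transform(rnorm(5)), "n >= 8")
  expect_warning(screen_and_transform(rep(2, 20)), "constant")
})

test_that("mixed rm-ANOVA reproduces a hand-worked sums-of-squares oracle", {
  # 2 (between) x 2 (within), 4 subjects per group, fixed values
  y <- c(3.1, 4.0, 2.8, 3.5, 3.9, 4.8, 3.6, 4.1,   # g1: w1 then w2
         5.2, 6.1, 4.9, 5.6, 6.0, 7.2, 5.8, 6.5)   # g2: w1 then w2
  d <- data.frame(
    y = y,
    subject = rep(c(sprintf("a%d", 1:4), sprintf("a%d", 1:4),
                    sprintf("b%d", 1:4), sprintf("b%d", 1:4))),
    w = rep(rep(c("w1", "w2"), each = 4), 2),
    g = rep(c("g1", "g2"), each = 8))
  res <- mixed_rm_anova(d, "y", subject = "subject", within = "w",
                        between = "g")
  # explicit textbook sums of squares
  a <- 2; n <- 4; b <- 2
  grand <- mean(y)
  m_subj <- tapply(d$y, d$subject, mean)
  m_g <- tapply(d$y, d$g, mean)
  m_w <- tapply(d$y, d$w, mean)
  m_gw <- tapply(d$y, interaction(d$g, d$w), mean)
  ss_between_subj <- b * sum((m_subj - grand)^2)
  ss_A <- n * b * sum((m_g - grand)^2)
  ss_subjA <- ss_between_subj - ss_A
  ss_B <- a * n * sum((m_w - grand)^2)
  ss_AB <- n * sum((m_gw - rep(m_g, 2) - rep(m_w, each = 2) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_between_subj - ss_B - ss_AB
  F_A <- (ss_A / (a - 1)) / (ss_subjA / (a * (n - 1)))
  F_B <- (ss_B / (b - 1)) / (ss_err / (a * (n - 1) * (b - 1)))
  F_AB <- (ss_AB / ((a - 1) * (b - 1))) / (ss_err / (a * (n - 1) * (b - 1)))
  expect_equal(res$F[res$effect == "g"], F_A, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "w"], F_B, tolerance = 1e-9)
  expect_equal(res$F[res$effect == "g:w"], F_AB, tolerance = 1e-9)
  expect_equal(res$df_num[res$effect == "g"], 1)
  expect_equal(res$df_den[res$effect == "g"], 6)
  expect_equal(res$partial_eta_sq[res$effect == "g"],
               ss_A / (ss_A + ss_subjA), tolerance = 1e-9)
  expect_equal(res$partial_eta_sq[res$effect == "w"],
               ss_B / (ss_B + ss_err), tolerance = 1e-9)
  # location and scale invariance of F
  d2 <- d; d2$y <- 3 * d$y + 100
  res2 <- mixed_rm_anova(d2, "y", subject = "subject", within = "w",
                         between = "g")
  expect_equal(res2$F, res$F, tolerance = 1e-9)
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
})

test_that("rm-ANOVA on pure noise stays null and incomplete subjects are dropped", {
  set.seed(202)
  d <- expand.grid(subject = sprintf("s%02d", 1:12),
                   w = c("w1", "w2"), p = c("p1", "p2", "p3"))
  d$g <- ifelse(as.integer(sub("s", "", d$subject)) <= 6, "g1", "g2")
  d$y <- rnorm(nrow(d))
  res <- mixed_rm_anova(d, "y", subject = "subject",
                        within = c("w", "p"), between = "g")
  expect_true(all(res$p > 0.05))
  # dropping one subject's cell triggers listwise deletion
  d_inc <- d[-1, ]
  expect_message(res2 <- mixed_rm_anova(d_inc, "y", subject = "subject",
                                        within = c("w", "p"),
                                        between = "g"),
                 "incomplete")
  expect_error(mixed_rm_anova(d, "y", subject = "subject",
                              within = "w",
                              between = NULL) -> tmp, NA)
})

test_that("pairwise tests report Cohen's d with the right conventions", {
  x <- c(1, 2, 3, 4, 5)
  r <- pairwise_with_d(x, x)
  expect_equal(r$cohen_d, 0)
  expect_equal(r$p, 1, tolerance = 1e-12)
  set.seed(204)
  a <- rnorm(50); b <- rnorm(50, mean = 1)
  r2 <- pairwise_with_d(a, b)
  expect_gt(abs(r2$cohen_d), 0.7)
  expect_lt(abs(r2$cohen_d), 1.3)
  expect_lt(r2$p, 0.001)
  # paired with a constant shift is degenerate
  expect_error(pairwise_with_d(a, a + 2, paired = TRUE), "zero variance")
  rp <- pairwise_with_d(a + rnorm(50, 1, 0.5), a, paired = TRUE)
  expect_gt(rp$cohen_d, 0.5)
})

test_that("two-stage BKY control matches limits and dominates stage-1 BH", {
  expect_equal(bky_fdr(rep(1, 10))$n_rejected, 0L)
  expect_equal(bky_fdr(rep(0, 10))$n_rejected, 10L)
  expect_length(bky_fdr(numeric(0))$reject, 0)
  expect_error(bky_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(204)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    res <- bky_fdr(p, 0.05)
    # never fewer rejections than BH at alpha / (1 + alpha)
    bh <- sum(p.adjust(p, "BH") <= 0.05 / 1.05)
    expect_gte(res$n_rejected, bh)
    # flags consistent with the reported count
    expect_equal(sum(res$reject), res$n_rejected)
  }
})

test_that("simple regression summaries are exact", {
  x <- 1:10
  # exact fit: summary.lm warns about its own precision, which is fine
  r <- suppressWarnings(regress_r2(x, 2 * x))
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  set.seed(205)
  xn <- rnorm(100); yn <- rnorm(100)
  r2 <- regress_r2(xn, yn)
  expect_lt(r2$r_squared, 0.05)
  expect_equal(r2$r_squared, cor(xn, yn)^2, tolerance = 1e-12)
  expect_error(regress_r2(rep(1, 10), rnorm(10)), "constant predictor")
})
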