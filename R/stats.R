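#' Normality screening with Box-Cox fallback
#'
#' Tests the sample with the Anderson-Darling test; when normality is
#' rejected at `alpha`, applies a Box-Cox transformation with the
#' maximum-likelihood lambda (values are shifted to be strictly positive
#' first; the shift is recorded).
#'
#' @param x Numeric sample, n >= 8.
#' @param alpha Significance level of the Anderson-Darling screen.
#' @return List with `x` (possibly transformed sample), `transformed`,
#'   `lambda` (NA when untransformed), `shift`, `ad_p`.
#' @export
screen_and_transform <- function(x, alpha = 0.05) {
  if (length(x) < 8L)
    stop("Anderson-Darling screening needs n >= 8", call. = FALSE)
  if (sd(x) == 0) {
    warning("constant sample: returning identity", call. = FALSE)
    return(list(x = x, transformed = FALSE, lambda = NA_real_,
                shift = 0, ad_p = NA_real_))
  }
  ad <- nortest::ad.test(x)
  if (ad$p.value >= alpha)
    return(list(x = x, transformed = FALSE, lambda = NA_real_,
                shift = 0, ad_p = ad$p.value))
  shift <- if (min(x) > 0) 0 else -min(x) + 0.001 * max(diff(range(x)), 1)
  y <- x + shift
  bcd <- data.frame(y = y)
  bc <- MASS::boxcox(y ~ 1, data = bcd, lambda = seq(-5, 5, 0.01),
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(x = z, transformed = TRUE, lambda = lambda, shift = shift,
       ad_p = ad$p.value)
}

#' Mixed repeated-measures ANOVA with partial eta squared
#'
#' Classical univariate mixed ANOVA via `aov()` with an
#' `Error(subject/within)` stratification: one between-subjects factor
#' (optional) and one or two within-subject factors. Partial eta squared
#' is SS_effect / (SS_effect + SS_error) with the error term of the
#' effect's stratum. Subjects with incomplete within-cells are dropped
#' listwise (with a message). No sphericity correction is applied by
#' default.
#'
#' @param data Long-format data.frame.
#' @param response Name of the response column.
#' @param subject Name of the subject-id column.
#' @param within Character vector (length 1 or 2) of within-subject
#'   factor columns.
#' @param between Optional name of the between-subjects factor column.
#' @return A data.frame with one row per effect: `effect`, `df_num`,
#'   `df_den`, `ss`, `F`, `p`, `partial_eta_sq`.
#' @export
mixed_rm_anova <- function(data, response, subject, within,
                           between = NULL) {
  data <- as.data.frame(data)
  for (v in c(subject, within, between))
    data[[v]] <- factor(data[[v]])
  for (v in c(within, between))
    if (nlevels(data[[v]]) < 2L)
      stop("factor '", v, "' needs at least 2 levels", call. = FALSE)
  # listwise deletion of subjects with incomplete within-design
  cells <- interaction(data[within], drop = TRUE)
  n_cells <- nlevels(cells)
  cnt <- table(data[[subject]], cells)
  ok <- rownames(cnt)[apply(cnt, 1, function(r) all(r == r[1]) && r[1] > 0)]
  if (length(ok) < nlevels(data[[subject]])) {
    message(sprintf("dropping %d subject(s) with incomplete cells",
                    nlevels(data[[subject]]) - length(ok)))
    data <- data[data[[subject]] %in% ok, , drop = FALSE]
    data[[subject]] <- droplevels(data[[subject]])
  }
  rhs <- paste(c(between, within), collapse = " * ")
  errterm <- paste0("Error(", subject, "/(",
                    paste(within, collapse = " * "), "))")
  f <- stats::as.formula(paste(response, "~", rhs, "+", errterm))
  fit <- aov(f, data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    res <- which(rn == "Residuals")
    if (!length(res)) next
    ss_err <- tab[res, "Sum Sq"]; df_err <- tab[res, "Df"]
    for (i in setdiff(seq_len(nrow(tab)), res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(" ", "", rn[i]),
        df_num = tab[i, "Df"], df_den = df_err,
        ss = tab[i, "Sum Sq"],
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        partial_eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise t-test with Cohen's d
#'
#' Classical (pooled-variance) two-sample or paired t-test, with
#' Cohen's d computed from the pooled SD (unpaired) or the SD of the
#' differences (paired).
#'
#' @param x,y Numeric samples (paired: equal length).
#' @param paired Paired comparison?
#' @return List with `t`, `df`, `p`, `mean_diff`, `cohen_d`, `n`.
#' @export
pairwise_with_d <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 observations per side", call. = FALSE)
  if (paired) {
    if (length(x) != length(y))
      stop("paired samples must have equal length", call. = FALSE)
    d <- x - y
    if (sd(d) <= 1e-10 * (abs(mean(d)) + 1))
      stop("zero variance of the paired differences", call. = FALSE)
    tt <- t.test(x, y, paired = TRUE)
    cd <- mean(d) / sd(d)
  } else {
    if (sd(x) == 0 && sd(y) == 0)
      stop("zero variance in both groups", call. = FALSE)
    tt <- t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    cd <- (mean(x) - mean(y)) / sp
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(x) - mean(y), cohen_d = cd,
       n = c(length(x), length(y)))
}

## Number of Benjamini-Hochberg step-up rejections of p at level q.
bh_n_rejected <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- which(ps <= q * seq_len(m) / m)
  if (!length(k)) 0L else max(k)
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR control
#'
#' The adaptive two-stage linear step-up procedure: stage 1 applies a
#' step-up at q' = alpha / (1 + alpha) to estimate the number of true
#' nulls m0 = m - r1; stage 2 re-applies the step-up at q' * m / m0.
#' When stage 1 rejects nothing or everything the procedure stops there.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @param alpha Target false discovery rate (default 0.05).
#' @return List with `reject` (logical, in input order), `n_rejected`,
#'   `m0` (estimated true nulls; NA when stage 1 stopped the procedure),
#'   `stage2_level`, `threshold` (largest rejected p, 0 if none).
#' @export
bky_fdr <- function(pvals, alpha = 0.05) {
  if (!length(pvals))
    return(list(reject = logical(0), n_rejected = 0L, m0 = NA_real_,
                stage2_level = NA_real_, threshold = 0))
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvals)
  q1 <- alpha / (1 + alpha)
  r1 <- bh_n_rejected(pvals, q1)
  if (r1 == 0L)
    return(list(reject = rep(FALSE, m), n_rejected = 0L, m0 = NA_real_,
                stage2_level = q1, threshold = 0))
  if (r1 == m)
    return(list(reject = rep(TRUE, m), n_rejected = m, m0 = NA_real_,
                stage2_level = q1, threshold = max(pvals)))
  m0 <- m - r1
  q2 <- q1 * m / m0
  r2 <- bh_n_rejected(pvals, q2)
  thr <- if (r2 > 0L) sort(pvals)[r2] else 0
  list(reject = pvals <= thr & r2 > 0L, n_rejected = r2, m0 = m0,
       stage2_level = q2, threshold = thr)
}

#' Simple linear regression summary
#'
#' @param x Predictor sample (non-constant, n >= 3).
#' @param y Response sample, same length.
#' @return List with `r_squared`, `p` (two-sided slope test), `slope`,
#'   `intercept`, `n`.
#' @export
regress_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(r_squared = sm$r.squared, p = sm$coefficients[2, 4],
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}
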