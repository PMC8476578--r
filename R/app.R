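#' Run the full steering-study analysis chain
#'
#' From a set of flight recordings: feature extraction, z-scoring,
#' Euclidean-distance outlier downweighting, weighted PCA on three
#' subsets (all trials with PC1 selection; torso-controlled trials with
#' PC1 + PC2 selection; head-controlled trials with PC1 selection),
#' normalized-loading variable selection with functional clustering, a
#' t-test confirming the control separation on the all-trials PC1, and
#' mixed repeated-measures ANOVAs (age between, control and phase
#' within) on the error and on a representative of each selected
#' variable, with two-stage FDR control over the collected age-effect
#' p-values. Outlier weights are recomputed per PCA subset.
#'
#' @param cohort A [simulate_cohort()] result, or a list with elements
#'   `flight` (trials) and `courses`.
#' @param loading_threshold Normalized-loading selection threshold.
#' @param outlier_k,outlier_weight Outlier rule parameters.
#' @param reject_threshold Segment discontinuity threshold (degrees).
#' @param anova_phases Phases entering the rm-ANOVA (the training
#'   sequences are excluded by default, keeping a balanced
#'   within-design).
#' @param subsets Which PCA subsets to run (default all three).
#' @param ... Additional arguments passed to [feature_table()].
#' @return List bundle: `features`, `pca` (per subset: `pca`,
#'   `weights`, `selected`, `clusters`), `separation`, `anova`,
#'   `fdr`.
#' @export
run_study1 <- function(cohort, loading_threshold = 0.75, outlier_k = 4,
                       outlier_weight = 0.5, reject_threshold = 20,
                       anova_phases = c("Before", "After", "DayAfter"),
                       subsets = c("all", "torso", "head"), ...) {
  trials <- cohort$flight
  if (!length(trials)) stop("no flight trials in input", call. = FALSE)
  ctl <- unique(vapply(trials, function(tr) tr$meta$control %||% "?", ""))
  if (!all(CONTROLS %in% ctl))
    stop("both control conditions must be present", call. = FALSE)
  ft <- feature_table(trials, cohort$courses,
                      reject_threshold = reject_threshold, ...)
  ft <- ft[ft$status == "ok", , drop = FALSE]
  varcols <- feature_catalog()$name
  pca_on <- function(rows, n_pcs) {
    X <- as.matrix(ft[rows, varcols, drop = FALSE])
    keep <- colSums(is.na(X)) == 0
    X <- X[, keep, drop = FALSE]
    Z <- suppressWarnings(zscore_matrix(X))
    w <- detect_outliers(Z, k = outlier_k, w = outlier_weight)
    p <- weighted_pca(Z, w)
    sel <- select_variables(p, loading_threshold, n_pcs)
    list(pca = p, weights = w, selected = sel,
         clusters = cluster_selected(sel), rows = which(rows))
  }
  res <- list()
  if ("all" %in% subsets)
    res$all <- pca_on(rep(TRUE, nrow(ft)), n_pcs = 1L)
  if ("torso" %in% subsets)
    res$torso <- pca_on(ft$control == "torso", n_pcs = 2L)
  if ("head" %in% subsets)
    res$head <- pca_on(ft$control == "head", n_pcs = 1L)
  separation <- if (!is.null(res$all))
    separation_test(res$all$pca$scores, ft$control, pc = 1L) else NULL
  # rm-ANOVAs on the error and the selected variables
  adat <- ft[ft$phase %in% anova_phases, , drop = FALSE]
  selected_vars <- unique(c("var01_error_mean",
                            unlist(lapply(res, function(r)
                              r$selected$variable))))
  selected_vars <- intersect(selected_vars, names(adat))
  anovas <- list()
  for (v in selected_vars) {
    y <- adat[[v]]
    if (anyNA(y) || sd(y) == 0) next
    st <- screen_and_transform(y)
    adat$.y <- st$x
    anovas[[v]] <- tryCatch(
      mixed_rm_anova(adat, ".y", subject = "participant_id",
                     within = c("control", "phase"),
                     between = "age_group"),
      error = function(e) NULL)
  }
  age_p <- vapply(anovas, function(a)
    a$p[a$effect == "age_group"][1] %||% NA_real_, 0)
  fdr <- bky_fdr(age_p[!is.na(age_p)])
  list(features = ft, pca = res, separation = separation,
       anova = anovas, fdr = fdr)
}

#' Run the full JAR-study analysis chain
#'
#' Per-trial JAR metrics, per participant x body part x condition
#' summaries, and per age group the simple regressions linking the
#' torso-controlled flight error to the JAR decoupling metrics
#' (head-torso final difference without visual feedback, head alignment
#' error with feedback) and to the torso JAR signed error.
#'
#' @param cohort A [simulate_cohort()] result (JAR trials plus at least
#'   one torso-controlled flight sequence per participant); regressions
#'   are skipped with a warning when the flight sequences are absent.
#' @param flight_phase Phase of the torso-controlled flight sequence
#'   used as performance measure (default `"Before"`).
#' @param ... Passed to [jar_condition_summary()].
#' @return List bundle: `metrics` (per-trial), `summary`,
#'   `flight_error` (per participant), `regressions` (per age group).
#' @export
run_study2 <- function(cohort, flight_phase = "Before", ...) {
  if (!length(cohort$jar)) stop("no JAR trials in input", call. = FALSE)
  js <- jar_condition_summary(cohort$jar, ...)
  fl <- Filter(function(tr) identical(tr$meta$control, "torso") &&
                 identical(tr$meta$phase, flight_phase), cohort$flight)
  if (!length(fl)) {
    warning("no torso-controlled flight sequence: regressions skipped",
            call. = FALSE)
    return(list(metrics = js$trials, summary = js$summary,
                flight_error = NULL, regressions = NULL))
  }
  fe <- do.call(rbind, lapply(fl, function(tr) {
    fv <- feature_vector(tr, cohort$courses[[tr$meta$course_id]])
    data.frame(participant_id = tr$meta$participant_id,
               age_group = tr$meta$age_group,
               flight_error = unname(fv$values["var01_error_mean"]))
  }))
  sm <- js$summary
  predictors <- list(
    head_torso_diff_nofeedback = c("head_torso_final_diff", "NoFeedback"),
    head_torso_diff_forward = c("head_torso_final_diff", "Forward"),
    head_alignment_feedback = c("head_alignment_error", "Feedback"),
    signed_error_nofeedback = c("signed_error", "NoFeedback"))
  regressions <- list()
  for (g in unique(fe$age_group)) {
    res <- list()
    for (nm in names(predictors)) {
      metric <- predictors[[nm]][1]; cond <- predictors[[nm]][2]
      px <- sm[sm$body_part == "torso" & sm$condition == cond &
                 sm$age_group == g, c("participant_id", metric)]
      d <- merge(px, fe[fe$age_group == g, ], by = "participant_id")
      res[[nm]] <- tryCatch(regress_r2(d[[metric]], d$flight_error),
                            error = function(e) NULL)
    }
    regressions[[g]] <- res
  }
  list(metrics = js$trials, summary = js$summary, flight_error = fe,
       regressions = regressions)
}
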