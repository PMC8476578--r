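#' Column-wise z-scoring with constant-column dropping
#'
#' @param X Numeric matrix or data.frame (observations x variables).
#' @return Matrix with column mean 0 and SD 1; constant columns are
#'   dropped with a warning (their names in attribute `dropped`).
#' @export
zscore_matrix <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  const <- sds == 0 | is.na(sds)
  if (all(const))
    stop("all variables are constant; nothing to standardize",
         call. = FALSE)
  if (any(const))
    warning("dropping constant variable(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  Z <- scale(X[, !const, drop = FALSE])
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  attr(Z, "dropped") <- colnames(X)[const]
  Z
}

#' Downweight multivariate outliers by Euclidean distance to the centroid
#'
#' Observations whose Euclidean distance to the centroid of the z-scored
#' dataset exceeds the average distance by more than `k` standard
#' deviations of the distance distribution receive weight `w`; all
#' others weight 1.
#'
#' @param Z Standardized matrix (>= 3 observations).
#' @param k SD multiplier (default 4).
#' @param w Downweight for outliers (default 0.5).
#' @return Numeric vector of per-observation weights in `{1, w}`.
#' @export
detect_outliers <- function(Z, k = 4, w = 0.5) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 3L) stop("need at least 3 observations", call. = FALSE)
  ctr <- colMeans(Z)
  d <- sqrt(rowSums(sweep(Z, 2, ctr)^2))
  ifelse(d > mean(d) + k * sd(d), w, 1)
}

#' Weighted principal component analysis
#'
#' Eigendecomposition of the weighted covariance
#' C = sum_i w_i (z_i - mu_w)(z_i - mu_w)' / sum_i w_i with weighted mean
#' mu_w. Components are ordered by decreasing eigenvalue with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param Z Standardized matrix (observations x variables).
#' @param weights Per-observation weights (default all 1).
#' @return An object of class `pca_result`: `loadings` (variables x
#'   components), `scores` (observations x components),
#'   `explained_variance_pct` (sums to 100), `eigenvalues`, `weights`,
#'   `n_effective` (number of components above numerical rank
#'   tolerance).
#' @export
weighted_pca <- function(Z, weights = rep(1, nrow(Z))) {
  Z <- as.matrix(Z)
  if (length(weights) != nrow(Z))
    stop("one weight per observation required", call. = FALSE)
  wn <- weights / sum(weights)
  mu <- colSums(Z * wn)
  Zc <- sweep(Z, 2, mu)
  C <- crossprod(Zc * sqrt(wn))
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(Z)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  scores <- Zc %*% V
  n_eff <- sum(lam > max(lam[1], .Machine$double.eps) * 1e-12)
  if (n_eff < length(lam))
    message(sprintf("rank-deficient data: %d of %d components carry variance",
                    n_eff, length(lam)))
  structure(list(loadings = V, scores = scores,
                 explained_variance_pct = 100 * lam / sum(lam),
                 eigenvalues = lam, weights = weights,
                 n_effective = n_eff),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance_pct
  cat(sprintf("<pca_result> %d observations x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", utils::head(ev, 5)), collapse = ", "),
      if (length(ev) > 5) "...", "\n")
  cat(sprintf("  downweighted observations: %d\n",
              sum(x$weights != 1)))
  invisible(x)
}

#' Select variables by normalized PCA loadings
#'
#' Within each examined component the loadings are normalized by the
#' component's maximum absolute loading; variables whose |normalized
#' loading| exceeds the threshold on any examined component are
#' selected.
#'
#' @param result A [weighted_pca()] result.
#' @param threshold Normalized-loading threshold (default 0.75).
#' @param n_pcs Number of leading components to examine (>= 1).
#' @param normalization `"max_abs"` (default) divides each component's
#'   loadings by its maximum absolute loading; `"unit_norm"` uses the
#'   raw unit-norm eigenvector entries.
#' @return A data.frame with one row per (variable, component) passing
#'   the threshold: `variable`, `pc`, `loading`, `normalized_loading`.
#' @export
select_variables <- function(result, threshold = 0.75, n_pcs = 1L,
                             normalization = c("max_abs", "unit_norm")) {
  if (n_pcs < 1L) stop("n_pcs must be >= 1", call. = FALSE)
  normalization <- match.arg(normalization)
  L <- result$loadings[, seq_len(n_pcs), drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(ncol(L)), function(j) {
    nl <- if (normalization == "max_abs") L[, j] / max(abs(L[, j]))
          else L[, j]
    sel <- abs(nl) > threshold
    if (!any(sel)) return(NULL)
    data.frame(variable = rownames(L)[sel], pc = j,
               loading = L[sel, j], normalized_loading = nl[sel],
               row.names = NULL)
  }))
  out %||% data.frame(variable = character(0), pc = integer(0),
                      loading = numeric(0),
                      normalized_loading = numeric(0))
}

#' Group selected variables into a priori functional clusters
#'
#' @param selected A data.frame from [select_variables()].
#' @param catalog Variable catalog with `name` and `category` columns
#'   (default [feature_catalog()]).
#' @return Named list of character vectors (selected variables per
#'   functional category).
#' @export
cluster_selected <- function(selected, catalog = feature_catalog()) {
  vars <- unique(selected$variable)
  cat <- catalog$category[match(vars, catalog$name)]
  cat[is.na(cat)] <- "other"
  split(vars, cat)
}

#' Two-sample t-test on PC scores between groups
#'
#' @param scores Score matrix from [weighted_pca()] (or a numeric
#'   vector).
#' @param groups Two-level grouping factor.
#' @param pc Which component to test (default 1).
#' @return List with `t`, `df`, `p`, `means`.
#' @export
separation_test <- function(scores, groups, pc = 1L) {
  s <- if (is.matrix(scores)) scores[, pc] else scores
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  if (min(table(groups)) < 2L)
    stop("need at least 2 observations per group", call. = FALSE)
  tt <- t.test(s ~ groups)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = tapply(s, groups, mean))
}
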