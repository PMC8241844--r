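#' Regress lesion volume out of a behavior score
#'
#' Lesion volume is the dominant confound in lesion-symptom mapping: larger
#' strokes damage more voxels and cause worse outcomes, so without control
#' every frequently lesioned voxel inherits a spurious association. This
#' removes it from the behavioral side by ordinary least squares on
#' (intercept, volume).
#'
#' @param y Numeric score vector (length >= 3).
#' @param v Numeric volume vector, same length, not constant.
#' @param log_volume If `TRUE`, regress on `log(v)` instead of raw volume.
#' @return Residual vector with zero mean and zero covariance with the
#'   regressor used.
#' @export
residualize_behavior <- function(y, v, log_volume = FALSE) {
  check_volume_regressor(y, v)
  if (log_volume) v <- log(v)
  qr_v <- qr(cbind(1, v))
  as.vector(qr.resid(qr_v, y))
}

#' Regress lesion volume out of voxelwise lesion data
#'
#' Each column of the subject-by-voxel matrix is replaced by its OLS residual
#' on (intercept, volume); constant columns (including all-ones) become zero
#' columns because the intercept absorbs them.
#'
#' @param X Subject-by-voxel numeric matrix.
#' @param v Volume vector, one entry per row of `X`, not constant.
#' @inheritParams residualize_behavior
#' @return Matrix of the same dimension holding per-column residuals.
#' @export
residualize_voxels <- function(X, v, log_volume = FALSE) {
  check_volume_regressor(X[, 1L], v)
  if (nrow(X) != length(v)) stop("volume length must match rows of X")
  if (log_volume) v <- log(v)
  qr_v <- qr(cbind(1, v))
  out <- qr.resid(qr_v, X)
  dimnames(out) <- dimnames(X)
  out
}

#' @keywords internal
check_volume_regressor <- function(y, v) {
  if (length(y) != length(v)) stop("y and v must have equal length")
  if (length(v) < 3L) stop("need at least 3 subjects")
  if (!all(is.finite(v)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(v) == 0)
    stop("degenerate regressor: lesion volume is constant")
  invisible(TRUE)
}

#' Direct total lesion volume control (DTLVC)
#'
#' Alternative to regression-based volume control: each subject's lesion
#' vector is scaled by `1 / sqrt(total lesioned voxels)` so that every lesion
#' has unit L2 norm, removing the gross volume signal from the feature space.
#' The behavior score is left untouched under this scheme.
#'
#' @param X Subject-by-voxel binary matrix.
#' @param lesion_sizes Total lesioned voxel count per subject (whole brain,
#'   not just the analysis mask); defaults to the row sums of `X`.
#' @return Rescaled matrix.
#' @export
dtlvc <- function(X, lesion_sizes = rowSums(X)) {
  if (any(lesion_sizes <= 0)) stop("lesion sizes must be positive")
  X / sqrt(lesion_sizes)
}

#' Apply the configured nuisance control to lesion data and behavior
#'
#' @param X Subject-by-voxel binary matrix.
#' @param y Behavior scores.
#' @param volumes_ml Lesion volumes (ml).
#' @param method `"regression"` (voxelwise and behavioral OLS on volume, the
#'   default), `"dtlvc"` (lesion-vector normalization, behavior untouched) or
#'   `"none"`.
#' @param lesion_sizes Optional voxel counts for `"dtlvc"`.
#' @inheritParams residualize_behavior
#' @return List with `X_resid`, `y_resid`, `volume_used` and `method_tag`.
#' @export
nuisance_control <- function(X, y, volumes_ml,
                             method = c("regression", "dtlvc", "none"),
                             lesion_sizes = NULL, log_volume = FALSE) {
  method <- match.arg(method)
  out <- switch(method,
    regression = list(
      X_resid = residualize_voxels(X, volumes_ml, log_volume = log_volume),
      y_resid = residualize_behavior(y, volumes_ml, log_volume = log_volume)),
    dtlvc = list(
      X_resid = dtlvc(X, if (is.null(lesion_sizes)) rowSums(X)
                         else lesion_sizes),
      y_resid = y),
    none = list(X_resid = X, y_resid = y))
  out$volume_used <- volumes_ml
  out$method_tag <- method
  out
}

#' Spearman rank correlation with mid-rank ties
#'
#' Correlation of mid-ranks (average ranks on ties) with a two-sided p-value
#' from the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom. For n <= 8, `exact = TRUE` enumerates all n!
#' permutations of one argument instead.
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @param exact Use the exact permutation p-value (n <= 8 only).
#' @return List with `rho` and `p_value`.
#' @export
spearman_rank_corr <- function(a, b, exact = FALSE) {
  n <- length(a)
  if (n != length(b)) stop("a and b must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector")
  ra <- rank(a); rb <- rank(b)
  rho <- stats::cor(ra, rb)
  if (exact) {
    if (n > 8L) stop("exact permutation p-value supported only for n <= 8")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(ra[p], rb))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' @keywords internal
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.integer(block)
    r <- r + nrow(sub)
  }
  out
}
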