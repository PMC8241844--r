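#' Hyperparameters for epsilon-SVR with an RBF kernel
#'
#' Defaults follow common SVR-LSM practice: box constraint `C = 30`,
#' `epsilon = 0.1`, and an RBF width chosen by the median-pairwise-distance
#' heuristic when `gamma` is `NULL`. Search bounds are on the natural scale
#' but explored in log10 space by [optimize_hyperparameters()].
#'
#' @param C Positive box constraint, or `NULL` (default) to use the
#'   Cherkassky--Ma heuristic `C = max|mean(y) +/- 3 sd(y)|` at fit time,
#'   which scales the regularization to the response. The constant `C = 30`
#'   used by the published MATLAB toolbox is kept as the reference triple of
#'   the hyperparameter search.
#' @param gamma Positive RBF width in `k(a, b) = exp(-gamma * ||a - b||^2)`,
#'   or `NULL` to use the median heuristic at fit time.
#' @param epsilon Nonnegative width of the insensitive tube.
#' @param search_bounds Named list of `c(lo, hi)` per parameter.
#' @param cv_folds Cross-validation folds for the hyperparameter search
#'   (default 20).
#' @param n_iterations Number of candidate evaluations in the search
#'   (default 200).
#' @return An object of class `svr_hyperparams`.
#' @export
svr_hyperparams <- function(C = NULL, gamma = NULL, epsilon = 0.1,
                            search_bounds = list(C = c(1e-3, 1e3),
                                                 gamma = c(1e-4, 1e1),
                                                 epsilon = c(1e-3, 1e1)),
                            cv_folds = 20L, n_iterations = 200L) {
  stopifnot(is.null(C) || C > 0, is.null(gamma) || gamma > 0, epsilon >= 0,
            cv_folds >= 2L, n_iterations >= 1L)
  for (nm in c("C", "gamma", "epsilon")) {
    b <- search_bounds[[nm]]
    if (is.null(b) || length(b) != 2L || b[1L] <= 0 || b[1L] >= b[2L])
      stop("search_bounds$", nm, " must be positive with lo < hi")
  }
  structure(list(C = C, gamma = gamma, epsilon = epsilon,
                 search_bounds = search_bounds,
                 cv_folds = as.integer(cv_folds),
                 n_iterations = as.integer(n_iterations)),
            class = "svr_hyperparams")
}

#' Median-distance heuristic for the RBF width
#'
#' `gamma = 1 / median(||x_i - x_j||^2)` over distinct row pairs: scale-free
#' and a standard default when the width is not tuned.
#'
#' @param X Subject-by-feature matrix.
#' @return Positive scalar.
#' @export
gamma_median_heuristic <- function(X) {
  d2 <- squared_distances(X)
  m <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(m) || m <= 0) 1 else 1 / m
}

#' Cherkassky--Ma heuristic for the box constraint
#'
#' `C = max(|mean(y) + 3 sd(y)|, |mean(y) - 3 sd(y)|)`: the standard
#' data-dependent prescription scaling the SVR regularization to the response
#' range, so that the fit cannot chase individual observations.
#'
#' @param y Response vector.
#' @return Positive scalar.
#' @export
c_heuristic <- function(y) {
  m <- mean(y); s <- stats::sd(y)
  out <- max(abs(m + 3 * s), abs(m - 3 * s))
  if (!is.finite(out) || out <= 0) 1 else out
}

#' @keywords internal
squared_distances <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

#' RBF kernel matrix
#' @param X,Y Row-wise sample matrices (`Y = NULL` for the symmetric case).
#' @param gamma Positive RBF width.
#' @return Kernel matrix `exp(-gamma * ||x - y||^2)`.
#' @export
rbf_kernel <- function(X, Y = NULL, gamma) exp(-gamma * squared_distances(X, Y))

# Core solver on a precomputed kernel: kernlab's SMO on the epsilon-SVR dual.
# Returns the full-length signed dual coefficient vector (alpha - alpha*),
# support indices and intercept, with the convention
#   f(x) = sum_i dual[i] * k(x, x_i) + intercept.
# A response that fits inside one epsilon tube has the all-zero dual with the
# midrange as intercept (the solver is bypassed; no support vectors).
#' @keywords internal
fit_svr_kernel <- function(K, y, C, epsilon, tol = 1e-3) {
  n <- length(y)
  if (diff(range(y)) <= 2 * epsilon) {
    return(list(dual_coef = numeric(n), support = integer(0L),
                intercept = (max(y) + min(y)) / 2))
  }
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                     C = C, epsilon = epsilon, tol = tol, scaled = FALSE)
  dual <- numeric(n)
  dual[kernlab::alphaindex(m)] <- unlist(kernlab::coef(m))
  list(dual_coef = dual, support = sort(kernlab::alphaindex(m)),
       intercept = -kernlab::b(m))
}

#' Fit epsilon-SVR on residualized lesion data
#'
#' Solves the standard epsilon-insensitive SVR dual with RBF kernel
#' `k(a, b) = exp(-gamma * ||a - b||^2)`. No feature scaling is applied
#' beyond the upstream residualization.
#'
#' @param X Subject-by-voxel matrix (residualized lesion data).
#' @param y Behavior vector (residualized), same length as `nrow(X)`.
#' @param params An [svr_hyperparams()]; a `NULL` `gamma` is resolved by
#'   [gamma_median_heuristic()].
#' @param tol Solver termination tolerance.
#' @return An object of class `svr_model` with fields `dual_coef`
#'   (full-length signed coefficients), `support`, `intercept`, `params`
#'   (gamma resolved), `X` (training matrix) and `fingerprint`.
#' @export
fit_svr <- function(X, y, params = svr_hyperparams(), tol = 1e-3) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("inputs must be finite")
  gamma <- if (is.null(params$gamma)) gamma_median_heuristic(X)
           else params$gamma
  if (is.null(params$C)) params$C <- c_heuristic(y)
  K <- rbf_kernel(X, gamma = gamma)
  fit <- fit_svr_kernel(K, y, params$C, params$epsilon, tol = tol)
  params$gamma <- gamma
  structure(list(dual_coef = fit$dual_coef, support = fit$support,
                 intercept = fit$intercept, params = params, X = X,
                 fingerprint = data_fingerprint(X, y)),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> ", length(x$support), "/", nrow(x$X),
      " support vectors; C=", x$params$C,
      " gamma=", signif(x$params$gamma, 4),
      " epsilon=", x$params$epsilon, "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted SVR model
#' @param object An [fit_svr()] result.
#' @param newdata Matrix of rows to predict (default: training rows).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @method predict svr_model
#' @export
predict.svr_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  sv <- object$support
  if (length(sv) == 0L) return(rep(object$intercept, nrow(newdata)))
  K <- rbf_kernel(as.matrix(newdata), object$X[sv, , drop = FALSE],
                  gamma = object$params$gamma)
  drop(K %*% object$dual_coef[sv]) + object$intercept
}

# Cheap content fingerprint used to detect beta back-projection against the
# wrong matrix; not a cryptographic hash.
#' @keywords internal
data_fingerprint <- function(X, y) {
  sprintf("%dx%d|%.12e|%.12e|%.12e", nrow(X), ncol(X),
          sum(X), sum(X * seq_along(X)), sum(y * seq_along(y)))
}

#' Back-project the SVR dual solution into a voxelwise feature-weight map
#'
#' The feature weight (beta) of voxel j is the dual-weighted sum of the
#' support vectors' values at j: `beta_j = sum_i dual_i * X[i, j]`. Positive
#' beta means lesion status at that voxel pushes the predicted score up
#' (worse outcome).
#'
#' @param model An [fit_svr()] result.
#' @param X The training matrix (checked against the model's fingerprint).
#' @param mask The [build_analysis_mask()] whose columns `X` follows.
#' @return An object of class `beta_map` with fields `beta` (one weight per
#'   mask voxel), `mask` and `sign_convention`.
#' @export
compute_beta_map <- function(model, X, mask) {
  fp <- data_fingerprint(as.matrix(X), 0)
  if (!identical(strsplit(fp, "|", fixed = TRUE)[[1L]][1:3],
                 strsplit(model$fingerprint, "|", fixed = TRUE)[[1L]][1:3]))
    stop("X is not the matrix this model was trained on")
  if (ncol(X) != length(mask$column_index))
    stop("X columns do not match the analysis mask")
  beta <- drop(crossprod(as.matrix(X), model$dual_coef))
  if (!all(is.finite(beta))) stop("non-finite feature weights")
  structure(list(beta = beta, mask = mask,
                 sign_convention = "positive = lesion associated with higher score"),
            class = "beta_map")
}

#' @export
print.beta_map <- function(x, ...) {
  cat("<beta_map> ", length(x$beta), " voxels; range ",
      paste(signif(range(x$beta), 4), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Deterministic stratified cross-validation folds
#'
#' Subjects are sorted by the response and, within consecutive blocks of `k`,
#' fold labels are randomly permuted under a seed-derived stream, so each fold
#' spans the response range and the split is reproducible.
#'
#' @param y Response vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in `1..k`.
#' @export
cv_folds_stratified <- function(y, k, seed = 1L) {
  n <- length(y)
  if (k > n) stop("more folds than subjects")
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ord <- order(y, seq_len(n))
  folds <- integer(n)
  pos <- 1L
  while (pos <= n) {
    block <- ord[pos:min(pos + k - 1L, n)]
    folds[block] <- sample(seq_len(k), length(block))
    pos <- pos + k
  }
  folds
}

# Mean CV loss of an (C, gamma, epsilon) triple given the full squared
# distance matrix (so each gamma costs one exp()). objective "mse" is the
# mean squared error of the held-out predictions; "cor" is 1 - Pearson
# correlation between held-out predictions and y.
#' @keywords internal
cv_loss <- function(D2, y, C, gamma, epsilon, folds,
                    objective = "mse", tol = 1e-3) {
  K <- exp(-gamma * D2)
  pred <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    fit <- fit_svr_kernel(K[tr, tr, drop = FALSE], y[tr], C, epsilon,
                          tol = tol)
    pred[te] <- if (length(fit$support) == 0L) fit$intercept else
      drop(K[te, tr[fit$support], drop = FALSE] %*%
             fit$dual_coef[fit$support]) + fit$intercept
  }
  if (objective == "mse") mean((y - pred)^2)
  else if (stats::sd(pred) == 0) 1
  else 1 - stats::cor(pred, y)
}

#' Cross-validated hyperparameter search
#'
#' Searches (C, gamma, epsilon) in log10 space within the configured bounds
#' for the triple minimizing the mean cross-validated loss. The search is a
#' seeded space-filling design (Latin hypercube) followed by local refinement
#' in shrinking boxes around the incumbent; the default triple (`C = 30`,
#' median-heuristic `gamma`, `epsilon = 0.1`, clamped into the bounds) is
#' always evaluated first, so the selected triple is never worse than the
#' default under the search's own objective. Reproducible: the same
#' `(X, y, seed)` select the same triple.
#'
#' @param X,y Residualized lesion matrix and behavior vector.
#' @param spec An [svr_hyperparams()] providing bounds, folds and the
#'   iteration budget.
#' @param seed Integer seed for fold assignment and candidate sampling.
#' @param objective `"mse"` (default) or `"cor"`.
#' @param tol Solver tolerance used during the search.
#' @return An [svr_hyperparams()] with the selected `C`, `gamma`, `epsilon`
#'   and attributes `cv_error` (at the selection) and `cv_error_default`.
#' @export
optimize_hyperparameters <- function(X, y, spec = svr_hyperparams(),
                                     seed = 1L, objective = c("mse", "cor"),
                                     tol = 1e-3) {
  objective <- match.arg(objective)
  X <- as.matrix(X)
  if (stats::sd(y) == 0)
    stop("cannot optimize hyperparameters: y has zero variance")
  if (nrow(X) < spec$cv_folds)
    stop("need at least cv_folds subjects")
  D2 <- squared_distances(X)
  folds <- cv_folds_stratified(y, spec$cv_folds, seed = seed)
  bounds <- spec$search_bounds
  lo <- log10(c(bounds$C[1L], bounds$gamma[1L], bounds$epsilon[1L]))
  hi <- log10(c(bounds$C[2L], bounds$gamma[2L], bounds$epsilon[2L]))
  clamp <- function(p) pmin(pmax(p, lo), hi)
  default <- clamp(log10(c(30, gamma_median_heuristic(X), 0.1)))
  evals <- list()
  eval_point <- function(p) {
    cv_loss(D2, y, C = 10^p[1L], gamma = 10^p[2L], epsilon = 10^p[3L],
            folds = folds, objective = objective, tol = tol)
  }
  budget <- spec$n_iterations
  pts <- matrix(default, nrow = 1L)
  n_global <- max(0L, min(budget - 1L, as.integer(ceiling(0.6 * budget))))
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed + 1L)
  if (n_global > 0L) {
    u <- lhs::randomLHS(n_global, 3L)
    pts <- rbind(pts, sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`))
  }
  losses <- apply(pts, 1L, eval_point)
  used <- nrow(pts)
  width <- (hi - lo) / 4
  while (used < budget) {
    m <- min(8L, budget - used)
    best <- pts[which.min(losses), ]
    u <- lhs::randomLHS(m, 3L)
    cand <- sweep(sweep(u, 2L, 2 * width, `*`), 2L, best - width, `+`)
    cand <- t(apply(cand, 1L, clamp))
    pts <- rbind(pts, cand)
    losses <- c(losses, apply(cand, 1L, eval_point))
    used <- used + m
    width <- width * 0.6
  }
  sel <- pts[which.min(losses), ]
  out <- spec
  out$C <- 10^sel[1L]
  out$gamma <- 10^sel[2L]
  out$epsilon <- 10^sel[3L]
  attr(out, "cv_error") <- min(losses)
  attr(out, "cv_error_default") <- losses[1L]
  out
}
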