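#' Permutation scheme for voxel and cluster inference
#'
#' Defaults reproduce the standard SVR-LSM settings: 10,000 permutations,
#' voxelwise threshold p < 0.005, cluster-extent FWE threshold p < 0.05,
#' exploratory reporting of clusters larger than 50 voxels, 26-connectivity.
#'
#' @param n_permutations Number of random permutations of the behavior
#'   vector (default 10000).
#' @param voxel_alpha Voxelwise significance level (default 0.005).
#' @param cluster_alpha Cluster-extent FWE level (default 0.05).
#' @param min_report_voxels Report clusters with more voxels than this
#'   (default 50, strict).
#' @param connectivity 6, 18 or 26 (default 26, vertex-adjacent).
#' @param seed Integer seed governing all permutations.
#' @return An object of class `permutation_scheme`.
#' @export
permutation_scheme <- function(n_permutations = 10000L, voxel_alpha = 0.005,
                               cluster_alpha = 0.05, min_report_voxels = 50L,
                               connectivity = 26L, seed = 1L) {
  stopifnot(n_permutations >= 1L, voxel_alpha > 0, voxel_alpha < 1,
            cluster_alpha > 0, cluster_alpha < 1, min_report_voxels >= 1L)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (n_permutations < 1 / voxel_alpha)
    warning("n_permutations < 1/voxel_alpha: the attainable p floor ",
            "1/(B+1) is coarse relative to the voxel threshold")
  structure(list(n_permutations = as.integer(n_permutations),
                 voxel_alpha = voxel_alpha, cluster_alpha = cluster_alpha,
                 min_report_voxels = as.integer(min_report_voxels),
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "permutation_scheme")
}

#' Label connected components of a 3D logical array
#'
#' Components are labeled by decreasing voxel count; ties are broken by the
#' smallest linear voxel index contained in the component.
#'
#' @param arr 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(arr, connectivity = 26L) {
  lab <- .label_components_cpp(as.logical(arr), dim(arr),
                               as.integer(connectivity))
  if (max(lab) > 1L) {
    size <- tabulate(lab)
    first <- integer(max(lab))
    nz <- which(lab > 0L)
    first[lab[nz[length(nz):1L]]] <- nz[length(nz):1L]  # min index per label
    ord <- order(-size, first)
    relab <- integer(max(lab))
    relab[ord] <- seq_along(ord)
    lab[nz] <- relab[lab[nz]]
  }
  array(lab, dim = dim(arr))
}

# Significance rule shared by the observed and permuted maps. p-values use
# the add-one estimator p = (1 + #{null >= value}) / (B + 1), so the floor is
# 1/(B+1); significance is p <= voxel_alpha. The inclusive comparison is
# deliberate: at the reference setting (B = 10000, alpha = 0.005) it selects
# exactly the same voxels as a strict comparison, while keeping the rule
# attainable at the reduced permutation counts used for validation, where a
# strict rule would be unattainable whenever B + 1 <= 1/alpha.
#' @keywords internal
sig_count_bound <- function(B, alpha) floor(alpha * (B + 1) + 1e-9) - 1L

#' Permutation test of the SVR feature-weight map
#'
#' For each permutation the behavior vector is randomly permuted, the SVR is
#' refit at the fixed hyperparameters (the kernel depends only on the lesion
#' data, so it is computed once), and the permuted feature-weight map is
#' back-projected. Voxel p-values are one-sided toward positive weights
#' (lesion associated with higher, i.e. worse, score):
#' `p_j = (1 + #\{b : beta_j^(b) >= beta_j\}) / (B + 1)`. For the cluster-extent
#' null, every permuted map is thresholded at its own permutation rank under
#' the same rule and the maximum suprathreshold cluster size per permutation
#' is recorded, giving an exchangeable max-statistic null.
#'
#' Permutation b draws from its own seed-derived substream, so results are
#' identical regardless of execution order or worker count.
#'
#' @param X Residualized subject-by-voxel matrix.
#' @param y_resid Residualized behavior vector.
#' @param params An [svr_hyperparams()] with fixed values (a `NULL` gamma is
#'   resolved once on the observed data).
#' @param scheme A [permutation_scheme()].
#' @param mask The [build_analysis_mask()] whose columns `X` follows.
#' @param two_sided If `TRUE`, use |beta| on both sides of the comparison.
#' @param tol Solver tolerance.
#' @return List with `beta_map` (observed), `pmap` (class `voxel_pmap`:
#'   fields `p`, `direction`, `n_permutations`), `null_max_sizes` (length B)
#'   and `sig_voxels` (logical per mask voxel, observed significance).
#' @export
permutation_test <- function(X, y_resid, params, scheme, mask,
                             two_sided = FALSE, tol = 1e-3) {
  B <- scheme$n_permutations
  if (B < 19L)
    stop("fewer than 19 permutations cannot support any conventional alpha")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (p != length(mask$column_index))
    stop("X columns do not match the analysis mask")
  gamma <- if (is.null(params$gamma)) gamma_median_heuristic(X)
           else params$gamma
  params$gamma <- gamma
  if (is.null(params$C)) params$C <- c_heuristic(y_resid)
  K <- rbf_kernel(X, gamma = gamma)
  obs_fit <- fit_svr_kernel(K, y_resid, params$C, params$epsilon, tol = tol)
  beta_obs <- drop(crossprod(X, obs_fit$dual_coef))
  if (!all(is.finite(beta_obs))) stop("non-finite feature weights")
  stat <- function(b) if (two_sided) abs(b) else b
  perm_seeds <- derive_seeds(scheme$seed, B)
  perm_stats <- matrix(0, nrow = B, ncol = p)
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  for (b in seq_len(B)) {
    set.seed(perm_seeds[b])
    yp <- y_resid[sample.int(n)]
    fit <- fit_svr_kernel(K, yp, params$C, params$epsilon, tol = tol)
    perm_stats[b, ] <- stat(drop(crossprod(X, fit$dual_coef)))
  }
  obs_stat <- stat(beta_obs)
  exceed <- colSums(perm_stats >= rep(obs_stat, each = B))
  pvals <- (1 + exceed) / (B + 1)
  bound <- sig_count_bound(B, scheme$voxel_alpha)
  sig_obs <- exceed <= bound
  # Permuted maps are thresholded at their own rank within the pooled set of
  # B+1 maps (observed + permuted), self excluded -- the same rule the
  # observed map faces, so all B+1 maps are exchangeable under the null.
  null_max <- integer(B)
  if (bound >= 0L) {
    pooled <- rbind(obs_stat, perm_stats)
    ge_counts <- apply(pooled, 2L, function(v)
      length(v) - rank(v, ties.method = "min"))  # #{others >= v} per map
    for (b in seq_len(B)) {
      sig_b <- ge_counts[b + 1L, ] <= bound
      null_max[b] <- max_cluster_size(sig_b, mask, scheme$connectivity)
    }
  }
  pmap <- structure(list(p = pvals,
                         direction = if (two_sided) "two-sided"
                                     else "one-sided toward worse outcome",
                         n_permutations = B, mask = mask),
                    class = "voxel_pmap")
  obs_model <- structure(list(dual_coef = obs_fit$dual_coef,
                              support = obs_fit$support,
                              intercept = obs_fit$intercept,
                              params = params, X = X,
                              fingerprint = data_fingerprint(X, y_resid)),
                         class = "svr_model")
  list(beta_map = compute_beta_map(obs_model, X, mask), model = obs_model,
       pmap = pmap, null_max_sizes = null_max, sig_voxels = sig_obs)
}

#' @keywords internal
max_cluster_size <- function(sig, mask, connectivity) {
  if (!any(sig)) return(0L)
  arr <- array(FALSE, dim = mask$geometry$shape)
  arr[mask$column_index[sig]] <- TRUE
  lab <- .label_components_cpp(as.logical(arr), dim(arr),
                               as.integer(connectivity))
  max(tabulate(lab))
}

#' Threshold a voxel p-map and form clusters
#'
#' Voxels significant at `scheme$voxel_alpha` (inclusive rule; see
#' [permutation_test()]) are partitioned into connected components under the
#' configured connectivity, labeled by decreasing size with ties broken by
#' the smallest linear voxel index.
#'
#' @param pmap A `voxel_pmap` from [permutation_test()].
#' @param mask The matching [build_analysis_mask()].
#' @param scheme A [permutation_scheme()].
#' @return An object of class `cluster_set`: fields `labels` (3D integer
#'   array), `clusters` (data frame with `id`, `voxel_count`, `peak_voxel`),
#'   `connectivity`. An empty set (no significant voxels) is allowed.
#' @export
threshold_and_cluster <- function(pmap, mask, scheme) {
  if (length(pmap$p) != length(mask$column_index))
    stop("p-map does not match the analysis mask")
  B <- pmap$n_permutations
  sig <- pmap$p * (B + 1) - 1 <= sig_count_bound(B, scheme$voxel_alpha) + 1e-9
  arr <- array(FALSE, dim = mask$geometry$shape)
  arr[mask$column_index[sig]] <- TRUE
  labels <- label_components(arr, scheme$connectivity)
  k <- max(labels)
  if (k == 0L) {
    clusters <- data.frame(id = integer(0L), voxel_count = integer(0L),
                           peak_voxel = integer(0L))
  } else {
    size <- tabulate(labels, nbins = k)
    peak <- integer(k)
    for (cl in seq_len(k)) {
      vox <- which(labels == cl)
      in_mask <- match(vox, mask$column_index)
      peak[cl] <- vox[order(pmap$p[in_mask], vox)[1L]]
    }
    clusters <- data.frame(id = seq_len(k), voxel_count = size,
                           peak_voxel = peak)
  }
  structure(list(labels = labels, clusters = clusters,
                 connectivity = scheme$connectivity,
                 geometry = mask$geometry),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> ", nrow(x$clusters), " cluster(s)",
      if (nrow(x$clusters)) paste0("; sizes ",
        paste(x$clusters$voxel_count, collapse = ", ")), "\n", sep = "")
  invisible(x)
}

#' Assign cluster-extent FWE-corrected p-values
#'
#' For each observed cluster,
#' `fwe_p = (1 + #\{b : null max size_b >= cluster size\}) / (B + 1)` against
#' the permutation distribution of the maximum suprathreshold cluster size.
#'
#' @param clusters A [threshold_and_cluster()] result.
#' @param null_max_sizes Per-permutation maximum null cluster sizes from
#'   [permutation_test()].
#' @return The `cluster_set` with columns `fwe_p` added and
#'   `null_max_sizes` attached.
#' @export
cluster_fwe <- function(clusters, null_max_sizes) {
  if (length(null_max_sizes) == 0L)
    stop("empty null distribution of max cluster sizes")
  B <- length(null_max_sizes)
  clusters$clusters$fwe_p <- vapply(
    clusters$clusters$voxel_count,
    function(s) (1 + sum(null_max_sizes >= s)) / (B + 1), numeric(1L))
  clusters$null_max_sizes <- null_max_sizes
  clusters
}

#' Cluster report table
#'
#' Rows for clusters with more than `scheme$min_report_voxels` voxels, sorted
#' by increasing FWE-corrected p-value, with center of mass mapped through
#' the grid affine to world mm (one decimal) and an FWE significance flag at
#' `scheme$cluster_alpha` (strict).
#'
#' @param clusters A [cluster_fwe()] result.
#' @param geom The [grid_geometry()] of the analysis.
#' @param scheme A [permutation_scheme()].
#' @return Data frame with columns `cluster`, `voxel_count`, `fwe_p`,
#'   `center_x_mm`, `center_y_mm`, `center_z_mm`, `fwe_significant`.
#' @export
cluster_report <- function(clusters, geom, scheme) {
  tab <- clusters$clusters
  if (is.null(tab$fwe_p)) stop("clusters carry no fwe_p; run cluster_fwe()")
  keep <- tab$voxel_count > scheme$min_report_voxels
  tab <- tab[keep, , drop = FALSE]
  centers <- matrix(numeric(0L), 0L, 3L)
  if (nrow(tab)) {
    centers <- t(vapply(tab$id, function(cl) {
      vox <- which(clusters$labels == cl, arr.ind = TRUE)
      colMeans(voxel_to_world(vox, geom))
    }, numeric(3L)))
  }
  out <- data.frame(cluster = tab$id, voxel_count = tab$voxel_count,
                    fwe_p = tab$fwe_p,
                    center_x_mm = round(centers[, 1L], 1L),
                    center_y_mm = round(centers[, 2L], 1L),
                    center_z_mm = round(centers[, 3L], 1L),
                    fwe_significant = tab$fwe_p < scheme$cluster_alpha)
  out <- out[order(out$fwe_p, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
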