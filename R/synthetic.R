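#' Configuration for the synthetic lesion-cohort generator
#'
#' The generator emulates the statistical structure of an acute-stroke
#' lesion-mapping cohort: right-skewed lesion volumes (lognormal voxel counts
#' whose defaults reproduce a median of 3.3 ml with IQR 1.1--16.9 ml at 2 mm
#' isotropic voxels), spatially biased lesion placement concentrated in one
#' hemisphere (mimicking middle-cerebral-artery territory strokes), an ordinal
#' outcome score on 0--10 (an EQ-5D-3L sum where higher is worse), a positive
#' score--volume association, and a compact ground-truth "critical region"
#' whose damage raises the score.
#'
#' The observed score is `round-half-up(clip(latent))` with
#' `latent = intercept + effect_size * damage_fraction +
#' volume_effect * z(log volume) + N(0, noise_sd)`, where `damage_fraction`
#' is the lesioned fraction of the critical region and `z(log volume)` the
#' cohort-standardized log lesion volume.
#'
#' @param n_subjects Number of subjects (default 329).
#' @param grid_shape Integer triple (default 32^3).
#' @param voxel_size_mm Positive triple of voxel edge lengths (default 2 mm).
#' @param volume_lognormal_params `c(meanlog, sdlog)` of lesioned-voxel
#'   counts. Defaults hit a 3.3 ml median and 1.1--16.9 ml IQR.
#' @param placement_bias_center Voxel coordinates of the lesion-seed Gaussian
#'   (default one hemisphere of the grid).
#' @param placement_bias_sd Per-axis SD (voxels) of the seed Gaussian.
#' @param critical_region Integer vector of linear voxel indices; default a
#'   3.5-voxel-radius sphere near the placement center. May be empty only if
#'   `effect_size == 0`.
#' @param intercept Latent score intercept (default 0.8, putting the median
#'   observed score near 1).
#' @param effect_size Score increase for full critical-region destruction.
#' @param volume_effect Score increase per SD of log lesion volume.
#' @param noise_sd SD of the latent Gaussian noise.
#' @param score_range Integer pair, observed score bounds (default 0--10).
#' @param max_lesion_fraction Cap on a single lesion's share of the grid.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 329L,
                              grid_shape = c(32L, 32L, 32L),
                              voxel_size_mm = c(2, 2, 2),
                              volume_lognormal_params = NULL,
                              placement_bias_center = NULL,
                              placement_bias_sd = c(4, 5, 5),
                              critical_region = NULL,
                              intercept = 0.8,
                              effect_size = 4,
                              volume_effect = 1.2,
                              noise_sd = 1.5,
                              score_range = c(0L, 10L),
                              max_lesion_fraction = 0.25,
                              seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            n_subjects >= 1L, effect_size >= 0, volume_effect >= 0,
            noise_sd >= 0, max_lesion_fraction > 0, max_lesion_fraction <= 1)
  score_range <- as.integer(score_range)
  if (length(score_range) != 2L || score_range[1L] >= score_range[2L])
    stop("score_range must be an increasing integer pair")
  voxel_ml <- prod(voxel_size_mm) / 1000
  if (is.null(volume_lognormal_params)) {
    # median 3.3 ml, IQR 1.1--16.9 ml in voxel counts
    volume_lognormal_params <- c(log(3.3 / voxel_ml),
                                 log(16.9 / 1.1) / (2 * stats::qnorm(0.75)))
  }
  if (is.null(placement_bias_center))
    placement_bias_center <- grid_shape * c(0.35, 0.5, 0.45)
  geom <- grid_geometry(grid_shape,
                        rbind(cbind(diag(voxel_size_mm),
                                    -voxel_size_mm * grid_shape / 2),
                              c(0, 0, 0, 1)))
  if (is.null(critical_region))
    critical_region <- sphere_region(grid_shape,
                                     placement_bias_center + c(1, 1, 2), 3.5)
  critical_region <- as.integer(critical_region)
  if (length(critical_region) &&
      (min(critical_region) < 1L || max(critical_region) > prod(grid_shape)))
    stop("critical_region indices fall outside the grid")
  if (length(critical_region) == 0L && effect_size > 0)
    stop("critical_region may not be empty while effect_size > 0")
  structure(list(n_subjects = as.integer(n_subjects), grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm, geometry = geom,
                 volume_lognormal_params = volume_lognormal_params,
                 placement_bias_center = placement_bias_center,
                 placement_bias_sd = placement_bias_sd,
                 critical_region = critical_region, intercept = intercept,
                 effect_size = effect_size, volume_effect = volume_effect,
                 noise_sd = noise_sd, score_range = score_range,
                 max_lesion_fraction = max_lesion_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Linear voxel indices of a spherical region
#'
#' @param grid_shape Integer triple.
#' @param center Voxel coordinates (1-based, may be fractional).
#' @param radius Radius in voxels.
#' @return Integer vector of column-major linear indices.
#' @export
sphere_region <- function(grid_shape, center, radius) {
  ijk <- as.matrix(expand.grid(i = seq_len(grid_shape[1L]),
                               j = seq_len(grid_shape[2L]),
                               k = seq_len(grid_shape[3L])))
  d2 <- rowSums(sweep(ijk, 2L, center)^2)
  which(d2 <= radius^2)
}

# Stable per-subject substreams: subject k's seed is the k-th draw from the
# master stream, so subject k is reproducible independent of n_subjects.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
save_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

#' @keywords internal
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Draw one subject's lesion: voxel count from the lognormal, seed voxel from
# the truncated placement Gaussian, then random-walk region growing (compact,
# connected). Runs inside the subject's own RNG substream.
#' @keywords internal
draw_lesion <- function(config) {
  shp <- config$grid_shape
  p <- config$volume_lognormal_params
  count <- round_half_up(stats::rlnorm(1L, p[1L], p[2L]))
  count <- max(1L, min(as.integer(count),
                       as.integer(config$max_lesion_fraction * prod(shp))))
  repeat {
    ctr <- round_half_up(stats::rnorm(3L, config$placement_bias_center,
                                      config$placement_bias_sd))
    if (all(ctr >= 1) && all(ctr <= shp)) break
  }
  start <- as.integer(ctr[1L] + (ctr[2L] - 1L) * shp[1L] +
                        (ctr[3L] - 1L) * shp[1L] * shp[2L])
  idx <- .grow_lesion_cpp(shp, start, count)
  arr <- array(0, dim = shp)
  arr[idx] <- 1
  arr
}

#' Generate a synthetic lesion cohort with ground truth
#'
#' See [simulation_config()] for the generative model. Identical seeds give
#' bit-identical cohorts; subject k's lesion does not depend on `n_subjects`.
#' A modified-Rankin-style covariate `mrs` (ordinal 0--6, correlated with the
#' behavior score through the shared latent) is attached as a covariate.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (a [lesion_cohort()]) and `truth` (list with
#'   `critical_region_mask` 3D logical, `damage_fraction`, `latent_scores`).
#' @export
generate_cohort <- function(config) {
  n <- config$n_subjects
  seeds <- derive_seeds(config$seed, n + 2L)
  lesions <- vector("list", n)
  noise <- numeric(n)
  mrs_noise <- numeric(n)
  for (k in seq_len(n)) {
    old <- save_rng_state()
    set.seed(seeds[k])
    lesions[[k]] <- draw_lesion(config)
    noise[k] <- stats::rnorm(1L, 0, config$noise_sd)
    mrs_noise[k] <- stats::rnorm(1L, 0, 0.8)
    restore_rng_state(old)
  }
  region <- config$critical_region
  damage <- if (length(region) == 0L) rep(0, n) else
    vapply(lesions, function(L) sum(L[region]) / length(region), numeric(1L))
  counts <- vapply(lesions, sum, numeric(1L))
  logv <- log(counts)
  zlogv <- if (stats::sd(logv) > 0) (logv - mean(logv)) / stats::sd(logv)
           else rep(0, n)
  latent <- config$intercept + config$effect_size * damage +
    config$volume_effect * zlogv + noise
  observed <- pmin(pmax(round_half_up(latent), config$score_range[1L]),
                   config$score_range[2L])
  mrs <- pmin(pmax(round_half_up(2 + 0.7 * (latent - config$intercept) +
                                   mrs_noise), 0), 6)
  cohort <- lesion_cohort(lesions, observed, config$geometry,
                          covariates = data.frame(mrs = mrs))
  truth <- list(
    critical_region_mask = {
      m <- array(FALSE, dim = config$grid_shape); m[region] <- TRUE; m
    },
    damage_fraction = damage,
    latent_scores = latent)
  list(cohort = cohort, truth = truth)
}

#' Generate a null cohort (scores independent of lesions)
#'
#' Lesions are generated exactly as in [generate_cohort()] (same per-subject
#' substreams), then the observed score vector is randomly permuted across
#' subjects, severing any lesion--score association while preserving the
#' score's marginal distribution.
#'
#' @param config A [simulation_config()].
#' @return A [lesion_cohort()].
#' @export
generate_null_cohort <- function(config) {
  g <- generate_cohort(config)
  seeds <- derive_seeds(config$seed, config$n_subjects + 2L)
  old <- save_rng_state()
  set.seed(seeds[config$n_subjects + 1L])
  perm <- sample.int(config$n_subjects)
  restore_rng_state(old)
  cohort <- g$cohort
  cohort$behavior <- cohort$behavior[perm]
  cohort
}

#' Calibrate the latent noise SD to a target signal strength
#'
#' Returns the `noise_sd` making the latent model's R-squared (share of latent
#' variance explained by the damage and volume terms) equal `r2`, estimated
#' from a pilot cohort of `n_pilot` subjects generated under `config`.
#'
#' @param config A [simulation_config()].
#' @param r2 Target latent R-squared in (0, 1).
#' @param n_pilot Pilot sample size for estimating the signal variance.
#' @return Noise SD (scalar).
#' @export
noise_sd_for_r2 <- function(config, r2, n_pilot = 1000L) {
  stopifnot(r2 > 0, r2 < 1)
  pilot <- config
  pilot$n_subjects <- as.integer(n_pilot)
  pilot$noise_sd <- 0
  g <- generate_cohort(pilot)
  signal <- config$effect_size * g$truth$damage_fraction
  counts <- vapply(g$cohort$lesions, sum, numeric(1L))
  zlogv <- scale(log(counts))[, 1L]
  signal <- signal + config$volume_effect * zlogv
  stats::sd(signal) * sqrt((1 - r2) / r2)
}

#' Calibrate the critical-region effect size to a target signal strength
#'
#' Returns the `effect_size` making the damage term's share of the latent
#' variance equal `r2`, i.e. `var(e * damage) / var(latent) = r2`, holding
#' the config's `volume_effect` and `noise_sd` fixed. Because damage fraction
#' and log volume are positively correlated by construction (larger lesions
#' damage more of any fixed region), the quadratic in `e` includes their
#' covariance; moments are estimated from a pilot cohort.
#'
#' @param config A [simulation_config()].
#' @param r2 Target share of latent variance for the damage term, in (0, 1).
#' @param n_pilot Pilot sample size for estimating the damage/volume moments.
#' @return Effect size (scalar).
#' @export
effect_size_for_r2 <- function(config, r2, n_pilot = 1000L) {
  stopifnot(r2 > 0, r2 < 1)
  pilot <- config
  pilot$n_subjects <- as.integer(n_pilot)
  pilot$noise_sd <- 0
  pilot$effect_size <- 0
  g <- generate_cohort(pilot)
  d <- g$truth$damage_fraction
  z <- scale(log(vapply(g$cohort$lesions, sum, numeric(1L))))[, 1L]
  A <- stats::var(d)
  if (A == 0) stop("damage fraction has zero variance under this config")
  v <- config$volume_effect
  cv <- stats::cov(d, z)
  rest <- v^2 * stats::var(z) + config$noise_sd^2
  disc <- (2 * r2 * v * cv)^2 + 4 * A * (1 - r2) * r2 * rest
  (2 * r2 * v * cv + sqrt(disc)) / (2 * A * (1 - r2))
}

#' Generate a toy probabilistic tract atlas
#'
#' Each tract is a tube around a polyline: the tract-membership probability at
#' a voxel is `peak_prob * exp(-d^2 / (2 * radius_mm^2))` where `d` is the
#' distance (mm) from the voxel center to the centerline. Stands in for a
#' population tractography atlas in tests and demonstrations.
#'
#' @param geom A [grid_geometry()].
#' @param tract_specs List of specs, each a list with `name`, `centerline`
#'   (matrix of 1-based voxel coordinates, one row per vertex), `radius_mm`,
#'   and `peak_prob` in `[0, 1]`.
#' @return A [tract_atlas()].
#' @export
generate_toy_tract_atlas <- function(geom, tract_specs) {
  grid <- as.matrix(expand.grid(i = seq_len(geom$shape[1L]),
                                j = seq_len(geom$shape[2L]),
                                k = seq_len(geom$shape[3L])))
  world <- voxel_to_world(grid, geom)
  maps <- list()
  for (sp in tract_specs) {
    if (sp$peak_prob < 0 || sp$peak_prob > 1)
      stop("peak_prob must lie in [0, 1]")
    cl <- sp$centerline
    if (is.null(dim(cl))) cl <- matrix(cl, nrow = 1L)
    if (any(cl < 1) || any(sweep(cl, 2L, geom$shape) > 0))
      stop("centerline of tract '", sp$name, "' leaves the grid")
    clw <- voxel_to_world(cl, geom)
    d2 <- rep(Inf, nrow(world))
    if (nrow(clw) == 1L) {
      d2 <- rowSums(sweep(world, 2L, clw[1L, ])^2)
    } else {
      for (s in seq_len(nrow(clw) - 1L)) {
        a <- clw[s, ]; b <- clw[s + 1L, ]
        ab <- b - a
        len2 <- sum(ab^2)
        t <- if (len2 == 0) rep(0, nrow(world)) else
          pmin(pmax(sweep(world, 2L, a) %*% ab / len2, 0), 1)
        proj <- sweep(t %*% t(ab), 2L, a, `+`)
        d2 <- pmin(d2, rowSums((world - proj)^2))
      }
    }
    maps[[sp$name]] <- array(sp$peak_prob * exp(-d2 / (2 * sp$radius_mm^2)),
                             dim = geom$shape)
  }
  tract_atlas(maps, geom, source_label = "synthetic toy atlas")
}

#' Write a cohort (and optional ground truth) to disk
#'
#' Produces one NIfTI mask per subject plus a `behavior.csv` in the format
#' [load_cohort()] reads, so generated data round-trips through the standard
#' input path. Ground truth is saved as a NIfTI mask plus CSV.
#'
#' @param cohort A [lesion_cohort()].
#' @param dir Output directory (created if needed).
#' @param truth Optional truth list from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$subjects))
    write_volume(cohort$lesions[[i]], cohort$geometry,
                 file.path(dir, paste0(cohort$subjects[i], ".nii.gz")))
  tab <- data.frame(subject_id = cohort$subjects, score = cohort$behavior)
  if (!is.null(cohort$covariates)) tab <- cbind(tab, cohort$covariates)
  utils::write.csv(tab, file.path(dir, "behavior.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    write_volume(truth$critical_region_mask, cohort$geometry,
                 file.path(dir, "truth_critical_region.nii.gz"))
    utils::write.csv(
      data.frame(subject_id = cohort$subjects,
                 damage_fraction = truth$damage_fraction,
                 latent_score = truth$latent_scores),
      file.path(dir, "truth_subjects.csv"), row.names = FALSE)
  }
  invisible(dir)
}
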