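#' Full analysis configuration
#'
#' All defaults equal the reference SVR-LSM settings: minimum lesion overlap
#' 10, voxelwise p < 0.005, cluster-extent FWE p < 0.05 over 10,000
#' permutations, exploratory reporting of clusters > 50 voxels, and a tract
#' intersection certainty threshold of 90%.
#'
#' @param masks Character vector of NIfTI paths or a single glob pattern.
#' @param behavior Path to the behavior table (CSV/TSV, columns
#'   `subject_id`, `score`).
#' @param output_dir Run directory for all artifacts.
#' @param atlas_manifest Optional tract-atlas manifest CSV.
#' @param min_overlap Minimum overlapping lesions per analysis voxel.
#' @param nuisance List: `method` ("regression", "dtlvc", "none") and
#'   `log_volume` flag.
#' @param svr List of SVR settings: `C`, `gamma` (NULL = median heuristic),
#'   `epsilon`, `cv_folds`, `n_iterations`, `optimize` (logical).
#' @param permutation List of permutation settings: `n_permutations`,
#'   `voxel_alpha`, `cluster_alpha`, `min_report_voxels`, `connectivity`.
#' @param tract_threshold Tract certainty pass threshold (strict >).
#' @param seed Integer seed for every random element of the run.
#' @param log_level "info" or "quiet".
#' @return An object of class `run_config`.
#' @export
run_config <- function(masks = NULL, behavior = NULL, output_dir = "lesionmap_run",
                       atlas_manifest = NULL, min_overlap = 10L,
                       nuisance = list(), svr = list(), permutation = list(),
                       tract_threshold = 0.90, seed = 1L,
                       log_level = "info") {
  nuisance <- utils::modifyList(list(method = "regression",
                                     log_volume = FALSE), nuisance)
  svr <- utils::modifyList(list(C = NULL, gamma = NULL, epsilon = 0.1,
                                cv_folds = 20L, n_iterations = 200L,
                                optimize = TRUE), svr)
  permutation <- utils::modifyList(list(n_permutations = 10000L,
                                        voxel_alpha = 0.005,
                                        cluster_alpha = 0.05,
                                        min_report_voxels = 50L,
                                        connectivity = 26L), permutation)
  structure(list(masks = masks, behavior = behavior, output_dir = output_dir,
                 atlas_manifest = atlas_manifest,
                 min_overlap = as.integer(min_overlap), nuisance = nuisance,
                 svr = svr, permutation = permutation,
                 tract_threshold = tract_threshold, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys mirror the arguments of [run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @keywords internal
log_msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(format(Sys.time(), "%H:%M:%S"), " [lesionmap] ", ...)
  invisible(NULL)
}

#' @keywords internal
resolve_mask_paths <- function(config) {
  masks <- config$masks
  if (is.null(masks)) stop("config gives no lesion mask paths")
  if (length(masks) == 1L && grepl("[*?]", masks))
    masks <- Sys.glob(masks)
  if (length(masks) == 0L) stop("mask glob matched no files")
  sort(masks)
}

#' @keywords internal
require_upstream <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' needs missing upstream file: ", path)
  path
}

#' @keywords internal
scheme_from_config <- function(config) {
  p <- config$permutation
  permutation_scheme(n_permutations = p$n_permutations,
                     voxel_alpha = p$voxel_alpha,
                     cluster_alpha = p$cluster_alpha,
                     min_report_voxels = p$min_report_voxels,
                     connectivity = p$connectivity, seed = config$seed)
}

#' @keywords internal
hyperparams_from_config <- function(config) {
  s <- config$svr
  svr_hyperparams(C = s$C, gamma = s$gamma, epsilon = s$epsilon,
                  cv_folds = s$cv_folds, n_iterations = s$n_iterations)
}

# Shared preprocessing: load -> overlap mask -> exclusions -> flatten ->
# nuisance control. Returns everything later stages need in memory.
#' @keywords internal
prepare_inputs <- function(config) {
  cohort <- load_cohort(resolve_mask_paths(config), config$behavior)
  mask <- build_analysis_mask(cohort, config$min_overlap)
  excl <- exclude_nonoverlapping_subjects(cohort, mask)
  X <- flatten_cohort(excl$cohort, mask)
  nc <- nuisance_control(X, excl$cohort$behavior, excl$cohort$volumes_ml,
                         method = config$nuisance$method,
                         lesion_sizes = round(excl$cohort$volumes_ml /
                           cohort$geometry$voxel_volume_ml),
                         log_volume = isTRUE(config$nuisance$log_volume))
  list(cohort = excl$cohort, excluded = excl$excluded, mask = mask,
       X = X, nc = nc)
}

#' Run the full SVR-LSM pipeline
#'
#' Executes load, minimum-overlap masking, subject exclusion, flattening,
#' nuisance control, hyperparameter selection, SVR fit and beta
#' back-projection, permutation inference, cluster FWE correction and
#' reporting, and (if an atlas is configured) tract intersection certainty.
#' Every intermediate is written into the run directory; a `manifest.json`
#' records the package version, the full configuration, the seed and input
#' checksums. Reruns with the same configuration and seed reproduce all
#' numeric outputs byte-identically.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the run directory and the in-memory results
#'   (`cluster_table`, `tract_report`, `beta_map`, `params`, `excluded`).
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  t0 <- Sys.time()
  log_msg(config, "loading cohort")
  prep <- prepare_inputs(config)
  geom <- prep$cohort$geometry
  write_volume(prep$mask$overlap, geom, out("overlap_count.nii.gz"))
  write_volume(prep$mask$mask, geom, out("analysis_mask.nii.gz"))
  utils::write.csv(data.frame(subject_id = prep$excluded),
                   out("excluded_subjects.csv"), row.names = FALSE)
  log_msg(config, length(prep$cohort$subjects), " subjects, ",
          length(prep$mask$column_index), " analysis voxels, ",
          length(prep$excluded), " excluded")

  utils::write.csv(data.frame(subject_id = prep$cohort$subjects,
                              volume_ml = prep$cohort$volumes_ml,
                              score = prep$cohort$behavior,
                              score_residual = prep$nc$y_resid),
                   out("residualized_behavior.csv"), row.names = FALSE)

  params <- hyperparams_from_config(config)
  if (isTRUE(config$svr$optimize)) {
    log_msg(config, "hyperparameter search (", params$n_iterations,
            " iterations, ", params$cv_folds, "-fold CV)")
    params <- optimize_hyperparameters(prep$nc$X_resid, prep$nc$y_resid,
                                       spec = params, seed = config$seed)
  }
  jsonlite::write_json(
    list(C = params$C, gamma = params$gamma, epsilon = params$epsilon,
         cv_error = attr(params, "cv_error"),
         cv_error_default = attr(params, "cv_error_default")),
    out("hyperparams.json"), auto_unbox = TRUE, digits = NA, null = "null")

  scheme <- scheme_from_config(config)
  log_msg(config, "permutation inference (B = ", scheme$n_permutations, ")")
  perm <- permutation_test(prep$nc$X_resid, prep$nc$y_resid, params, scheme,
                           prep$mask)
  write_volume(unflatten_to_volume(perm$beta_map$beta, prep$mask), geom,
               out("beta_map.nii.gz"))
  write_volume(unflatten_to_volume(perm$pmap$p, prep$mask, fill = 1), geom,
               out("voxel_p.nii.gz"))
  utils::write.csv(data.frame(permutation = seq_along(perm$null_max_sizes),
                              max_cluster_size = perm$null_max_sizes),
                   out("null_max_sizes.csv"), row.names = FALSE)

  clusters <- threshold_and_cluster(perm$pmap, prep$mask, scheme)
  clusters <- cluster_fwe(clusters, perm$null_max_sizes)
  write_volume(clusters$labels, geom, out("cluster_labels.nii.gz"))
  report <- cluster_report(clusters, geom, scheme)
  utils::write.csv(report, out("clusters.csv"), row.names = FALSE)
  log_msg(config, nrow(report), " reportable cluster(s); ",
          sum(report$fwe_significant), " FWE-significant")

  tract_report <- NULL
  if (!is.null(config$atlas_manifest) &&
      any(clusters$clusters$voxel_count > scheme$min_report_voxels)) {
    atlas <- load_tract_atlas(config$atlas_manifest, geom)
    tract_report <- build_certainty_report(
      clusters, atlas, threshold = config$tract_threshold,
      cluster_filter = scheme$min_report_voxels)
    utils::write.csv(as.data.frame(tract_report), out("tracts.csv"),
                     row.names = FALSE)
  }

  writeLines(format_summary(report, tract_report, scheme), out("summary.txt"))
  manifest <- list(
    package = "lesionmap",
    version = as.character(utils::packageVersion("lesionmap")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(c(resolve_mask_paths(config),
                                        config$behavior))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_msg(config, "run complete: ", config$output_dir)
  invisible(list(run_dir = config$output_dir, cluster_table = report,
                 tract_report = tract_report, beta_map = perm$beta_map,
                 params = params, excluded = prep$excluded,
                 clusters = clusters))
}

#' @keywords internal
format_summary <- function(report, tract_report, scheme) {
  lines <- c("SVR-LSM cluster report",
             sprintf("(voxel p <= %.3g, cluster FWE alpha %.2g, clusters > %d voxels)",
                     scheme$voxel_alpha, scheme$cluster_alpha,
                     scheme$min_report_voxels), "")
  if (nrow(report) == 0L) {
    lines <- c(lines, "No cluster exceeded the reporting size.")
  } else {
    lines <- c(lines,
               sprintf("%-8s %-10s %-10s %-24s %s", "cluster", "voxels",
                       "FWE p", "center (mm)", "significant"),
               sprintf("%-8d %-10d %-10.4f %-24s %s", report$cluster,
                       report$voxel_count, report$fwe_p,
                       paste0(report$center_x_mm, "; ", report$center_y_mm,
                              "; ", report$center_z_mm),
                       ifelse(report$fwe_significant, "yes *", "no")))
  }
  if (!is.null(tract_report)) {
    pass <- tract_report[tract_report$passing, , drop = FALSE]
    lines <- c(lines, "", sprintf(
      "Tracts intersecting the cluster union with certainty > %d%%:",
      round(100 * attr(tract_report, "threshold"))),
      if (nrow(pass) == 0L) "  none" else
        sprintf("  %-40s %3d%%", pass$tract, pass$percent))
  }
  lines
}

# ---- file-driven stage subcommands ----------------------------------------

#' Run one pipeline stage against a run directory
#'
#' Stages consume the files their upstream stages wrote into
#' `config$output_dir` and write their own outputs there, allowing the
#' analysis to be advanced or redone step by step. `run_full_pipeline()` is
#' the single-shot equivalent.
#'
#' @param stage One of `"mask"`, `"map"`, `"permute"`, `"clusters"`,
#'   `"tracts"`, `"report"`.
#' @param config A [run_config()].
#' @return Invisibly, the stage's main result.
#' @export
run_stage <- function(stage = c("mask", "map", "permute", "clusters",
                                "tracts", "report"), config) {
  stage <- match.arg(stage)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         mask = stage_mask(config),
         map = stage_map(config),
         permute = stage_permute(config),
         clusters = stage_clusters(config),
         tracts = stage_tracts(config),
         report = stage_report(config))
}

#' @keywords internal
stage_mask <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  cohort <- load_cohort(resolve_mask_paths(config), config$behavior)
  mask <- build_analysis_mask(cohort, config$min_overlap)
  excl <- exclude_nonoverlapping_subjects(cohort, mask)
  write_volume(mask$overlap, cohort$geometry, out("overlap_count.nii.gz"))
  write_volume(mask$mask, cohort$geometry, out("analysis_mask.nii.gz"))
  utils::write.csv(data.frame(subject_id = excl$excluded),
                   out("excluded_subjects.csv"), row.names = FALSE)
  invisible(mask)
}

#' @keywords internal
stage_map <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  require_upstream(out("analysis_mask.nii.gz"), "map")
  prep <- prepare_inputs(config)
  params <- hyperparams_from_config(config)
  if (isTRUE(config$svr$optimize))
    params <- optimize_hyperparameters(prep$nc$X_resid, prep$nc$y_resid,
                                       spec = params, seed = config$seed)
  model <- fit_svr(prep$nc$X_resid, prep$nc$y_resid, params)
  bmap <- compute_beta_map(model, prep$nc$X_resid, prep$mask)
  jsonlite::write_json(
    list(C = model$params$C, gamma = model$params$gamma,
         epsilon = model$params$epsilon),
    out("hyperparams.json"), auto_unbox = TRUE, digits = NA, null = "null")
  write_volume(unflatten_to_volume(bmap$beta, prep$mask),
               prep$cohort$geometry, out("beta_map.nii.gz"))
  invisible(bmap)
}

#' @keywords internal
stage_permute <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  hp_path <- require_upstream(out("hyperparams.json"), "permute")
  hp <- jsonlite::read_json(hp_path)
  prep <- prepare_inputs(config)
  params <- svr_hyperparams(C = hp$C, gamma = hp$gamma, epsilon = hp$epsilon)
  scheme <- scheme_from_config(config)
  perm <- permutation_test(prep$nc$X_resid, prep$nc$y_resid, params, scheme,
                           prep$mask)
  write_volume(unflatten_to_volume(perm$pmap$p, prep$mask, fill = 1),
               prep$cohort$geometry, out("voxel_p.nii.gz"))
  write_volume(unflatten_to_volume(perm$beta_map$beta, prep$mask),
               prep$cohort$geometry, out("beta_map.nii.gz"))
  utils::write.csv(data.frame(permutation = seq_along(perm$null_max_sizes),
                              max_cluster_size = perm$null_max_sizes),
                   out("null_max_sizes.csv"), row.names = FALSE)
  invisible(perm)
}

#' @keywords internal
stage_clusters <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  p_path <- require_upstream(out("voxel_p.nii.gz"), "clusters")
  nmax_path <- require_upstream(out("null_max_sizes.csv"), "clusters")
  mask_path <- require_upstream(out("analysis_mask.nii.gz"), "clusters")
  mask_img <- RNifti::readNifti(mask_path)
  geom <- grid_geometry_from_nifti(mask_img)
  mask <- structure(list(mask = array(mask_img > 0.5, dim = geom$shape),
                         min_overlap = config$min_overlap,
                         column_index = which(array(mask_img > 0.5,
                                                    dim = geom$shape)),
                         geometry = geom),
                    class = "analysis_mask")
  p_arr <- array(as.numeric(RNifti::readNifti(p_path)), dim = geom$shape)
  scheme <- scheme_from_config(config)
  pmap <- structure(list(p = p_arr[mask$column_index],
                         direction = "one-sided toward worse outcome",
                         n_permutations = scheme$n_permutations,
                         mask = mask),
                    class = "voxel_pmap")
  null_max <- utils::read.csv(nmax_path)$max_cluster_size
  clusters <- cluster_fwe(threshold_and_cluster(pmap, mask, scheme), null_max)
  write_volume(clusters$labels, geom, out("cluster_labels.nii.gz"))
  report <- cluster_report(clusters, geom, scheme)
  utils::write.csv(report, out("clusters.csv"), row.names = FALSE)
  invisible(clusters)
}

#' @keywords internal
stage_tracts <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  lab_path <- require_upstream(out("cluster_labels.nii.gz"), "tracts")
  require_upstream(out("clusters.csv"), "tracts")
  if (is.null(config$atlas_manifest))
    stop("stage 'tracts' needs config$atlas_manifest")
  lab_img <- RNifti::readNifti(lab_path)
  geom <- grid_geometry_from_nifti(lab_img)
  labels <- array(as.integer(round(lab_img)), dim = geom$shape)
  k <- max(labels)
  clusters <- structure(
    list(labels = labels,
         clusters = data.frame(id = seq_len(k),
                               voxel_count = tabulate(labels, nbins = k)),
         geometry = geom),
    class = "cluster_set")
  atlas <- load_tract_atlas(config$atlas_manifest, geom)
  rep <- build_certainty_report(clusters, atlas,
                                threshold = config$tract_threshold,
                                cluster_filter = config$permutation$min_report_voxels)
  utils::write.csv(as.data.frame(rep), out("tracts.csv"), row.names = FALSE)
  invisible(rep)
}

#' @keywords internal
stage_report <- function(config) {
  out <- function(f) file.path(config$output_dir, f)
  cl_path <- require_upstream(out("clusters.csv"), "report")
  report <- utils::read.csv(cl_path)
  tract_report <- NULL
  if (file.exists(out("tracts.csv"))) {
    tract_report <- utils::read.csv(out("tracts.csv"))
    attr(tract_report, "threshold") <- config$tract_threshold
  }
  scheme <- scheme_from_config(config)
  lines <- format_summary(report, tract_report, scheme)
  writeLines(lines, out("summary.txt"))
  invisible(lines)
}
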