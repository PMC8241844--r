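#' Assemble a lesion cohort from in-memory arrays
#'
#' A lesion cohort bundles per-subject binary lesion volumes registered to a
#' common grid with a behavioral score per subject (here: an EQ-5D-style sum
#' score where higher means worse self-reported quality of life) and optional
#' covariates such as the modified Rankin Scale.
#'
#' @param lesions List of 3D arrays (one per subject) with values in {0, 1}.
#' @param behavior Numeric vector of scores, one per subject.
#' @param geometry A [grid_geometry()] shared by all volumes.
#' @param subjects Character vector of subject ids (default `s001`, ...).
#' @param covariates Optional data frame of per-subject covariates.
#' @return An object of class `lesion_cohort` with fields `subjects`,
#'   `lesions`, `behavior`, `covariates`, `volumes_ml` and `geometry`.
#' @export
lesion_cohort <- function(lesions, behavior, geometry, subjects = NULL,
                          covariates = NULL) {
  n <- length(lesions)
  if (n == 0L) stop("empty cohort")
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(n))
  subjects <- as.character(subjects)
  behavior <- as.numeric(behavior)
  if (length(subjects) != n || length(behavior) != n)
    stop("subjects, lesions and behavior must have equal length")
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  if (!all(is.finite(behavior))) stop("behavior scores must be finite")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
  }
  for (i in seq_len(n)) {
    L <- lesions[[i]]
    if (!all(dim(L) == geometry$shape))
      stop(sprintf("lesion %s does not match the cohort grid", subjects[i]))
    check_binary(L, subjects[i])
    if (sum(L) < 1)
      stop(sprintf("subject %s has an empty lesion", subjects[i]))
  }
  volumes <- vapply(lesions, compute_volume_ml, numeric(1L), geom = geometry)
  structure(list(subjects = subjects, lesions = lesions, behavior = behavior,
                 covariates = covariates, volumes_ml = volumes,
                 geometry = geometry),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("<lesion_cohort> ", length(x$subjects), " subjects on ",
      paste(x$geometry$shape, collapse = "x"),
      " grid; median volume ", signif(stats::median(x$volumes_ml), 3),
      " ml\n", sep = "")
  invisible(x)
}

# Binarity rule for registered masks: interpolation dust in [0, 1] is snapped
# to the nearest level; values outside [0, 1] (beyond 1e-6) are rejected.
#' @keywords internal
check_binary <- function(arr, label = "volume", tol = 1e-6) {
  v <- range(arr)
  if (v[1L] < -tol || v[2L] > 1 + tol)
    stop(sprintf("%s has values outside [0, 1] (range %.4g..%.4g)",
                 label, v[1L], v[2L]))
  invisible(TRUE)
}

#' @keywords internal
binarize <- function(arr) {
  storage.mode(arr) <- "double"
  arr[] <- as.numeric(arr >= 0.5)
  arr
}

#' Load a cohort from NIfTI lesion masks and a behavior table
#'
#' Masks are matched to table rows by subject id; the id of a mask is its file
#' name stripped of `.nii`/`.nii.gz`. Subject order follows the table. All
#' masks must share shape and affine (affines compared element-wise within
#' `affine_tol` mm); voxel values must be binary up to interpolation dust
#' (values in `[0, 0.5)` map to 0, `[0.5, 1]` to 1, anything outside
#' `[0, 1] + 1e-6` is rejected).
#'
#' @param mask_paths Character vector of NIfTI file paths, one per subject.
#' @param behavior_table Path to a CSV/TSV file with a header containing
#'   columns `subject_id` and `score`; any further columns are kept as
#'   covariates.
#' @param affine_tol Element-wise affine agreement tolerance in mm.
#' @return A [lesion_cohort()].
#' @export
load_cohort <- function(mask_paths, behavior_table, affine_tol = 1e-4) {
  if (length(mask_paths) == 0L) stop("no mask paths given")
  ids <- sub("\\.nii(\\.gz)?$", "", basename(mask_paths))
  tab <- read_behavior_table(behavior_table)
  missing_masks <- setdiff(tab$subject_id, ids)
  missing_rows <- setdiff(ids, tab$subject_id)
  if (length(missing_masks) || length(missing_rows))
    stop("subject id mismatch between masks and behavior table; ",
         if (length(missing_masks))
           paste0("no mask for: ", paste(missing_masks, collapse = ", "), "; "),
         if (length(missing_rows))
           paste0("no table row for: ", paste(missing_rows, collapse = ", ")))
  ord <- match(tab$subject_id, ids)
  geom <- NULL
  lesions <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    path <- mask_paths[ord[r]]
    img <- RNifti::readNifti(path)
    g <- grid_geometry_from_nifti(img)
    if (is.null(geom)) geom <- g
    else if (!same_geometry(geom, g, tol = affine_tol))
      stop(sprintf(
        "geometry mismatch: %s has shape %s / differing affine (first mask: %s)",
        basename(path), paste(g$shape, collapse = "x"),
        paste(geom$shape, collapse = "x")))
    arr <- array(as.numeric(img), dim = g$shape)
    check_binary(arr, basename(path))
    lesions[[r]] <- binarize(arr)
  }
  cov <- tab[, setdiff(names(tab), c("subject_id", "score")), drop = FALSE]
  if (ncol(cov) == 0L) cov <- NULL
  lesion_cohort(lesions, tab$score, geom, subjects = tab$subject_id,
                covariates = cov)
}

#' @keywords internal
read_behavior_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(tab)))
    stop("behavior table must have columns 'subject_id' and 'score'")
  tab$subject_id <- as.character(tab$subject_id)
  tab
}

#' Lesion volume in milliliters
#'
#' Volume of a binary lesion map: number of lesioned voxels times the voxel
#' volume derived from the grid affine.
#'
#' @param lesion 3D array with values in {0, 1}.
#' @param geom A [grid_geometry()].
#' @return Volume in ml (0 for an empty lesion).
#' @examples
#' geom <- grid_geometry(c(10, 10, 10), diag(c(2, 2, 2, 1)))
#' les <- array(0, c(10, 10, 10)); les[1:5, 1:5, 1:5] <- 1
#' compute_volume_ml(les, geom)  # 125 voxels x 0.008 ml = 1 ml
#' @export
compute_volume_ml <- function(lesion, geom) {
  check_binary(lesion, "lesion")
  if (any(lesion != 0 & lesion != 1))
    stop("lesion must be strictly binary; binarize first")
  sum(lesion) * geom$voxel_volume_ml
}

#' Minimum-overlap analysis mask
#'
#' Restricts the analysis to voxels lesioned in at least `min_overlap`
#' subjects, the standard stabilization rule in lesion-symptom mapping. The
#' returned object carries the voxel-to-column map used to flatten the cohort
#' into a subject-by-voxel matrix: columns enumerate mask voxels in R's native
#' column-major array order (first axis fastest), which is fixed and
#' documented so that flattening is reproducible.
#'
#' @param cohort A [lesion_cohort()].
#' @param min_overlap Minimum number of overlapping lesions per voxel
#'   (default 10).
#' @return An object of class `analysis_mask` with fields `mask` (3D logical),
#'   `overlap` (3D integer lesion counts), `min_overlap`, `column_index`
#'   (linear indices of mask voxels, column-major) and `geometry`.
#' @export
build_analysis_mask <- function(cohort, min_overlap = 10L) {
  min_overlap <- as.integer(min_overlap)
  n <- length(cohort$subjects)
  if (min_overlap < 1L || min_overlap > n)
    stop("min_overlap must be between 1 and the number of subjects")
  overlap <- Reduce(`+`, cohort$lesions)
  mask <- overlap >= min_overlap
  if (!any(mask))
    stop("analysis mask is empty: no voxel reaches ", min_overlap,
         " overlapping lesions; lower min_overlap")
  structure(list(mask = mask, overlap = overlap, min_overlap = min_overlap,
                 column_index = which(mask), geometry = cohort$geometry),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat("<analysis_mask> ", length(x$column_index), " voxels at min_overlap=",
      x$min_overlap, "\n", sep = "")
  invisible(x)
}

#' Drop subjects whose lesion misses the analysis mask
#'
#' Subjects with no lesioned voxel inside the minimum-overlap mask carry no
#' information for the multivariate fit and are excluded, mirroring the usual
#' SVR-LSM preprocessing.
#'
#' @param cohort A [lesion_cohort()].
#' @param mask An [build_analysis_mask()] result on the same grid.
#' @return List with `cohort` (filtered) and `excluded` (character vector of
#'   dropped subject ids, possibly empty).
#' @export
exclude_nonoverlapping_subjects <- function(cohort, mask) {
  if (!same_geometry(cohort$geometry, mask$geometry))
    stop("mask geometry does not match cohort")
  keep <- vapply(cohort$lesions,
                 function(L) any(L[mask$column_index] > 0), logical(1L))
  excluded <- cohort$subjects[!keep]
  if (!any(keep))
    stop("all subjects excluded: no lesion overlaps the analysis mask")
  out <- cohort
  out$subjects <- cohort$subjects[keep]
  out$lesions <- cohort$lesions[keep]
  out$behavior <- cohort$behavior[keep]
  out$volumes_ml <- cohort$volumes_ml[keep]
  if (!is.null(cohort$covariates))
    out$covariates <- cohort$covariates[keep, , drop = FALSE]
  list(cohort = out, excluded = excluded)
}

#' Flatten a cohort to a subject-by-voxel matrix
#'
#' Row i holds subject i's lesion status at the mask voxels, in the column
#' order fixed by `mask$column_index`.
#'
#' @param cohort A [lesion_cohort()] (typically after
#'   [exclude_nonoverlapping_subjects()]).
#' @param mask An [build_analysis_mask()] result.
#' @return Numeric matrix (subjects x mask voxels) with entries in {0, 1} and
#'   subject ids as row names.
#' @export
flatten_cohort <- function(cohort, mask) {
  X <- t(vapply(cohort$lesions, function(L) as.numeric(L[mask$column_index]),
                numeric(length(mask$column_index))))
  rownames(X) <- cohort$subjects
  X
}

#' Expand per-mask-voxel values back into a 3D volume
#'
#' Inverse of the voxel-to-column map: values land at `mask$column_index`,
#' everything outside the mask is `fill`.
#'
#' @param values Numeric vector, one value per mask voxel.
#' @param mask An [build_analysis_mask()] result.
#' @param fill Value outside the mask (default 0).
#' @return 3D numeric array on the mask's grid.
#' @export
unflatten_to_volume <- function(values, mask, fill = 0) {
  if (length(values) != length(mask$column_index))
    stop("values length does not match mask voxel count")
  arr <- array(fill, dim = mask$geometry$shape)
  arr[mask$column_index] <- values
  arr
}
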