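#' Grid geometry of a registered lesion dataset
#'
#' Describes the common voxel grid all cohort volumes must share: the array
#' shape, the 4x4 voxel-index-to-world-millimeter affine (NIfTI convention,
#' zero-based voxel indices), and the derived voxel volume in milliliters.
#'
#' @param shape Integer triple, voxels per axis.
#' @param affine 4x4 numeric matrix mapping zero-based voxel indices (i, j, k)
#'   to world millimeters; last row must be (0, 0, 0, 1).
#' @return An object of class `grid_geometry` with elements `shape`, `affine`
#'   and `voxel_volume_ml`.
#' @examples
#' geom <- grid_geometry(c(32, 32, 32), diag(c(2, 2, 2, 1)))
#' geom$voxel_volume_ml  # 0.008 ml per 2 mm isotropic voxel
#' @export
grid_geometry <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be a positive integer triple")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  if (max(abs(affine[4L, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("affine last row must be (0, 0, 0, 1)")
  d <- det(affine[1:3, 1:3])
  if (abs(d) < .Machine$double.eps * 100)
    stop("affine is singular")
  structure(list(shape = shape, affine = affine,
                 voxel_volume_ml = abs(d) / 1000),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("<grid_geometry> ", paste(x$shape, collapse = " x "),
      " voxels, ", signif(x$voxel_volume_ml, 4), " ml/voxel\n", sep = "")
  invisible(x)
}

#' @rdname grid_geometry
#' @param image An `RNifti` image (or path readable by [RNifti::readNifti()]).
#' @export
grid_geometry_from_nifti <- function(image) {
  if (is.character(image)) image <- RNifti::readNifti(image)
  x <- RNifti::xform(image)
  grid_geometry(dim(image)[1:3], unclass(x)[1:4, 1:4])
}

#' Map voxel indices to world millimeters
#'
#' @param ijk Numeric matrix (n x 3) or length-3 vector of one-based voxel
#'   indices (R array convention); may be fractional (e.g. a center of mass).
#' @param geom A [grid_geometry()].
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, geom) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1L)
  stopifnot(ncol(ijk) == 3L)
  # affine acts on zero-based indices
  w <- (ijk - 1) %*% t(geom$affine[1:3, 1:3])
  sweep(w, 2L, geom$affine[1:3, 4L], `+`)
}

#' @keywords internal
same_geometry <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

# Write a volume on a grid_geometry as NIfTI (sform carries the affine).
#' Write a 3D array on a grid as a NIfTI file
#'
#' @param arr 3D numeric/logical array matching `geom$shape`.
#' @param geom A [grid_geometry()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, geom, path) {
  if (!all(dim(arr) == geom$shape))
    stop("array dimensions do not match geometry")
  img <- RNifti::asNifti(array(as.numeric(arr), dim = geom$shape))
  img <- RNifti::`sform<-`(img, structure(geom$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
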