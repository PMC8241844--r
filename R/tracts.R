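#' Probabilistic white-matter tract atlas
#'
#' A named set of probability volumes (values in `[0, 1]`) on the analysis
#' grid, e.g. population tractography maps. Maps delivered on a 0--100 scale
#' are rescaled to 0--1 with a warning, since both conventions circulate.
#'
#' @param maps Named list of 3D arrays.
#' @param geometry The [grid_geometry()] the maps live on.
#' @param source_label Free-text provenance label.
#' @return An object of class `tract_atlas`.
#' @export
tract_atlas <- function(maps, geometry, source_label = "") {
  if (length(maps) == 0L || is.null(names(maps)) || any(names(maps) == ""))
    stop("maps must be a non-empty named list")
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!all(dim(m) == geometry$shape))
      stop("tract map '", nm, "' does not match the grid")
    mx <- max(m)
    if (min(m) < -1e-6) stop("tract map '", nm, "' has negative values")
    if (mx > 1 + 1e-6) {
      if (mx <= 100 + 1e-6) {
        warning("tract map '", nm, "' looks 0-100 scaled; rescaling to 0-1")
        maps[[nm]] <- m / 100
      } else stop("tract map '", nm, "' has values above 100")
    }
  }
  structure(list(tracts = maps, geometry = geometry,
                 source_label = source_label),
            class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat("<tract_atlas> ", length(x$tracts), " tract(s): ",
      paste(utils::head(names(x$tracts), 5L), collapse = ", "),
      if (length(x$tracts) > 5L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Load a tract atlas from a manifest CSV
#'
#' The manifest must have columns `name` and `file` (NIfTI paths, relative to
#' the manifest's directory unless absolute); an optional `hemisphere` column
#' is appended to the tract name as `" (L)"` / `" (R)"`.
#'
#' @param manifest_csv Path to the manifest.
#' @param geometry Expected [grid_geometry()]; volumes are checked against it.
#' @return A [tract_atlas()].
#' @export
load_tract_atlas <- function(manifest_csv, geometry) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  if (!all(c("name", "file") %in% names(man)))
    stop("atlas manifest needs columns 'name' and 'file'")
  base <- dirname(manifest_csv)
  maps <- list()
  for (r in seq_len(nrow(man))) {
    path <- man$file[r]
    if (!file.exists(path)) path <- file.path(base, man$file[r])
    if (!file.exists(path)) stop("atlas volume not found: ", man$file[r])
    img <- RNifti::readNifti(path)
    g <- grid_geometry_from_nifti(img)
    if (!same_geometry(geometry, g))
      stop("atlas volume ", man$file[r], " is not on the analysis grid")
    nm <- man$name[r]
    if ("hemisphere" %in% names(man) && nzchar(man$hemisphere[r]))
      nm <- paste0(nm, " (", man$hemisphere[r], ")")
    maps[[nm]] <- array(as.numeric(img), dim = g$shape)
  }
  tract_atlas(maps, geometry, source_label = manifest_csv)
}

#' Certainty that a tract intersects the cluster union
#'
#' The certainty that a probabilistic tract intersects a set of significant
#' voxels is the maximum tract-membership probability over the voxels of the
#' set: if any cluster voxel belongs to the tract with probability q, the
#' tract crosses the cluster with certainty at least q.
#'
#' @param cluster_union 3D logical array (nonempty union of clusters).
#' @param tract_map 3D probability array on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
tract_certainty <- function(cluster_union, tract_map) {
  if (length(dim(cluster_union)) != length(dim(tract_map)) ||
      !all(dim(cluster_union) == dim(tract_map)))
    stop("geometry mismatch between cluster union and tract map")
  idx <- which(cluster_union != 0)
  if (length(idx) == 0L) stop("empty cluster union")
  max(tract_map[idx])
}

#' Tract-intersection certainty report
#'
#' Forms the union of clusters exceeding `cluster_filter` voxels, computes
#' the intersection certainty for every atlas tract, and flags tracts whose
#' certainty strictly exceeds `threshold` (default 0.90). Certainties are
#' also given as integer percentages for reporting.
#'
#' @param clusters A [threshold_and_cluster()] / [cluster_fwe()] result.
#' @param atlas A [tract_atlas()] on the same grid.
#' @param threshold Passing threshold on the certainty (strict >).
#' @param cluster_filter Minimum cluster size (strict >) to enter the union.
#' @return An object of class `tract_certainty_report`: a data frame with
#'   columns `tract`, `certainty`, `percent`, `passing` sorted by decreasing
#'   certainty, plus attributes `threshold` and `union_voxels`.
#' @export
build_certainty_report <- function(clusters, atlas, threshold = 0.90,
                                   cluster_filter = 50L) {
  if (!same_geometry(clusters$geometry, atlas$geometry))
    stop("atlas is not on the analysis grid")
  ids <- clusters$clusters$id[clusters$clusters$voxel_count > cluster_filter]
  if (length(ids) == 0L)
    stop("no cluster exceeds ", cluster_filter,
         " voxels; the cluster union is empty")
  union <- array(clusters$labels %in% ids, dim = dim(clusters$labels))
  cert <- vapply(atlas$tracts, function(m) tract_certainty(union, m),
                 numeric(1L))
  out <- data.frame(tract = names(cert), certainty = unname(cert),
                    percent = round_half_up(100 * unname(cert)),
                    passing = unname(cert) > threshold)
  out <- out[order(-out$certainty, out$tract), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "union_voxels") <- sum(union)
  class(out) <- c("tract_certainty_report", "data.frame")
  out
}
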