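#' Dataset geometry
#'
#' Describes the bounding box and imaging grid of a volume-EM dataset. All
#' stored coordinates in this package are in nanometres; derived lengths,
#' areas and volumes are reported in micrometres (or powers thereof), with
#' conversion applied at computation time only.
#'
#' @param bbox_min_nm,bbox_max_nm Numeric 3-vectors, the dataset bounding box
#'   corners in nm. `bbox_min_nm` must be componentwise smaller than
#'   `bbox_max_nm`.
#' @param voxel_size_nm Numeric 3-vector, the voxel edge lengths in nm.
#'   Defaults to the 10 x 10 nm lateral resolution and 25 nm cutting
#'   thickness of serial block-face EM.
#' @param boundary_margin_um Margin in micrometres used to flag dendrites as
#'   potentially clipped by the dataset boundary (default 7).
#'
#' @return An object of class `dataset_geometry`.
#' @examples
#' geom <- dataset_geometry(c(0, 0, 0), c(256000, 256000, 384000))
#' voxel_volume_um3(geom)
#' @export
dataset_geometry <- function(bbox_min_nm = c(0, 0, 0),
                             bbox_max_nm = c(256000, 256000, 384000),
                             voxel_size_nm = c(10, 10, 25),
                             boundary_margin_um = 7) {
  bbox_min_nm <- as.numeric(bbox_min_nm)
  bbox_max_nm <- as.numeric(bbox_max_nm)
  voxel_size_nm <- as.numeric(voxel_size_nm)
  stopifnot(length(bbox_min_nm) == 3, length(bbox_max_nm) == 3,
            length(voxel_size_nm) == 3)
  if (!all(bbox_min_nm < bbox_max_nm)) {
    abort("`bbox_min_nm` must be componentwise smaller than `bbox_max_nm`.")
  }
  if (!all(voxel_size_nm > 0)) {
    abort("All voxel edge lengths must be positive.")
  }
  if (boundary_margin_um < 0) {
    abort("`boundary_margin_um` must be non-negative.")
  }
  structure(
    list(bbox_min_nm = bbox_min_nm, bbox_max_nm = bbox_max_nm,
         voxel_size_nm = voxel_size_nm,
         boundary_margin_um = as.numeric(boundary_margin_um)),
    class = "dataset_geometry"
  )
}

#' @export
print.dataset_geometry <- function(x, ...) {
  ext <- (x$bbox_max_nm - x$bbox_min_nm) / 1000
  cat(sprintf(
    "<dataset_geometry> %g x %g x %g um, voxel %g x %g x %g nm, margin %g um\n",
    ext[1], ext[2], ext[3], x$voxel_size_nm[1], x$voxel_size_nm[2],
    x$voxel_size_nm[3], x$boundary_margin_um))
  invisible(x)
}

#' @rdname dataset_geometry
#' @param geometry A `dataset_geometry`.
#' @return `voxel_volume_um3()`: the volume of one voxel in cubic
#'   micrometres.
#' @export
voxel_volume_um3 <- function(geometry) {
  stopifnot(inherits(geometry, "dataset_geometry"))
  prod(geometry$voxel_size_nm) / 1e9
}

#' Cell-type vocabulary
#'
#' The cell-type labels used throughout the package, partitioned into
#' intrinsic neuron types (somata inside the volume), extrinsic projecting
#' axon classes, and non-neuronal classes.
#'
#' @return A character vector of labels.
#' @examples
#' intrinsic_types()
#' @export
cell_type_levels <- function() {
  c(intrinsic_types(), projecting_types(), nonneuronal_types())
}

#' @rdname cell_type_levels
#' @export
intrinsic_types <- function() {
  c("MSN", "GPe", "GPi", "STN", "TAN", "LTS", "INT1", "INT2", "INT3")
}

#' @rdname cell_type_levels
#' @export
projecting_types <- function() {
  c("HVC_axon", "LMAN_axon", "DA_axon")
}

#' @rdname cell_type_levels
#' @export
nonneuronal_types <- function() {
  c("ASTRO", "MICRO", "OLIGO", "MIGR", "FRAG")
}
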