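#' Assemble a tabular connectome dataset
#'
#' Bundles the cell, synapse, organelle, skeleton, soma-vertex and
#' spine-annotation tables of a reconstructed volume into a single validated
#' object. All referential integrity rules are checked on construction:
#' dangling identifiers are hard errors, never silent drops.
#'
#' @param cells Tibble with columns `cell_id`, `type`, `is_fragment`.
#' @param synapses Tibble with columns `synapse_id`, `pre_id`, `post_id`,
#'   `probability`, `mesh_area_um2`, `x_nm`, `y_nm`, `z_nm`,
#'   `post_compartment` and optionally `pre_compartment` (defaults to
#'   `"axon"`) and `size_um2`. The synapse size is defined as the synaptic
#'   mesh area divided by two; if `size_um2` is present it must equal
#'   `mesh_area_um2 / 2` exactly, otherwise it is derived.
#' @param organelles Tibble with columns `organelle_id`, `kind`
#'   (`"mitochondrion"` or `"vesicle_cloud"`), `voxel_count`, `x_nm`,
#'   `y_nm`, `z_nm`, `owner_cell_id`.
#' @param skeletons Tibble of skeleton nodes for all cells: `cell_id`,
#'   `node_id`, `parent_id` (`NA` for a root), `x_nm`, `y_nm`, `z_nm`,
#'   `radius_um`, `compartment` (`"axon"`, `"dendrite"` or `"soma"`),
#'   `myelinated`.
#' @param soma_vertices Tibble `cell_id`, `x_nm`, `y_nm`, `z_nm`; the soma
#'   surface point cloud of each cell (may omit fragments).
#' @param spine_counts Tibble `cell_id`, `n_spines`; dendritic spine
#'   annotations per cell. Cells without a row are treated as having zero
#'   annotated spines.
#' @param geometry A [dataset_geometry()].
#'
#' @return An object of class `connectome`: a named list of the validated
#'   tibbles plus the geometry.
#' @seealso [load_connectome()], [write_connectome()], [generate_connectome()]
#' @export
connectome <- function(cells, synapses, organelles, skeletons,
                       soma_vertices = NULL, spine_counts = NULL,
                       geometry = dataset_geometry()) {
  cells <- as_tibble(cells)
  synapses <- as_tibble(synapses)
  organelles <- as_tibble(organelles)
  skeletons <- as_tibble(skeletons)
  soma_vertices <- if (is.null(soma_vertices)) {
    tibble(cell_id = integer(), x_nm = double(), y_nm = double(),
           z_nm = double())
  } else as_tibble(soma_vertices)
  spine_counts <- if (is.null(spine_counts)) {
    tibble(cell_id = integer(), n_spines = integer())
  } else as_tibble(spine_counts)

  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      abort(sprintf("%s table is missing column(s): %s", what,
                    paste(missing, collapse = ", ")))
    }
  }
  need(cells, c("cell_id", "type", "is_fragment"), "cells")
  need(synapses, c("synapse_id", "pre_id", "post_id", "probability",
                   "mesh_area_um2", "x_nm", "y_nm", "z_nm",
                   "post_compartment"), "synapses")
  need(organelles, c("organelle_id", "kind", "voxel_count", "x_nm", "y_nm",
                     "z_nm", "owner_cell_id"), "organelles")
  need(skeletons, c("cell_id", "node_id", "parent_id", "x_nm", "y_nm",
                    "z_nm", "radius_um", "compartment", "myelinated"),
       "skeletons")

  organelles$voxel_count <- as.numeric(organelles$voxel_count)
  if (!"pre_compartment" %in% names(synapses)) {
    synapses$pre_compartment <- rep("axon", nrow(synapses))
  }
  if (!"size_um2" %in% names(synapses)) {
    synapses$size_um2 <- synapses$mesh_area_um2 / 2
  } else if (!identical(as.numeric(synapses$size_um2),
                        as.numeric(synapses$mesh_area_um2) / 2)) {
    abort("`size_um2` must equal `mesh_area_um2 / 2` exactly.")
  }

  x <- structure(
    list(cells = cells, synapses = synapses, organelles = organelles,
         skeletons = skeletons, soma_vertices = soma_vertices,
         spine_counts = spine_counts, geometry = geometry),
    class = "connectome"
  )
  validate_connectome(x)
}

#' Validate a connectome's invariants
#'
#' Checks referential integrity (every synapse endpoint, organelle owner,
#' skeleton node, soma vertex and spine annotation resolves to a cell),
#' value ranges (probabilities in the closed unit interval, non-negative
#' radii and sizes), the exact synapse-size halving rule, and that intrinsic
#' neurons carry soma vertices while fragments carry no soma nodes.
#'
#' @param x A `connectome`.
#' @return `x`, invisibly usable, after passing all checks; otherwise an
#'   error naming the offending rows.
#' @export
validate_connectome <- function(x) {
  stopifnot(inherits(x, "connectome"))
  ids <- x$cells$cell_id
  if (anyDuplicated(ids)) abort("Duplicated cell_id in cells table.")

  dangle <- function(ref, what) {
    bad <- which(!(ref %in% ids))
    if (length(bad)) {
      abort(sprintf(
        "Integrity error: %s references unknown cell id(s) in row(s) %s (ids: %s).",
        what, paste(head(bad, 10), collapse = ", "),
        paste(unique(head(ref[bad], 10)), collapse = ", ")))
    }
  }
  dangle(x$synapses$pre_id, "synapses$pre_id")
  dangle(x$synapses$post_id, "synapses$post_id")
  dangle(x$organelles$owner_cell_id, "organelles$owner_cell_id")
  dangle(x$skeletons$cell_id, "skeletons$cell_id")
  dangle(x$soma_vertices$cell_id, "soma_vertices$cell_id")
  dangle(x$spine_counts$cell_id, "spine_counts$cell_id")

  p <- x$synapses$probability
  if (length(p) && (min(p) < 0 || max(p) > 1)) {
    abort("Synapse probabilities must lie in [0, 1].")
  }
  if (length(x$synapses$mesh_area_um2) && min(x$synapses$mesh_area_um2) < 0) {
    abort("Synapse mesh areas must be non-negative.")
  }
  if (!identical(as.numeric(x$synapses$size_um2),
                 as.numeric(x$synapses$mesh_area_um2) / 2)) {
    abort("`size_um2` must equal `mesh_area_um2 / 2` exactly.")
  }
  if (length(x$skeletons$radius_um) && min(x$skeletons$radius_um) < 0) {
    abort("Skeleton node radii must be non-negative.")
  }
  if (length(x$organelles$voxel_count) && min(x$organelles$voxel_count) < 1) {
    abort("Organelle voxel counts must be >= 1.")
  }
  bad_comp <- setdiff(unique(x$skeletons$compartment),
                      c("axon", "dendrite", "soma"))
  if (length(bad_comp)) {
    abort(sprintf("Unknown skeleton compartment label(s): %s",
                  paste(bad_comp, collapse = ", ")))
  }

  intrinsic <- x$cells$cell_id[x$cells$type %in% intrinsic_types() &
                                 !x$cells$is_fragment]
  no_soma <- setdiff(intrinsic, unique(x$soma_vertices$cell_id))
  if (length(no_soma)) {
    abort(sprintf("Intrinsic neuron(s) without soma vertices: %s",
                  paste(head(no_soma, 10), collapse = ", ")))
  }
  frag <- x$cells$cell_id[x$cells$is_fragment]
  frag_soma <- x$skeletons$cell_id[x$skeletons$compartment == "soma"]
  bad_frag <- intersect(frag, unique(frag_soma))
  if (length(bad_frag)) {
    abort(sprintf("Fragment(s) carrying soma skeleton nodes: %s",
                  paste(head(bad_frag, 10), collapse = ", ")))
  }
  x
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d cells, %d synapses, %d organelles, %d skeleton nodes\n",
    nrow(x$cells), nrow(x$synapses), nrow(x$organelles), nrow(x$skeletons)))
  tt <- sort(table(x$cells$type), decreasing = TRUE)
  cat("  types:", paste(sprintf("%s=%d", names(tt), tt), collapse = " "), "\n")
  invisible(x)
}

#' Look up cell types for a set of ids
#'
#' @param cells The cells tibble of a connectome (or a `connectome`).
#' @param id Vector of cell ids.
#' @return Character vector of type labels; errors if any id is unknown.
#' @keywords internal
cell_type_of <- function(cells, id) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  m <- match(id, cells$cell_id)
  if (anyNA(m)) {
    abort(sprintf("Unknown cell id(s): %s",
                  paste(unique(id[is.na(m)]), collapse = ", ")))
  }
  cells$type[m]
}
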