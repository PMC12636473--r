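#' Skeleton edge table
#'
#' Expands parent links of one or many skeletons into an edge table with
#' Euclidean edge lengths (in micrometres) and the compartment labels of
#' both endpoints. Used by all length-based morphometry.
#'
#' @param skeletons Skeleton node tibble (see [connectome()]); may contain
#'   one or many `cell_id`s.
#' @return Tibble with one row per edge: `cell_id`, `node_id`, `parent_id`,
#'   `length_um`, `compartment` (child node label), `parent_compartment`,
#'   `myelin_edge` (both endpoints myelinated).
#' @export
skeleton_edges <- function(skeletons) {
  skeletons <- as_tibble(skeletons)
  if (!"cell_id" %in% names(skeletons)) skeletons$cell_id <- 1L
  child <- skeletons[!is.na(skeletons$parent_id), , drop = FALSE]
  if (!nrow(child)) {
    return(tibble(cell_id = skeletons$cell_id[0], node_id = integer(),
                  parent_id = integer(), length_um = double(),
                  compartment = character(), parent_compartment = character(),
                  myelin_edge = logical()))
  }
  key <- paste(skeletons$cell_id, skeletons$node_id)
  m <- match(paste(child$cell_id, child$parent_id), key)
  if (anyNA(m)) {
    abort("Structural error: parent_id not present among the cell's nodes.")
  }
  dx <- child$x_nm - skeletons$x_nm[m]
  dy <- child$y_nm - skeletons$y_nm[m]
  dz <- child$z_nm - skeletons$z_nm[m]
  tibble(
    cell_id = child$cell_id,
    node_id = child$node_id,
    parent_id = child$parent_id,
    length_um = sqrt(dx^2 + dy^2 + dz^2) / 1000,
    compartment = child$compartment,
    parent_compartment = skeletons$compartment[m],
    myelin_edge = child$myelinated & skeletons$myelinated[m]
  )
}

check_forest <- function(skeletons) {
  edges <- skeletons[!is.na(skeletons$parent_id), , drop = FALSE]
  if (!nrow(edges)) return(invisible(TRUE))
  if (!"cell_id" %in% names(skeletons)) skeletons$cell_id <- 1L
  if (!"cell_id" %in% names(edges)) edges$cell_id <- 1L
  verts <- paste(skeletons$cell_id, skeletons$node_id)
  g <- igraph::graph_from_edgelist(
    cbind(paste(edges$cell_id, edges$node_id),
          paste(edges$cell_id, edges$parent_id)),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(verts, igraph::V(g)$name))
  if (igraph::ecount(g) != igraph::vcount(g) -
        igraph::count_components(g)) {
    abort("Structural error: skeleton contains a cycle; expected a forest.")
  }
  invisible(TRUE)
}

#' Skeleton path length per compartment
#'
#' Sums Euclidean edge lengths over a skeleton. An edge contributes to a
#' single-compartment length only when both of its endpoints carry that
#' label; edges spanning two labels count only towards `"total"`. Lengths
#' are returned in micrometres (node coordinates are stored in nm).
#'
#' @param skeleton Node tibble of one cell.
#' @param compartment `"axon"`, `"dendrite"`, `"soma"` or `"total"`.
#' @return Length in micrometres (0 for an empty compartment).
#' @examples
#' sk <- tibble::tibble(cell_id = 1, node_id = 1:2, parent_id = c(NA, 1),
#'   x_nm = c(0, 10000), y_nm = 0, z_nm = 0, radius_um = 0.1,
#'   compartment = "axon", myelinated = FALSE)
#' path_length(sk, "axon") # 10
#' @export
path_length <- function(skeleton,
                        compartment = c("total", "axon", "dendrite", "soma")) {
  compartment <- match.arg(compartment)
  check_forest(skeleton)
  e <- skeleton_edges(skeleton)
  if (compartment != "total") {
    e <- e[e$compartment == compartment &
             e$parent_compartment == compartment, , drop = FALSE]
  }
  sum(e$length_um)
}

#' Per-cell compartment path lengths
#'
#' Vectorised version of [path_length()] over all cells of a skeleton
#' table.
#'
#' @param skeletons Skeleton node tibble with a `cell_id` column.
#' @return Tibble with one row per cell: `cell_id`, `axon_um`,
#'   `dendrite_um`, `soma_um`, `total_um`, `myelinated_axon_um`.
#' @export
compartment_lengths <- function(skeletons) {
  check_forest(skeletons)
  e <- skeleton_edges(skeletons)
  same <- e$compartment == e$parent_compartment
  per <- function(keep) {
    v <- rowsum(e$length_um[keep], e$cell_id[keep])
    setNames(v[, 1], rownames(v))
  }
  all_ids <- unique(skeletons$cell_id)
  get <- function(tab) {
    out <- tab[as.character(all_ids)]
    out[is.na(out)] <- 0
    unname(out)
  }
  tibble(
    cell_id = all_ids,
    axon_um = get(per(same & e$compartment == "axon")),
    dendrite_um = get(per(same & e$compartment == "dendrite")),
    soma_um = get(per(same & e$compartment == "soma")),
    total_um = get(per(rep(TRUE, nrow(e)))),
    myelinated_axon_um = get(per(same & e$compartment == "axon" &
                                   e$myelin_edge))
  )
}
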