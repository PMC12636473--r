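minimal_skeleton <- function(cell_id, center_nm = c(0, 0, 0),
                             soma_radius_um = 5, axon_um = 250,
                             dend_um = 250) {
  step <- 10000
  # n edges within the compartment = n nodes - 1, so realised single-label
  # path length equals the requested length exactly
  na <- max(2L, as.integer(round(axon_um * 1000 / step)) + 1L)
  nd <- max(2L, as.integer(round(dend_um * 1000 / step)) + 1L)
  ax <- tibble(
    cell_id = cell_id, node_id = 1L + seq_len(na),
    parent_id = c(1L, 1L + seq_len(na - 1)),
    x_nm = center_nm[1] + soma_radius_um * 1000 + seq_len(na) * step,
    y_nm = center_nm[2], z_nm = center_nm[3],
    radius_um = 0.1, compartment = "axon", myelinated = FALSE)
  de <- tibble(
    cell_id = cell_id, node_id = 1L + na + seq_len(nd),
    parent_id = c(1L, 1L + na + seq_len(nd - 1)),
    x_nm = center_nm[1] - soma_radius_um * 1000 - seq_len(nd) * step,
    y_nm = center_nm[2], z_nm = center_nm[3],
    radius_um = 0.3, compartment = "dendrite", myelinated = FALSE)
  soma <- tibble(
    cell_id = cell_id, node_id = 1L, parent_id = NA_integer_,
    x_nm = center_nm[1], y_nm = center_nm[2], z_nm = center_nm[3],
    radius_um = soma_radius_um, compartment = "soma", myelinated = FALSE)
  bind_rows(soma, ax, de)
}

octahedron_vertices <- function(cell_id, center_nm, radius_um) {
  r <- radius_um * 1000
  tibble(
    cell_id = cell_id,
    x_nm = center_nm[1] + c(r, -r, 0, 0, 0, 0),
    y_nm = center_nm[2] + c(0, 0, r, -r, 0, 0),
    z_nm = center_nm[3] + c(0, 0, 0, 0, r, -r))
}

#' Hand-built toy connectomes
#'
#' Small enumerable fixtures used by exact oracle tests and examples.
#'
#' * `"three_msn"`: 3 MSNs, 2 GPi cells, 1 GPe cell and 6 MSN-to-pallidum
#'   synapses whose aggregate GPi area share is exactly 0.75; its 6-row
#'   presynaptic column has 6! = 720 permutations, so the permutation null
#'   can be enumerated exhaustively.
#' * `"reciprocal_pair"`: one STN and one GPi neuron with synapses in both
#'   directions.
#' * `"int_clusters"`: 30 interneurons in three well-separated feature
#'   clusters around the INT1-3 classification thresholds (generated with
#'   a fixed internal seed).
#' * `"boundary_cells"`: six MSNs, half of them with dendrites within the
#'   boundary margin of the dataset box (fixed internal seed).
#'
#' @param name One of `"three_msn"`, `"reciprocal_pair"`, `"int_clusters"`,
#'   `"boundary_cells"`.
#' @return A validated [connectome()].
#' @export
generate_toy <- function(name = c("three_msn", "reciprocal_pair",
                                  "int_clusters", "boundary_cells")) {
  name <- match.arg(name)
  geom <- dataset_geometry(c(0, 0, 0), c(1e6, 1e6, 1e6))
  if (name == "three_msn") {
    centers <- list(`1` = c(1, 1, 1), `2` = c(2, 1, 1), `3` = c(3, 1, 1),
                    `4` = c(1, 2, 1), `5` = c(2, 2, 1), `6` = c(3, 2, 1))
    centers <- lapply(centers, function(p) p * 1e5)
    cells <- tibble(cell_id = 1:6,
                    type = c("MSN", "MSN", "MSN", "GPi", "GPi", "GPe"),
                    is_fragment = FALSE)
    sizes <- c(0.30, 0.20, 0.25, 0.15, 0.20, 0.10)
    syn <- tibble(
      synapse_id = 1:6,
      pre_id = c(1L, 1L, 2L, 2L, 3L, 3L),
      post_id = c(4L, 6L, 4L, 5L, 5L, 6L),
      probability = 1,
      mesh_area_um2 = sizes * 2,
      x_nm = 5e5, y_nm = 5e5, z_nm = 5e5,
      post_compartment = "shaft", pre_compartment = "axon")
    skel <- bind_rows(lapply(1:6, function(i)
      minimal_skeleton(i, centers[[as.character(i)]])))
    soma <- bind_rows(lapply(1:6, function(i)
      octahedron_vertices(i, centers[[as.character(i)]], 5)))
    spines <- tibble(cell_id = 1:6, n_spines = c(15L, 15L, 15L, 0L, 0L, 0L))
    return(connectome(cells, syn, empty_organelles(), skel, soma, spines,
                      geom))
  }
  if (name == "reciprocal_pair") {
    cells <- tibble(cell_id = 1:2, type = c("STN", "GPi"),
                    is_fragment = FALSE)
    syn <- tibble(
      synapse_id = 1:4,
      pre_id = c(1L, 1L, 2L, 2L), post_id = c(2L, 2L, 1L, 1L),
      probability = 1, mesh_area_um2 = c(0.6, 0.4, 0.5, 0.3),
      x_nm = 5e5, y_nm = 5e5, z_nm = 5e5,
      post_compartment = c("shaft", "soma", "shaft", "shaft"),
      pre_compartment = "axon")
    skel <- bind_rows(minimal_skeleton(1L, c(1e5, 1e5, 1e5)),
                      minimal_skeleton(2L, c(5e5, 5e5, 5e5)))
    soma <- bind_rows(octahedron_vertices(1L, c(1e5, 1e5, 1e5), 5),
                      octahedron_vertices(2L, c(5e5, 5e5, 5e5), 7))
    spines <- tibble(cell_id = 1:2, n_spines = 0L)
    return(connectome(cells, syn, empty_organelles(), skel, soma, spines,
                      geom))
  }
  if (name == "int_clusters") {
    cfg <- generator_config(
      seed = 424242L,
      n_per_type = c(INT1 = 10, INT2 = 10, INT3 = 10),
      boundary_clip_fraction = 0)
    return(generate_connectome(cfg)$dataset)
  }
  # boundary_cells
  cfg <- generator_config(
    seed = 737373L,
    n_per_type = c(MSN = 6, GPe = 2, GPi = 2),
    boundary_clip_fraction = 0.5)
  generate_connectome(cfg)$dataset
}

empty_organelles <- function() {
  tibble(organelle_id = integer(), kind = character(),
         voxel_count = double(), x_nm = double(), y_nm = double(),
         z_nm = double(), owner_cell_id = integer())
}
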