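# Independent brute-force oracles; deliberately written with plain loops,
# sharing no code with the package internals.

oracle_edge_sum <- function(skeleton, compartment = "total") {
  total <- 0
  for (i in seq_len(nrow(skeleton))) {
    p <- skeleton$parent_id[i]
    if (is.na(p)) next
    j <- which(skeleton$node_id == p)
    if (compartment != "total" &&
        !(skeleton$compartment[i] == compartment &&
          skeleton$compartment[j] == compartment)) next
    total <- total + sqrt((skeleton$x_nm[i] - skeleton$x_nm[j])^2 +
                            (skeleton$y_nm[i] - skeleton$y_nm[j])^2 +
                            (skeleton$z_nm[i] - skeleton$z_nm[j])^2) / 1000
  }
  total
}

oracle_filter_synapses <- function(syn, min_p = 0.6, min_s = 0.1) {
  keep <- logical(nrow(syn))
  for (i in seq_len(nrow(syn))) {
    keep[i] <- syn$probability[i] >= min_p &&
      syn$size_um2[i] >= min_s &&
      syn$pre_compartment[i] == "axon" &&
      syn$post_compartment[i] %in% c("shaft", "spine_neck", "spine_head",
                                     "soma")
  }
  syn$synapse_id[keep]
}

oracle_nearest_node <- function(skeleton, x, y, z) {
  best <- Inf
  best_id <- NA_integer_
  ord <- order(skeleton$node_id)
  for (i in ord) {
    d <- (skeleton$x_nm[i] - x)^2 + (skeleton$y_nm[i] - y)^2 +
      (skeleton$z_nm[i] - z)^2
    if (d < best) {
      best <- d
      best_id <- skeleton$node_id[i]
    }
  }
  best_id
}

# all permutations of 1..n as a list (n <= 6 in tests)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# a hand-built 20-cell fixture exercising every table
make_fixture <- function() {
  set.seed(99)
  types <- c(rep("MSN", 8), rep("GPe", 2), rep("GPi", 3), "STN", "TAN",
             rep("INT2", 2), rep("HVC_axon", 3))
  n <- length(types)
  is_frag <- types == "HVC_axon"
  cells <- tibble::tibble(cell_id = 1:n, type = types,
                          is_fragment = is_frag)
  centers <- cbind(runif(n, 2e5, 8e5), runif(n, 2e5, 8e5),
                   runif(n, 2e5, 8e5))
  skel <- list()
  soma <- list()
  for (i in 1:n) {
    if (is_frag[i]) {
      k <- 8L
      skel[[i]] <- tibble::tibble(
        cell_id = i, node_id = seq_len(k),
        parent_id = c(NA, seq_len(k - 1)),
        x_nm = centers[i, 1] + seq_len(k) * 9000,
        y_nm = centers[i, 2], z_nm = centers[i, 3],
        radius_um = 0.08, compartment = "axon",
        myelinated = FALSE)
    } else {
      skel[[i]] <- bgconnect:::minimal_skeleton(i, centers[i, ],
                                                soma_radius_um = 4 +
                                                  i / 10)
      soma[[i]] <- bgconnect:::octahedron_vertices(i, centers[i, ],
                                                   4 + i / 10)
    }
  }
  n_syn <- 60
  pre <- sample(1:n, n_syn, replace = TRUE)
  post <- sample(cells$cell_id[!is_frag], n_syn, replace = TRUE)
  syn <- tibble::tibble(
    synapse_id = 1:n_syn, pre_id = pre, post_id = post,
    probability = round(runif(n_syn), 3),
    mesh_area_um2 = round(rlnorm(n_syn, -1.5, 0.7), 5),
    x_nm = runif(n_syn, 1e5, 9e5), y_nm = runif(n_syn, 1e5, 9e5),
    z_nm = runif(n_syn, 1e5, 9e5),
    post_compartment = sample(c("shaft", "spine_head", "spine_neck",
                                "soma", "axon"), n_syn, replace = TRUE,
                              prob = c(.4, .2, .1, .2, .1)),
    pre_compartment = sample(c("axon", "dendrite"), n_syn,
                             replace = TRUE, prob = c(.9, .1)))
  org <- tibble::tibble(
    organelle_id = 1:30,
    kind = sample(c("mitochondrion", "vesicle_cloud"), 30, TRUE),
    voxel_count = sample(1e3:1e5, 30),
    x_nm = runif(30, 1e5, 9e5), y_nm = runif(30, 1e5, 9e5),
    z_nm = runif(30, 1e5, 9e5),
    owner_cell_id = sample(1:n, 30, TRUE))
  spines <- tibble::tibble(cell_id = cells$cell_id[!is_frag],
                           n_spines = sample(0:30, sum(!is_frag), TRUE))
  connectome(cells, syn, org, dplyr::bind_rows(skel),
             dplyr::bind_rows(soma), spines,
             dataset_geometry(c(0, 0, 0), c(1e6, 1e6, 1e6)))
}

small_config <- function(seed = 11, ...) {
  generator_config(
    seed = seed,
    n_per_type = c(MSN = 60, GPe = 4, GPi = 6, STN = 6, TAN = 2,
                   INT1 = 6, INT2 = 6, INT3 = 6, HVC_axon = 15),
    ...)
}
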