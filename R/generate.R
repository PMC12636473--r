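nb_moment_params <- function(mean, sd, what = "count") {
  if (mean < 0 || sd < 0) {
    abort(sprintf("Impossible %s mean/SD pair: mean=%g, sd=%g.", what, mean,
                  sd))
  }
  if (sd^2 <= mean) {
    list(family = "poisson", lambda = mean)
  } else {
    list(family = "nbinom", mu = mean, size = mean^2 / (sd^2 - mean))
  }
}

rcount <- function(n, params) {
  if (params$family == "poisson") rpois(n, params$lambda)
  else rnbinom(n, size = params$size, mu = params$mu)
}

# per-type morphometric profiles (means and SDs) used by the generator;
# INT1-3 come from int_cluster_centers/sds in the config instead
type_profiles <- function() {
  tibble::tribble(
    ~type, ~soma_radius, ~soma_radius_sd, ~axon_len, ~dend_len,
    ~axon_radius, ~dend_radius, ~axon_mito, ~dend_mito, ~soma_mito,
    ~vesicle, ~spine, ~myelin,
    "MSN",  4.5, 0.40, 400, 350, 0.09, 0.30, 0.012, 0.020, 0.05, 0.010, 0.060, 0.02,
    "INT1", 12.5, 0.30, 450, 300, 0.08, 0.35, 0.015, 0.020, 0.05, 0.015, 0.010, 0.05,
    "INT2",  9.0, 0.30, 450, 300, 0.08, 0.35, 0.015, 0.020, 0.05, 0.015, 0.045, 0.05,
    "INT3", 14.0, 0.30, 450, 300, 0.15, 0.35, 0.040, 0.020, 0.05, 0.015, 0.010, 0.05,
    "GPe", 10.0, 0.80, 600, 500, 0.18, 0.45, 0.050, 0.030, 0.06, 0.020, 0.003, 0.25,
    "GPi", 13.0, 1.00, 800, 600, 0.25, 0.50, 0.080, 0.035, 0.06, 0.020, 0.002, 0.50,
    "STN",  9.0, 0.70, 500, 400, 0.15, 0.40, 0.030, 0.025, 0.05, 0.015, 0.010, 0.30,
    "TAN", 11.0, 0.80, 450, 350, 0.12, 0.40, 0.020, 0.022, 0.05, 0.025, 0.004, 0.05,
    "LTS", 10.5, 0.80, 350, 300, 0.10, 0.35, 0.018, 0.020, 0.05, 0.015, 0.004, 0.02,
    "HVC_axon",  0, 0, 10, 0, 0.08, 0, 0.010, 0, 0, 0.012, 0, 0.30,
    "LMAN_axon", 0, 0, 10, 0, 0.10, 0, 0.012, 0, 0, 0.012, 0, 0.20,
    "DA_axon",   0, 0, 10, 0, 0.07, 0, 0.008, 0, 0, 0.015, 0, 0.00
  )
}

default_int_clusters <- function() {
  list(
    centers = list(
      INT1 = c(axon_mito_density = 0.015, axon_median_radius = 0.080,
               soma_radius = 12.5, spine_density = 0.010),
      INT2 = c(axon_mito_density = 0.015, axon_median_radius = 0.080,
               soma_radius = 9.0, spine_density = 0.045),
      INT3 = c(axon_mito_density = 0.040, axon_median_radius = 0.150,
               soma_radius = 14.0, spine_density = 0.010)),
    sds = c(axon_mito_density = 0.003, axon_median_radius = 0.009,
            soma_radius = 0.30, spine_density = 0.0045)
  )
}

default_projection_mix <- function() {
  tibble::tribble(
    ~pre_type, ~post_type, ~syn_per_pre, ~area_mean_um2,
    "HVC_axon",  "MSN",  NA, 0.14,   # NA: Poisson(length / 10) per fragment
    "LMAN_axon", "MSN",  NA, 0.16,
    "DA_axon",   "MSN",  NA, 0.10,
    "HVC_axon",  "STN",  NA, 0.15,
    "MSN", "TAN", 2, 0.12,
    "TAN", "MSN", 2, 0.12,
    "STN", "GPi", 6, 0.30,
    "GPi", "STN", 4, 0.28,
    "STN", "GPe", 2, 0.20,
    "GPe", "STN", 2, 0.20,
    "GPi", "GPi", 3, 0.30,
    "GPe", "INT2", 4, 0.18,
    "GPe", "INT3", 4, 0.18,
    "INT1", "GPi", 3, 0.15
  )
}

#' Configuration for the synthetic-connectome generator
#'
#' The defaults emulate the statistical structure reported for the songbird
#' basal-ganglia (Area X) EM dataset: per-MSN synapse counts onto the two
#' pallidal populations drawn from negative binomials with means/SDs
#' 9.6 +/- 7.2 (GPi) and 3.54 +/- 5.4 (GPe), lognormal synapse areas
#' calibrated so the aggregate GPi share of MSN-to-pallidum synaptic area
#' equals `gpi_area_share` (default 0.75), interneuron morphometric
#' clusters placed around the published INT1-3 classification thresholds,
#' short extrinsic axon fragments, and a configurable fraction of MSNs
#' whose dendrites approach the dataset boundary.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed.
#' @param n_per_type Named integer vector of cell counts per type. The
#'   default uses the published intrinsic-neuron census (8,093 MSNs, 27
#'   GPe, 47 GPi, 102 STN, 8 TAN, 37 LTS, 96/100/66 INT1-3) and a
#'   down-scaled fragment catalogue.
#' @param gpi_area_share Aggregate GPi share of MSN-to-pallidum synaptic
#'   area in (0, 1).
#' @param msn_gpi_count_mean,msn_gpi_count_sd,msn_gpe_count_mean,msn_gpe_count_sd
#'   Per-MSN synapse-count moments for the two pallidal targets. A
#'   negative binomial is fitted by method of moments; a Poisson is used
#'   when `sd^2 <= mean`.
#' @param gp_assignment `"marginal"` (default) draws the GPi and GPe counts
#'   of each MSN independently from the two fitted distributions, matching
#'   both printed marginal SDs. `"pooled"` draws the same per-MSN totals
#'   but assigns each synapse's target type independently with the mean
#'   count share, which makes an unselective population exchangeable with
#'   the presynaptic-identity permutation null (use this mode to check
#'   null-model calibration).
#' @param area_sdlog Lognormal sigma of synapse areas (all pairs).
#' @param msn_gpe_area_mean_um2 Mean MSN-to-GPe synapse area; the
#'   MSN-to-GPi mean is solved from `gpi_area_share` and the count means,
#'   so GPi synapses come out larger whenever the area share exceeds the
#'   count share.
#' @param selective_fraction Fraction of MSNs forced to be fully
#'   GPi-selective (all pallidal synapses onto GPi, GP ratio 1, hence at
#'   least `selective_level`).
#' @param selective_level Selectivity level the forced MSNs are guaranteed
#'   to reach (metadata; forcing always yields ratio 1).
#' @param boundary_clip_fraction Fraction of MSNs whose dendrite is laid
#'   out to approach within the boundary margin of the dataset box.
#' @param fragment_length Named list per projecting-axon class with
#'   `meanlog`/`sdlog` of the lognormal fragment skeleton length (um).
#' @param int_clusters List with `centers` (per INT class, named feature
#'   means) and `sds` (named feature SDs); defaults place the three
#'   clusters 3.3 SDs away from the published thresholds.
#' @param projection_mix Tibble of additional cell-type projections
#'   (`pre_type`, `post_type`, `syn_per_pre`, `area_mean_um2`).
#' @param qc_probability_mode If `TRUE`, synapse probabilities are drawn
#'   from a bimodal mixture and areas are scaled down so that the QC
#'   filters have non-trivial work; if `FALSE` (default) all probabilities
#'   are 1 and the dataset emulates an already-filtered table.
#' @param geometry A [dataset_geometry()]; the default is the published
#'   256 x 256 x 384 um effective dataset box.
#'
#' @return A list of class `generator_config`.
#' @seealso [generate_connectome()]
#' @export
generator_config <- function(
    seed = 1L,
    n_per_type = c(MSN = 8093, GPe = 27, GPi = 47, STN = 102, TAN = 8,
                   LTS = 37, INT1 = 96, INT2 = 100, INT3 = 66,
                   HVC_axon = 400, LMAN_axon = 80, DA_axon = 120),
    gpi_area_share = 0.75,
    msn_gpi_count_mean = 9.6, msn_gpi_count_sd = 7.2,
    msn_gpe_count_mean = 3.54, msn_gpe_count_sd = 5.4,
    gp_assignment = c("marginal", "pooled"),
    area_sdlog = 0.6,
    msn_gpe_area_mean_um2 = 0.25,
    selective_fraction = 0,
    selective_level = 0.9,
    boundary_clip_fraction = 0.1,
    fragment_length = list(HVC_axon = c(meanlog = log(10), sdlog = 1),
                           LMAN_axon = c(meanlog = log(10), sdlog = 1),
                           DA_axon = c(meanlog = log(10), sdlog = 1)),
    int_clusters = default_int_clusters(),
    projection_mix = default_projection_mix(),
    qc_probability_mode = FALSE,
    geometry = dataset_geometry()) {
  gp_assignment <- match.arg(gp_assignment)
  stopifnot(gpi_area_share > 0, gpi_area_share < 1,
            selective_fraction >= 0, selective_fraction <= 1,
            boundary_clip_fraction >= 0, boundary_clip_fraction <= 1,
            area_sdlog >= 0, msn_gpe_area_mean_um2 > 0)
  bad <- setdiff(names(n_per_type),
                 c(intrinsic_types(), projecting_types()))
  if (length(bad)) {
    abort(sprintf("Unknown cell type(s) in n_per_type: %s",
                  paste(bad, collapse = ", ")))
  }
  # validates the count moment pairs up front
  nb_moment_params(msn_gpi_count_mean, msn_gpi_count_sd, "MSN-GPi")
  nb_moment_params(msn_gpe_count_mean, msn_gpe_count_sd, "MSN-GPe")
  structure(
    list(seed = as.integer(seed), n_per_type = n_per_type,
         gpi_area_share = gpi_area_share,
         msn_gpi_count_mean = msn_gpi_count_mean,
         msn_gpi_count_sd = msn_gpi_count_sd,
         msn_gpe_count_mean = msn_gpe_count_mean,
         msn_gpe_count_sd = msn_gpe_count_sd,
         gp_assignment = gp_assignment,
         area_sdlog = area_sdlog,
         msn_gpe_area_mean_um2 = msn_gpe_area_mean_um2,
         selective_fraction = selective_fraction,
         selective_level = selective_level,
         boundary_clip_fraction = boundary_clip_fraction,
         fragment_length = fragment_length,
         int_clusters = int_clusters,
         projection_mix = projection_mix,
         qc_probability_mode = qc_probability_mode,
         geometry = geometry),
    class = "generator_config")
}

STEP_NM <- 5000        # skeleton node spacing
FOLD_UM <- 25          # half-width of the folded-stick neurite territory

tri_fold <- function(s, width) {
  t <- s %% (2 * width)
  ifelse(t < width, t, 2 * width - t)
}

rand_unit <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Build folded-stick neurite chains for many cells at once.
# start: n x 3 matrix (nm), dirs: n x 3 unit vectors, len_um: target lengths,
# width_um: fold half-widths. Returns node tibble without ids/parents.
build_chains <- function(start, dirs, len_um, width_um) {
  n_nodes <- pmax(2L, as.integer(round(len_um * 1000 / STEP_NM)))
  idx <- rep(seq_along(len_um), n_nodes)
  s <- sequence(n_nodes) * STEP_NM
  width_um <- rep(width_um, length.out = length(n_nodes))
  off <- tri_fold(s, rep(width_um, n_nodes) * 1000)
  tibble(
    cell_row = idx,
    within = sequence(n_nodes),
    x_nm = start[idx, 1] + dirs[idx, 1] * off,
    y_nm = start[idx, 2] + dirs[idx, 2] * off,
    z_nm = start[idx, 3] + dirs[idx, 3] * off
  )
}

#' Generate a synthetic connectome with ground truth
#'
#' Draws a full tabular connectome (cells, SWC-style skeletons, soma vertex
#' clouds, mitochondria/vesicle-cloud organelles, spine annotations and a
#' synapse table) whose distributional structure follows a
#' [generator_config()]. Skeletons are simple parameterised trees (a soma
#' ball plus folded axon and dendrite sticks) carrying enough structure for
#' every morphometry operation; organelles are sized so that each cell's
#' realised mitochondrial volume densities match its drawn feature values.
#' The ground-truth table records each cell's true type and realised
#' morphometric features and, for MSNs, the true pallidal target ratio; no
#' analysis function ever reads it.
#'
#' @param config A [generator_config()].
#' @return A list with elements `dataset` (a validated [connectome()]) and
#'   `ground_truth` (a tibble with one row per generated cell; the
#'   configuration is attached as attribute `"config"`).
#' @examples
#' g <- generate_connectome(generator_config(
#'   seed = 7, n_per_type = c(MSN = 30, GPe = 3, GPi = 5)))
#' g$dataset
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  geom <- config$geometry
  npt <- config$n_per_type[config$n_per_type > 0]
  types <- rep(names(npt), npt)
  n_cells <- length(types)
  cell_id <- seq_len(n_cells)
  is_frag <- types %in% projecting_types()

  prof <- type_profiles()
  pr <- prof[match(types, prof$type), ]

  # --- per-cell feature draws -------------------------------------------
  soma_r <- pmax(1, rnorm(n_cells, pr$soma_radius, pr$soma_radius_sd))
  axon_len <- pmax(20, rnorm(n_cells, pr$axon_len, pr$axon_len * 0.2))
  dend_len <- pmax(20, rnorm(n_cells, pr$dend_len, pr$dend_len * 0.2))
  axon_rad <- pmax(0.01, rnorm(n_cells, pr$axon_radius,
                               pr$axon_radius * 0.08))
  dend_rad <- pmax(0.05, pr$dend_radius)
  ax_mito <- pmax(1e-4, rnorm(n_cells, pr$axon_mito, pr$axon_mito * 0.15))
  de_mito <- pmax(0, pr$dend_mito * runif(n_cells, 0.8, 1.2))
  so_mito <- pmax(0, pr$soma_mito * runif(n_cells, 0.8, 1.2))
  vesicle <- pmax(0, pr$vesicle * runif(n_cells, 0.8, 1.2))
  spine_d <- pmax(0, rnorm(n_cells, pr$spine, pr$spine * 0.2))
  myelin_f <- pmin(1, pmax(0, rnorm(n_cells, pr$myelin,
                                    0.05 * (pr$myelin > 0))))

  # interneuron classes live in configured feature clusters around the
  # published thresholds
  icc <- config$int_clusters
  for (cls in intersect(c("INT1", "INT2", "INT3"), unique(types))) {
    sel <- which(types == cls)
    ctr <- icc$centers[[cls]]
    sds <- icc$sds
    ax_mito[sel] <- pmax(1e-4, rnorm(length(sel), ctr[["axon_mito_density"]],
                                     sds[["axon_mito_density"]]))
    axon_rad[sel] <- pmax(0.01, rnorm(length(sel),
                                      ctr[["axon_median_radius"]],
                                      sds[["axon_median_radius"]]))
    soma_r[sel] <- pmax(1, rnorm(length(sel), ctr[["soma_radius"]],
                                 sds[["soma_radius"]]))
    spine_d[sel] <- pmax(0, rnorm(length(sel), ctr[["spine_density"]],
                                  sds[["spine_density"]]))
    axon_len[sel] <- pmax(20, rnorm(length(sel), 450, 60))
    dend_len[sel] <- pmax(20, rnorm(length(sel), 300, 50))
    myelin_f[sel] <- pmin(1, pmax(0, rnorm(length(sel), 0.05, 0.02)))
  }

  # fragments: lognormal total lengths, axon only
  for (cls in intersect(projecting_types(), unique(types))) {
    sel <- which(types == cls)
    fl <- config$fragment_length[[cls]]
    axon_len[sel] <- pmax(5, rlnorm(length(sel), fl[["meanlog"]],
                                    fl[["sdlog"]]))
    dend_len[sel] <- 0
    soma_r[sel] <- 0
  }

  # --- soma placement ----------------------------------------------------
  inset_nm <- (FOLD_UM + geom$boundary_margin_um + soma_r + 8) * 1000
  lo <- matrix(geom$bbox_min_nm, n_cells, 3, byrow = TRUE) + inset_nm
  hi <- matrix(geom$bbox_max_nm, n_cells, 3, byrow = TRUE) - inset_nm
  centers <- lo + matrix(runif(3 * n_cells), ncol = 3) * (hi - lo)

  # boundary-clipped MSNs sit near the x-min face, dendrite folded towards it
  msn_rows <- which(types == "MSN")
  n_clip <- round(config$boundary_clip_fraction * length(msn_rows))
  clip_rows <- if (n_clip > 0) sort(sample(msn_rows, n_clip)) else integer()
  clipped <- logical(n_cells)
  clipped[clip_rows] <- TRUE
  if (n_clip > 0) {
    centers[clip_rows, 1] <- geom$bbox_min_nm[1] +
      runif(n_clip, 40, 60) * 1000
  }

  # --- skeletons ---------------------------------------------------------
  axon_dir <- rand_unit(n_cells)
  dend_dir <- -axon_dir
  # clipped cells: dendrite folds inside [face + d_target, soma centre],
  # guaranteeing a node within the boundary margin
  dend_width <- rep(FOLD_UM, n_cells)
  if (n_clip > 0) {
    d_target <- runif(n_clip, 1, 3)
    dend_dir[clip_rows, ] <- matrix(rep(c(-1, 0, 0), each = n_clip),
                                    ncol = 3)
    axon_dir[clip_rows, ] <- matrix(rep(c(1, 0, 0), each = n_clip),
                                    ncol = 3)
    dend_width[clip_rows] <-
      (centers[clip_rows, 1] - geom$bbox_min_nm[1]) / 1000 - d_target -
      soma_r[clip_rows]
  }

  ax_start <- centers + axon_dir * (soma_r * 1000)
  de_start <- centers + dend_dir * (soma_r * 1000)

  ax_nodes <- build_chains(ax_start, axon_dir, axon_len, FOLD_UM)
  has_dend <- dend_len > 0
  de_nodes <- build_chains(de_start[has_dend, , drop = FALSE],
                           dend_dir[has_dend, , drop = FALSE],
                           dend_len[has_dend],
                           dend_width[has_dend])
  de_nodes$cell_row <- which(has_dend)[de_nodes$cell_row]

  n_ax <- tabulate(ax_nodes$cell_row, n_cells)
  n_de <- tabulate(de_nodes$cell_row, n_cells)

  # myelination: a contiguous distal run of axon nodes such that the number
  # of fully-myelinated edges matches the drawn fraction
  my_edges <- round(myelin_f * pmax(0, n_ax - 1))
  ax_myel <- ax_nodes$within > (n_ax[ax_nodes$cell_row] -
                                  my_edges[ax_nodes$cell_row] - 1)
  ax_myel[my_edges[ax_nodes$cell_row] == 0] <- FALSE

  soma_nodes <- tibble(
    cell_id = cell_id[!is_frag], node_id = 1L, parent_id = NA_integer_,
    x_nm = centers[!is_frag, 1], y_nm = centers[!is_frag, 2],
    z_nm = centers[!is_frag, 3], radius_um = soma_r[!is_frag],
    compartment = "soma", myelinated = FALSE)
  has_soma <- !is_frag
  ax_first_id <- ifelse(has_soma, 2L, 1L)
  skel_ax <- tibble(
    cell_id = cell_id[ax_nodes$cell_row],
    node_id = ax_nodes$within + ax_first_id[ax_nodes$cell_row] - 1L,
    parent_id = ifelse(
      ax_nodes$within == 1L,
      ifelse(has_soma[ax_nodes$cell_row], 1L, NA_integer_),
      ax_nodes$within + ax_first_id[ax_nodes$cell_row] - 2L),
    x_nm = ax_nodes$x_nm, y_nm = ax_nodes$y_nm, z_nm = ax_nodes$z_nm,
    radius_um = axon_rad[ax_nodes$cell_row],
    compartment = "axon", myelinated = ax_myel)
  de_first_id <- ax_first_id + n_ax
  skel_de <- tibble(
    cell_id = cell_id[de_nodes$cell_row],
    node_id = de_nodes$within + de_first_id[de_nodes$cell_row] - 1L,
    parent_id = ifelse(
      de_nodes$within == 1L, 1L,
      de_nodes$within + de_first_id[de_nodes$cell_row] - 2L),
    x_nm = de_nodes$x_nm, y_nm = de_nodes$y_nm, z_nm = de_nodes$z_nm,
    radius_um = dend_rad[de_nodes$cell_row],
    compartment = "dendrite", myelinated = FALSE)
  skeletons <- dplyr::arrange(bind_rows(soma_nodes, skel_ax, skel_de),
                              .data$cell_id, .data$node_id)

  lens <- compartment_lengths(skeletons)
  lens <- lens[match(cell_id, lens$cell_id), ]

  # --- soma vertex clouds (points exactly on a sphere of the drawn radius)
  # antipodal vertex pairs make the componentwise median vertex equal the
  # true centre, so the median-distance soma radius is exact
  n_vert <- 40L
  som_rows <- which(!is_frag)
  half <- rand_unit(n_vert / 2 * length(som_rows))
  vdir <- matrix(0, n_vert * length(som_rows), 3)
  odd <- rep(c(TRUE, FALSE), length.out = nrow(vdir))
  vdir[odd, ] <- half
  vdir[!odd, ] <- -half
  vidx <- rep(som_rows, each = n_vert)
  soma_vertices <- tibble(
    cell_id = cell_id[vidx],
    x_nm = centers[vidx, 1] + vdir[, 1] * soma_r[vidx] * 1000,
    y_nm = centers[vidx, 2] + vdir[, 2] * soma_r[vidx] * 1000,
    z_nm = centers[vidx, 3] + vdir[, 3] * soma_r[vidx] * 1000)

  # --- organelles --------------------------------------------------------
  vox_vol <- voxel_volume_um3(geom)
  place_organelles <- function(comp_nodes, target_total_um3, kind) {
    # comp_nodes: skeleton rows of one compartment class, sorted by cell;
    # cell ids are 1..n_cells so ids double as row indices
    rows <- which(target_total_um3 > 0)
    rows <- rows[tabulate(comp_nodes$cell_id, n_cells)[rows] > 0]
    if (!length(rows)) {
      return(tibble(kind = character(), voxel_count = double(),
                    x_nm = double(), y_nm = double(), z_nm = double(),
                    owner_cell_id = cell_id[0]))
    }
    k <- pmax(1L, as.integer(round(target_total_um3[rows] / 0.5)))
    owner <- rep(rows, k)
    raw <- rlnorm(length(owner), 0, 0.5)
    tot <- rowsum(raw, owner)[, 1]      # owner groups sorted = rows order
    scale <- (target_total_um3[rows] / vox_vol) / tot
    vox <- pmax(1, round(raw * rep(scale, k)))
    # pick a uniform random node of the owner's compartment run
    cnt <- tabulate(comp_nodes$cell_id, n_cells)
    first <- cumsum(c(0L, cnt))[seq_len(n_cells)]
    node_row <- first[owner] + 1L +
      as.integer(floor(runif(length(owner)) * cnt[owner]))
    tibble(kind = kind, voxel_count = as.numeric(vox),
           x_nm = comp_nodes$x_nm[node_row],
           y_nm = comp_nodes$y_nm[node_row],
           z_nm = comp_nodes$z_nm[node_row],
           owner_cell_id = cell_id[owner])
  }
  ax_sk <- skeletons[skeletons$compartment == "axon", ]
  de_sk <- skeletons[skeletons$compartment == "dendrite", ]
  so_sk <- skeletons[skeletons$compartment == "soma", ]
  organelles <- bind_rows(
    place_organelles(ax_sk, ax_mito * lens$axon_um, "mitochondrion"),
    place_organelles(de_sk, de_mito * lens$dendrite_um, "mitochondrion"),
    place_organelles(so_sk, so_mito * (4 / 3) * pi * soma_r^3 *
                       (!is_frag), "mitochondrion"),
    place_organelles(ax_sk, vesicle * lens$axon_um, "vesicle_cloud"))
  organelles$organelle_id <- seq_len(nrow(organelles))
  organelles <- organelles[, c("organelle_id", "kind", "voxel_count",
                               "x_nm", "y_nm", "z_nm", "owner_cell_id")]

  spine_counts <- tibble(
    cell_id = cell_id[!is_frag],
    n_spines = as.integer(round(spine_d[!is_frag] *
                                  lens$dendrite_um[!is_frag])))

  # --- MSN -> pallidum synapses -----------------------------------------
  msn_ids <- cell_id[types == "MSN"]
  gpi_ids <- cell_id[types == "GPi"]
  gpe_ids <- cell_id[types == "GPe"]
  gp_truth <- NULL
  syn_gp <- NULL
  if (length(msn_ids) && length(gpi_ids) && length(gpe_ids)) {
    pi_par <- nb_moment_params(config$msn_gpi_count_mean,
                               config$msn_gpi_count_sd, "MSN-GPi")
    pe_par <- nb_moment_params(config$msn_gpe_count_mean,
                               config$msn_gpe_count_sd, "MSN-GPe")
    n_msn <- length(msn_ids)
    n_gpi <- rcount(n_msn, pi_par)
    n_gpe <- rcount(n_msn, pe_par)
    n_tot <- n_gpi + n_gpe
    pre <- rep(msn_ids, n_tot)
    if (config$gp_assignment == "marginal") {
      to_gpi <- unlist(mapply(function(a, b) c(rep(TRUE, a), rep(FALSE, b)),
                              n_gpi, n_gpe, SIMPLIFY = FALSE),
                       use.names = FALSE)
      if (is.null(to_gpi)) to_gpi <- logical()
    } else {
      p_share <- config$msn_gpi_count_mean /
        (config$msn_gpi_count_mean + config$msn_gpe_count_mean)
      to_gpi <- runif(length(pre)) < p_share
    }
    n_forced <- round(config$selective_fraction * n_msn)
    if (n_forced > 0) {
      forced_ids <- sample(msn_ids, n_forced)
      to_gpi[pre %in% forced_ids] <- TRUE
    } else {
      forced_ids <- integer()
    }
    # area calibration: mean GPi area solved so the expected aggregate GPi
    # area share equals the configured share
    s <- config$gpi_area_share
    m_e <- config$msn_gpe_area_mean_um2
    m_i <- s / (1 - s) * config$msn_gpe_count_mean * m_e /
      config$msn_gpi_count_mean
    sdl <- config$area_sdlog
    mu_i <- log(m_i) - sdl^2 / 2
    mu_e <- log(m_e) - sdl^2 / 2
    size <- ifelse(to_gpi, rlnorm(length(pre), mu_i, sdl),
                   rlnorm(length(pre), mu_e, sdl))
    post <- integer(length(pre))
    post[to_gpi] <- sample(gpi_ids, sum(to_gpi), replace = TRUE)
    post[!to_gpi] <- sample(gpe_ids, sum(!to_gpi), replace = TRUE)
    comp <- sample(c("shaft", "soma"), length(pre), replace = TRUE,
                   prob = c(0.85, 0.15))
    syn_gp <- tibble(pre_id = pre, post_id = post, size_um2 = size,
                     post_compartment = comp)
    area_i <- rowsum(size * to_gpi, pre)[, 1]
    area_t <- rowsum(size, pre)[, 1]
    cnt_i <- rowsum(as.numeric(to_gpi), pre)[, 1]
    cnt_t <- rowsum(rep(1, length(pre)), pre)[, 1]
    key <- as.character(msn_ids)
    gp_truth <- tibble(
      cell_id = msn_ids,
      true_gp_ratio_area = unname((area_i / area_t)[key]),
      true_gp_ratio_count = unname((cnt_i / cnt_t)[key]),
      forced_selective = msn_ids %in% forced_ids)
  }

  # --- other type-to-type projections -----------------------------------
  mix <- config$projection_mix
  mix <- mix[mix$pre_type %in% types & mix$post_type %in% types, ,
             drop = FALSE]
  syn_mix <- NULL
  if (nrow(mix)) {
    parts <- purrr::pmap(mix, function(pre_type, post_type, syn_per_pre,
                                       area_mean_um2) {
      pres <- cell_id[types == pre_type]
      posts <- cell_id[types == post_type]
      lam <- if (is.na(syn_per_pre)) axon_len[pres] / 10 else
        rep(syn_per_pre, length(pres))
      k <- rpois(length(pres), lam)
      if (!sum(k)) return(NULL)
      pre <- rep(pres, k)
      post <- sample(posts, sum(k), replace = TRUE)
      mu <- log(area_mean_um2) - config$area_sdlog^2 / 2
      spiny <- post_type == "MSN"
      comp <- if (spiny) {
        sample(c("spine_head", "spine_neck", "shaft", "soma"), sum(k),
               replace = TRUE, prob = c(0.55, 0.1, 0.3, 0.05))
      } else {
        sample(c("shaft", "soma"), sum(k), replace = TRUE,
               prob = c(0.8, 0.2))
      }
      tibble(pre_id = pre, post_id = post,
             size_um2 = rlnorm(sum(k), mu, config$area_sdlog),
             post_compartment = comp)
    })
    syn_mix <- bind_rows(parts)
  }

  synapses <- bind_rows(syn_gp, syn_mix)
  if (is.null(synapses) || !nrow(synapses)) {
    synapses <- tibble(pre_id = integer(), post_id = integer(),
                       size_um2 = double(), post_compartment = character())
  }
  n_syn <- nrow(synapses)
  if (config$qc_probability_mode && n_syn) {
    pick <- runif(n_syn) < 0.7
    prob <- numeric(n_syn)
    prob[pick] <- stats::rbeta(sum(pick), 9, 1.5)
    prob[!pick] <- stats::rbeta(sum(!pick), 1.2, 4)
    synapses$size_um2 <- synapses$size_um2 * rlnorm(n_syn, -0.6, 0.8)
    pre_comp <- sample(c("axon", "dendrite", "unknown"), n_syn,
                       replace = TRUE, prob = c(0.9, 0.05, 0.05))
  } else {
    prob <- rep(1, n_syn)
    pre_comp <- rep("axon", n_syn)
  }
  # synapse positions: near the postsynaptic soma centre
  post_row <- match(synapses$post_id, cell_id)
  jit <- matrix(runif(3 * n_syn, -1, 1), ncol = 3) * 2000
  synapses <- tibble(
    synapse_id = seq_len(n_syn),
    pre_id = synapses$pre_id, post_id = synapses$post_id,
    probability = prob,
    mesh_area_um2 = synapses$size_um2 * 2,
    x_nm = centers[post_row, 1] + jit[, 1],
    y_nm = centers[post_row, 2] + jit[, 2],
    z_nm = centers[post_row, 3] + jit[, 3],
    post_compartment = synapses$post_compartment,
    pre_compartment = pre_comp)

  cells <- tibble(cell_id = cell_id, type = types, is_fragment = is_frag)
  dataset <- connectome(cells = cells, synapses = synapses,
                        organelles = organelles, skeletons = skeletons,
                        soma_vertices = soma_vertices,
                        spine_counts = spine_counts, geometry = geom)

  gt <- tibble(
    cell_id = cell_id, type = types, is_fragment = is_frag,
    soma_radius_um = ifelse(is_frag, NA_real_, soma_r),
    axon_length_um = lens$axon_um,
    dendrite_length_um = lens$dendrite_um,
    axon_median_radius_um = axon_rad,
    axon_mito_density = ax_mito,
    dendrite_mito_density = ifelse(is_frag, NA_real_, de_mito),
    spine_density = ifelse(is_frag, NA_real_,
                           spine_counts$n_spines[match(cell_id,
                             spine_counts$cell_id)] /
                             ifelse(lens$dendrite_um > 0,
                                    lens$dendrite_um, NA_real_)),
    myelin_fraction = ifelse(lens$axon_um > 0,
                             lens$myelinated_axon_um / lens$axon_um,
                             NA_real_),
    near_boundary = clipped)
  if (!is.null(gp_truth)) {
    gt <- left_join(gt, gp_truth, by = "cell_id")
    gt$forced_selective[is.na(gt$forced_selective)] <- FALSE
  } else {
    gt$true_gp_ratio_area <- NA_real_
    gt$true_gp_ratio_count <- NA_real_
    gt$forced_selective <- FALSE
  }
  attr(gt, "config") <- config
  list(dataset = dataset, ground_truth = gt)
}
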