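#' Soma radius from a soma vertex cloud
#'
#' The soma centre is the componentwise median of the soma surface
#' vertices; the radius is the median Euclidean distance from the vertices
#' to that centre. This median-of-distances estimate is translation- and
#' rotation-invariant and robust to uneven vertex sampling.
#'
#' @param soma_vertices Vertex tibble of one cell (`x_nm`, `y_nm`,
#'   `z_nm`).
#' @return Radius in micrometres; `NA` for an empty vertex set (an
#'   undefined feature, not zero).
#' @export
soma_radius <- function(soma_vertices) {
  if (!nrow(soma_vertices)) return(NA_real_)
  cx <- median(soma_vertices$x_nm)
  cy <- median(soma_vertices$y_nm)
  cz <- median(soma_vertices$z_nm)
  median(sqrt((soma_vertices$x_nm - cx)^2 + (soma_vertices$y_nm - cy)^2 +
                (soma_vertices$z_nm - cz)^2)) / 1000
}

#' Median axon radius
#'
#' Median of the stored node radii over axon-labelled skeleton nodes. With
#' an even node count the mean of the two middle values is used.
#'
#' @param skeleton Skeleton node tibble of one cell.
#' @return Radius in micrometres; `NA` when the cell has no axon nodes.
#' @export
axon_median_radius <- function(skeleton) {
  r <- skeleton$radius_um[skeleton$compartment == "axon"]
  if (!length(r)) return(NA_real_)
  median(r)
}

#' Map organelles to skeleton compartments
#'
#' Assigns each organelle the compartment label of the nearest skeleton
#' node to its representative coordinate (the whole organelle goes to one
#' compartment, an acknowledged approximation for organelles straddling a
#' compartment boundary). Exact distance ties are broken towards the
#' lowest `node_id`.
#'
#' @param skeleton Skeleton node tibble of one cell.
#' @param organelles Organelle tibble (rows owned by that cell).
#' @return `organelles` with added columns `compartment` and
#'   `nearest_node_id`.
#' @export
organelle_compartment_map <- function(skeleton, organelles) {
  if (!nrow(skeleton)) abort("Cannot map organelles to an empty skeleton.")
  skeleton <- dplyr::arrange(skeleton, .data$node_id)
  if (!nrow(organelles)) {
    organelles$compartment <- character()
    organelles$nearest_node_id <- integer()
    return(organelles)
  }
  sx <- skeleton$x_nm; sy <- skeleton$y_nm; sz <- skeleton$z_nm
  nearest <- vapply(seq_len(nrow(organelles)), function(i) {
    d2 <- (sx - organelles$x_nm[i])^2 + (sy - organelles$y_nm[i])^2 +
      (sz - organelles$z_nm[i])^2
    which.min(d2)  # first minimum = lowest node_id after sorting
  }, integer(1))
  organelles$compartment <- skeleton$compartment[nearest]
  organelles$nearest_node_id <- skeleton$node_id[nearest]
  organelles
}

#' Mitochondrial volume density of a compartment
#'
#' Sum of mitochondrial voxel counts times the voxel volume (default
#' 10 x 10 x 25 nm), over mitochondria mapped to the compartment's nearest
#' skeleton nodes, divided by the compartment's skeleton path length.
#'
#' @param skeleton Skeleton node tibble of one cell.
#' @param organelles Organelle tibble of that cell.
#' @param compartment `"axon"`, `"dendrite"` or `"soma"`.
#' @param geometry A [dataset_geometry()] supplying the voxel size.
#' @return Density in um^3 per um of path length; `NA` when the
#'   compartment path length is zero (undefined feature).
#' @export
mito_volume_density <- function(skeleton, organelles,
                                compartment = "axon",
                                geometry = dataset_geometry()) {
  len <- path_length(skeleton, compartment)
  if (len <= 0) return(NA_real_)
  mito <- organelles[organelles$kind == "mitochondrion", , drop = FALSE]
  if (!nrow(mito)) return(0)
  mapped <- organelle_compartment_map(skeleton, mito)
  vol <- sum(mapped$voxel_count[mapped$compartment == compartment]) *
    voxel_volume_um3(geometry)
  vol / len
}

#' Dendritic spine density
#'
#' Number of annotated spines divided by the dendritic path length. Spine
#' annotations are an input column (the synthetic generator emits them);
#' no spine detection is performed.
#'
#' @param n_spines Spine count of the cell.
#' @param skeleton Skeleton node tibble of the cell.
#' @return Spines per micrometre; `NA` when the dendritic length is zero.
#' @export
spine_density <- function(n_spines, skeleton) {
  len <- path_length(skeleton, "dendrite")
  if (len <= 0) return(NA_real_)
  n_spines / len
}

#' Axonal myelination fraction
#'
#' Myelinated axonal path length (edges whose both endpoints are flagged
#' myelinated) divided by total axonal path length.
#'
#' @param skeleton Skeleton node tibble of the cell.
#' @return Fraction in `[0, 1]`; `NA` when the axonal length is zero.
#' @export
myelin_fraction <- function(skeleton) {
  e <- skeleton_edges(skeleton)
  ax <- e$compartment == "axon" & e$parent_compartment == "axon"
  tot <- sum(e$length_um[ax])
  if (tot <= 0) return(NA_real_)
  sum(e$length_um[ax & e$myelin_edge]) / tot
}

frustum_surface <- function(r1, r2, len) {
  pi * (r1 + r2) * sqrt(len^2 + (r1 - r2)^2)
}

frustum_volume <- function(r1, r2, len) {
  pi * len * (r1^2 + r1 * r2 + r2^2) / 3
}

#' The morphometric feature set
#'
#' Names of the per-cell features computed by [morphometry_features()] and
#' used by default for embeddings: compartment path lengths, frustum-based
#' surface areas and cell volume, median radii, soma size, mitochondrial
#' and vesicle-cloud volume densities, per-compartment synaptic densities
#' (synaptic area per surface area), spine density and myelin fraction.
#'
#' @return Character vector of 18 feature names.
#' @export
morpho_feature_set <- function() {
  c("axon_length_um", "axon_surface_um2", "axon_median_radius_um",
    "dendrite_length_um", "dendrite_surface_um2",
    "dendrite_median_radius_um", "soma_diameter_um", "soma_surface_um2",
    "cell_volume_um3", "axon_mito_density", "dendrite_mito_density",
    "soma_mito_density", "vesicle_density", "syn_density_axon",
    "syn_density_dendrite", "syn_density_soma", "spine_density_per_um",
    "myelin_fraction")
}

#' Per-cell morphometric features
#'
#' Computes the full feature table for every cell of a connectome:
#' skeleton path lengths per compartment, soma radius/diameter from the
#' soma vertex cloud, median node radii, frustum (truncated-cone) surface
#' areas and volumes of the neurites plus a spherical soma, mitochondrial
#' volume densities per compartment (somatic density is relative to the
#' estimated spherical soma volume), vesicle-cloud volume density along
#' the axon, synaptic area per compartment surface area, spine density
#' and axonal myelin fraction. Undefined features (empty compartments)
#' are `NA`, never zero.
#'
#' @param x A [connectome()].
#' @return A tibble with one row per cell: `cell_id`, `type` and the
#'   columns of [morpho_feature_set()] plus `soma_radius_um`.
#' @export
morphometry_features <- function(x) {
  stopifnot(inherits(x, "connectome"))
  lens <- compartment_lengths(x$skeletons)
  e <- skeleton_edges(x$skeletons)
  sk <- x$skeletons

  rad <- sk |>
    dplyr::group_by(.data$cell_id) |>
    summarise(
      axon_median_radius_um = if (any(.data$compartment == "axon"))
        median(.data$radius_um[.data$compartment == "axon"]) else NA_real_,
      dendrite_median_radius_um = if (any(.data$compartment == "dendrite"))
        median(.data$radius_um[.data$compartment == "dendrite"]) else
          NA_real_)

  key <- paste(sk$cell_id, sk$node_id)
  er1 <- sk$radius_um[match(paste(e$cell_id, e$node_id), key)]
  er2 <- sk$radius_um[match(paste(e$cell_id, e$parent_id), key)]
  surf <- tibble(cell_id = e$cell_id, compartment = e$compartment,
                 same = e$compartment == e$parent_compartment,
                 s = frustum_surface(er1, er2, e$length_um),
                 v = frustum_volume(er1, er2, e$length_um)) |>
    filter(.data$same, .data$compartment %in% c("axon", "dendrite")) |>
    dplyr::group_by(.data$cell_id, .data$compartment) |>
    summarise(s = sum(.data$s), v = sum(.data$v), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = c("s", "v"), values_fill = 0)
  for (cmp in c("s_axon", "v_axon", "s_dendrite", "v_dendrite")) {
    if (!cmp %in% names(surf)) surf[[cmp]] <- 0
  }

  soma <- x$soma_vertices |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ tibble(soma_radius_um = soma_radius(.x))) |>
    ungroup()

  vox <- voxel_volume_um3(x$geometry)
  org <- x$organelles
  org_comp <- if (nrow(org)) {
    split(org, org$owner_cell_id) |>
      purrr::imap_dfr(function(o, id) {
        skc <- sk[sk$cell_id == as.numeric(id), , drop = FALSE]
        organelle_compartment_map(skc, o)
      })
  } else {
    org$compartment <- character()
    org
  }
  org_sum <- org_comp |>
    dplyr::group_by(.data$owner_cell_id, .data$kind, .data$compartment) |>
    summarise(vol = sum(.data$voxel_count) * vox, .groups = "drop")
  pick_org <- function(kind, compartment) {
    v <- org_sum$vol[org_sum$kind == kind &
                       org_sum$compartment == compartment]
    id <- org_sum$owner_cell_id[org_sum$kind == kind &
                                  org_sum$compartment == compartment]
    setNames(v, id)
  }

  syn <- x$synapses
  syn_out <- rowsum(syn$size_um2, syn$pre_id)
  post_cmp <- dplyr::case_when(
    syn$post_compartment %in% c("shaft", "spine_neck", "spine_head") ~
      "dendrite",
    syn$post_compartment == "soma" ~ "soma",
    TRUE ~ "other")
  syn_in_d <- rowsum(syn$size_um2[post_cmp == "dendrite"],
                     syn$post_id[post_cmp == "dendrite"])
  syn_in_s <- rowsum(syn$size_um2[post_cmp == "soma"],
                     syn$post_id[post_cmp == "soma"])
  lut <- function(tab, id) {
    if (is.null(dim(tab)) || !nrow(tab)) return(rep(0, length(id)))
    v <- tab[, 1][as.character(id)]
    ifelse(is.na(v), 0, v)
  }

  out <- x$cells |>
    left_join(lens, by = "cell_id") |>
    left_join(rad, by = "cell_id") |>
    left_join(soma, by = "cell_id") |>
    left_join(x$spine_counts, by = "cell_id")

  mito_ax <- pick_org("mitochondrion", "axon")
  mito_de <- pick_org("mitochondrion", "dendrite")
  mito_so <- pick_org("mitochondrion", "soma")
  ves_ax <- pick_org("vesicle_cloud", "axon")
  g0 <- function(v) ifelse(is.na(v), 0, v)
  id_chr <- as.character(out$cell_id)
  surf_m <- surf[match(out$cell_id, surf$cell_id), ]
  soma_surf <- 4 * pi * out$soma_radius_um^2
  soma_vol <- (4 / 3) * pi * out$soma_radius_um^3

  tibble(
    cell_id = out$cell_id,
    type = out$type,
    soma_radius_um = out$soma_radius_um,
    axon_length_um = g0(out$axon_um),
    axon_surface_um2 = g0(surf_m$s_axon),
    axon_median_radius_um = out$axon_median_radius_um,
    dendrite_length_um = g0(out$dendrite_um),
    dendrite_surface_um2 = g0(surf_m$s_dendrite),
    dendrite_median_radius_um = out$dendrite_median_radius_um,
    soma_diameter_um = 2 * out$soma_radius_um,
    soma_surface_um2 = soma_surf,
    cell_volume_um3 = g0(surf_m$v_axon) + g0(surf_m$v_dendrite) +
      g0(soma_vol),
    axon_mito_density = ifelse(g0(out$axon_um) > 0,
                               g0(mito_ax[id_chr]) / out$axon_um, NA_real_),
    dendrite_mito_density = ifelse(g0(out$dendrite_um) > 0,
                                   g0(mito_de[id_chr]) / out$dendrite_um,
                                   NA_real_),
    soma_mito_density = ifelse(g0(soma_vol) > 0,
                               g0(mito_so[id_chr]) / soma_vol, NA_real_),
    vesicle_density = ifelse(g0(out$axon_um) > 0,
                             g0(ves_ax[id_chr]) / out$axon_um, NA_real_),
    syn_density_axon = ifelse(axon_surface_um2 > 0,
                              lut(syn_out, cell_id) / axon_surface_um2,
                              NA_real_),
    syn_density_dendrite = ifelse(dendrite_surface_um2 > 0,
                                  lut(syn_in_d, cell_id) /
                                    dendrite_surface_um2, NA_real_),
    syn_density_soma = ifelse(soma_surf > 0,
                              lut(syn_in_s, cell_id) / soma_surf,
                              NA_real_),
    spine_density_per_um = ifelse(g0(out$dendrite_um) > 0,
                                  g0(out$n_spines) / out$dendrite_um,
                                  NA_real_),
    myelin_fraction = ifelse(g0(out$axon_um) > 0,
                             g0(out$myelinated_axon_um) / out$axon_um,
                             NA_real_))
}

#' Standardise features and project onto principal components
#'
#' Each selected feature is standardised to a z-score using the population
#' standard deviation, then the rows are projected onto the leading
#' principal components. The sign of each component is fixed so that the
#' feature with the largest absolute loading has a positive loading. Rows
#' containing undefined features are dropped with an audit count.
#'
#' @param features Feature tibble (e.g. from [morphometry_features()]).
#' @param feature_subset Character vector of feature columns; defaults to
#'   the classical four-feature pallidal set.
#' @param n_components Number of components to return.
#' @return Tibble `cell_id` (plus `type` if present) and `PC1..PCk`, of
#'   class `morpho_embedding`, with attributes `loadings`, `audit`,
#'   `feature_subset`.
#' @export
zscore_embed <- function(features,
                         feature_subset = c("axon_mito_density",
                                            "axon_median_radius_um",
                                            "myelin_fraction",
                                            "soma_diameter_um"),
                         n_components = 1) {
  missing <- setdiff(feature_subset, names(features))
  if (length(missing)) {
    abort(sprintf("Unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(features[, feature_subset, drop = FALSE])
  ok <- complete.cases(m)
  dropped <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 2) abort("Need at least two cells with defined features.")
  mu <- colMeans(m)
  pop_sd <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(pop_sd == 0)) {
    abort(sprintf("Constant feature(s): %s",
                  paste(feature_subset[pop_sd == 0], collapse = ", ")))
  }
  z <- sweep(sweep(m, 2, mu), 2, pop_sd, "/")
  n_components <- min(n_components, ncol(z))
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- z %*% rot
  out <- tibble(cell_id = features$cell_id[ok])
  if ("type" %in% names(features)) out$type <- features$type[ok]
  for (j in seq_len(ncol(scores))) out[[paste0("PC", j)]] <- scores[, j]
  structure(out,
            class = c("morpho_embedding", class(out)),
            loadings = rot,
            audit = tibble(criterion = c("embedded", "undefined_feature"),
                           n = c(sum(ok), dropped)),
            feature_subset = feature_subset)
}

#' Interneuron classification thresholds
#'
#' The published four thresholds separating the three local interneuron
#' classes, together with the side (above/below) each class must fall on
#' for every feature. A cell is assigned a class only if it lies strictly
#' on that class's side of all four thresholds; cells on a threshold or
#' with mixed sides stay unassigned.
#'
#' @param axon_mito_density Axonal mitochondrial volume density threshold
#'   (um^3/um).
#' @param axon_median_radius_um Axon median radius threshold (um).
#' @param soma_radius_um Soma radius threshold (um), on the scale of the
#'   median-vertex-distance soma size estimate.
#' @param spine_density_per_um Spine density threshold (1/um).
#' @param side_table Tibble `class`, `feature`, `side`
#'   (`"above"`/`"below"`) covering all three classes and four features.
#' @return A list of class `int_thresholds`.
#' @export
int_thresholds <- function(axon_mito_density = 0.025,
                           axon_median_radius_um = 0.11,
                           soma_radius_um = 11.5,
                           spine_density_per_um = 0.025,
                           side_table = default_int_side_table()) {
  need <- tidyr::expand_grid(
    class = c("INT1", "INT2", "INT3"),
    feature = c("axon_mito_density", "axon_median_radius_um",
                "soma_radius_um", "spine_density_per_um"))
  if (nrow(anti_join(need, side_table, by = c("class", "feature")))) {
    abort("side_table must cover all three classes x four features.")
  }
  if (!all(side_table$side %in% c("above", "below"))) {
    abort("side_table sides must be 'above' or 'below'.")
  }
  structure(
    list(thresholds = c(axon_mito_density = axon_mito_density,
                        axon_median_radius_um = axon_median_radius_um,
                        soma_radius_um = soma_radius_um,
                        spine_density_per_um = spine_density_per_um),
         side_table = side_table),
    class = "int_thresholds")
}

#' @rdname int_thresholds
#' @export
default_int_side_table <- function() {
  tibble::tribble(
    ~class, ~feature, ~side,
    "INT1", "axon_mito_density", "below",
    "INT1", "axon_median_radius_um", "below",
    "INT1", "soma_radius_um", "above",
    "INT1", "spine_density_per_um", "below",
    "INT2", "axon_mito_density", "below",
    "INT2", "axon_median_radius_um", "below",
    "INT2", "soma_radius_um", "below",
    "INT2", "spine_density_per_um", "above",
    "INT3", "axon_mito_density", "above",
    "INT3", "axon_median_radius_um", "above",
    "INT3", "soma_radius_um", "above",
    "INT3", "spine_density_per_um", "below")
}

#' Threshold-based interneuron classification
#'
#' Assigns each cell to INT1, INT2 or INT3 when all four features lie
#' strictly on the class's configured side of the thresholds; any cell on
#' a threshold value, with mixed sides, or with an undefined feature is
#' `"unassigned"`.
#'
#' @param features Feature tibble with the four threshold features (e.g.
#'   from [morphometry_features()]).
#' @param thresholds An [int_thresholds()].
#' @return `features` with an added `int_class` column.
#' @export
classify_int <- function(features, thresholds = int_thresholds()) {
  stopifnot(inherits(thresholds, "int_thresholds"))
  feats <- names(thresholds$thresholds)
  missing <- setdiff(feats, names(features))
  if (length(missing)) {
    abort(sprintf("Feature(s) missing from input: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- as.matrix(features[, feats, drop = FALSE])
  cls <- rep("unassigned", nrow(features))
  for (class in c("INT1", "INT2", "INT3")) {
    st <- thresholds$side_table[thresholds$side_table$class == class, ]
    ok <- rep(TRUE, nrow(features))
    for (i in seq_len(nrow(st))) {
      thr <- thresholds$thresholds[[st$feature[i]]]
      v <- m[, st$feature[i]]
      ok <- ok & !is.na(v) &
        if (st$side[i] == "above") v > thr else v < thr
    }
    cls[ok] <- class
  }
  features$int_class <- cls
  features
}
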