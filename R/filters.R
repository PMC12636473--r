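#' Quality-control filter configuration
#'
#' Thresholds used to restrict connectivity analyses to reliable synapses
#' and sufficiently complete reconstructions: a minimum classifier-assigned
#' synapse probability of 0.6, a minimum synapse size of 0.1 um^2, only
#' axo-dendritic and axo-somatic synapse geometries, at least 200 um of
#' both axonal and dendritic skeleton for intrinsic neurons, at least
#' 50 um of total skeleton for extrinsic axon fragments, and a 7 um
#' dataset-boundary margin for dendrite completeness. All thresholds are
#' inclusive (`>=`).
#'
#' @param min_synapse_probability,min_synapse_size_um2 Synapse-level
#'   thresholds.
#' @param min_compartment_length_um Per-compartment (axon and dendrite)
#'   completeness threshold for intrinsic neurons.
#' @param min_fragment_length_um Total-length threshold for projecting
#'   axon fragments; sensitivity analyses conventionally use 0, 50 or 200.
#' @param boundary_margin_um Dendrite boundary margin.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_synapse_probability = 0.6,
                          min_synapse_size_um2 = 0.1,
                          min_compartment_length_um = 200,
                          min_fragment_length_um = 50,
                          boundary_margin_um = 7) {
  vals <- c(min_synapse_probability, min_synapse_size_um2,
            min_compartment_length_um, min_fragment_length_um,
            boundary_margin_um)
  if (any(vals < 0)) abort("All filter thresholds must be >= 0.")
  structure(
    list(min_synapse_probability = min_synapse_probability,
         min_synapse_size_um2 = min_synapse_size_um2,
         min_compartment_length_um = min_compartment_length_um,
         min_fragment_length_um = min_fragment_length_um,
         boundary_margin_um = boundary_margin_um),
    class = "filter_config")
}

#' Retrieve the audit of a filtering step
#'
#' Every filter returns its result with an `audit` attribute summarising
#' per-criterion exclusion counts; exclusions are attributed to the first
#' failing criterion in the documented order, so the counts plus the
#' retained count always sum to the input count.
#'
#' @param x A filtered table.
#' @return The audit tibble.
#' @export
qc_audit <- function(x) attr(x, "audit")

#' Filter synapses
#'
#' Retains a synapse iff its probability and size meet the configured
#' minima (inclusive), its presynaptic compartment is an axon and its
#' postsynaptic compartment is dendritic (shaft, spine neck, spine head)
#' or somatic. Rows whose postsynaptic compartment label is not in the
#' known vocabulary are warned about and excluded as unknown geometry,
#' counted separately. Exclusions are attributed to the first failing
#' criterion in the order probability, size, geometry, unknown
#' compartment.
#'
#' @param synapses Synapse tibble (see [connectome()]).
#' @param config A [filter_config()].
#' @return The retained rows, with an `audit` attribute (see
#'   [qc_audit()]).
#' @export
filter_synapses <- function(synapses, config = filter_config()) {
  synapses <- as_tibble(synapses)
  known_post <- c("shaft", "spine_neck", "spine_head", "soma", "axon",
                  "unknown")
  ok_post <- c("shaft", "spine_neck", "spine_head", "soma")
  pre <- if ("pre_compartment" %in% names(synapses)) {
    synapses$pre_compartment
  } else rep("axon", nrow(synapses))

  unknown <- !(synapses$post_compartment %in% known_post) |
    !(pre %in% c("axon", "dendrite", "soma", "unknown"))
  if (any(unknown)) {
    warn(sprintf("%d synapse(s) with unknown compartment label excluded.",
                 sum(unknown)))
  }
  fail_prob <- synapses$probability < config$min_synapse_probability
  fail_size <- synapses$size_um2 < config$min_synapse_size_um2
  fail_geom <- !(pre == "axon" & synapses$post_compartment %in% ok_post)

  first_fail <- rep("retained", nrow(synapses))
  first_fail[unknown & first_fail == "retained"] <- "unknown_compartment"
  first_fail[fail_prob & first_fail == "retained"] <- "probability"
  first_fail[fail_size & first_fail == "retained"] <- "size"
  first_fail[fail_geom & first_fail == "retained"] <- "geometry"

  out <- synapses[first_fail == "retained", , drop = FALSE]
  audit <- tibble(
    criterion = c("retained", "probability", "size", "geometry",
                  "unknown_compartment"),
    n = c(sum(first_fail == "retained"), sum(first_fail == "probability"),
          sum(first_fail == "size"), sum(first_fail == "geometry"),
          sum(first_fail == "unknown_compartment")))
  attr(out, "audit") <- audit
  out
}

#' Filter intrinsic neurons for completeness
#'
#' An intrinsic neuron is retained iff its skeleton has at least one node
#' of each of the three compartments and both its axonal and dendritic
#' path lengths reach the configured per-compartment minimum (inclusive).
#' Fragments and non-intrinsic types are excluded with a reason code.
#'
#' @param cells,skeletons Tables of a [connectome()] (or pass the
#'   connectome itself as `cells`).
#' @param config A [filter_config()].
#' @return Tibble of retained rows (`cell_id`, `type`) with an `audit`
#'   attribute; the audit holds one row per reason code.
#' @export
filter_complete_cells <- function(cells, skeletons = NULL,
                                  config = filter_config()) {
  if (inherits(cells, "connectome")) {
    skeletons <- cells$skeletons
    cells <- cells$cells
  }
  lens <- compartment_lengths(skeletons)
  has <- tibble(cell_id = unique(skeletons$cell_id)) |>
    left_join(
      skeletons |>
        dplyr::distinct(.data$cell_id, .data$compartment) |>
        mutate(present = TRUE) |>
        tidyr::pivot_wider(names_from = "compartment",
                           values_from = "present",
                           values_fill = FALSE),
      by = "cell_id")
  for (cmp in c("axon", "dendrite", "soma")) {
    if (!cmp %in% names(has)) has[[cmp]] <- FALSE
  }
  d <- cells |>
    left_join(lens, by = "cell_id") |>
    left_join(has[, c("cell_id", "axon", "dendrite", "soma")],
              by = "cell_id") |>
    mutate(across(all_of(c("axon_um", "dendrite_um")),
                  ~ tidyr::replace_na(.x, 0)),
           across(all_of(c("axon", "dendrite", "soma")),
                  ~ tidyr::replace_na(.x, FALSE)))
  reason <- dplyr::case_when(
    !(d$type %in% intrinsic_types()) | d$is_fragment ~ "not_intrinsic",
    !(d$axon & d$dendrite & d$soma) ~ "missing_compartment",
    d$axon_um < config$min_compartment_length_um ~ "short_axon",
    d$dendrite_um < config$min_compartment_length_um ~ "short_dendrite",
    TRUE ~ "retained")
  out <- d[reason == "retained", c("cell_id", "type"), drop = FALSE]
  audit <- tibble(criterion = c("retained", "not_intrinsic",
                                "missing_compartment", "short_axon",
                                "short_dendrite")) |>
    mutate(n = unname(vapply(.data$criterion,
                             function(r) sum(reason == r), integer(1))))
  attr(out, "audit") <- audit
  out
}

#' Filter projecting-axon fragments by total skeleton length
#'
#' Extrinsic axon fragments (HVC, LMAN, DA classes) are retained iff their
#' total skeleton length reaches `min_length_um` (inclusive). The default
#' comes from the [filter_config()]; pass 0 or 200 for the conventional
#' sensitivity modes.
#'
#' @param cells,skeletons Tables of a [connectome()] (or the connectome as
#'   `cells`).
#' @param config A [filter_config()].
#' @param min_length_um Threshold override in micrometres.
#' @return Tibble of retained fragments (`cell_id`, `type`,
#'   `total_um`) with an `audit` attribute.
#' @export
filter_projecting_fragments <- function(cells, skeletons = NULL,
                                        config = filter_config(),
                                        min_length_um =
                                          config$min_fragment_length_um) {
  if (inherits(cells, "connectome")) {
    skeletons <- cells$skeletons
    cells <- cells$cells
  }
  frags <- cells[cells$type %in% projecting_types(), , drop = FALSE]
  lens <- compartment_lengths(skeletons)
  d <- frags |>
    left_join(lens[, c("cell_id", "total_um")], by = "cell_id") |>
    mutate(total_um = tidyr::replace_na(.data$total_um, 0))
  keep <- d$total_um >= min_length_um
  out <- d[keep, c("cell_id", "type", "total_um"), drop = FALSE]
  attr(out, "audit") <- tibble(
    criterion = c("retained", "short_fragment"),
    n = c(sum(keep), sum(!keep)))
  out
}

#' Flag cells whose dendrite approaches the dataset boundary
#'
#' A cell is flagged iff any dendrite-labelled skeleton node lies within
#' the boundary margin of any face of the dataset bounding box. Nodes
#' outside the box are treated as near-boundary (with a warning). Flagged
#' cells are conventionally excluded from dendrite-complete analyses.
#'
#' @param skeletons Skeleton table of a [connectome()] (or the connectome).
#' @param geometry A [dataset_geometry()]; taken from the connectome when
#'   one is passed.
#' @return Tibble `cell_id`, `near_boundary`.
#' @export
dendrite_near_boundary <- function(skeletons, geometry = NULL) {
  if (inherits(skeletons, "connectome")) {
    geometry <- geometry %||% skeletons$geometry
    skeletons <- skeletons$skeletons
  }
  stopifnot(inherits(geometry, "dataset_geometry"))
  all_ids <- unique(skeletons$cell_id)
  dn <- skeletons[skeletons$compartment == "dendrite", , drop = FALSE]
  pos <- cbind(dn$x_nm, dn$y_nm, dn$z_nm)
  margin_nm <- geometry$boundary_margin_um * 1000
  lo <- matrix(geometry$bbox_min_nm, nrow(dn), 3, byrow = TRUE)
  hi <- matrix(geometry$bbox_max_nm, nrow(dn), 3, byrow = TRUE)
  outside <- rowSums(pos < lo | pos > hi) > 0
  if (any(outside)) {
    warn(sprintf(
      "%d dendrite node(s) outside the dataset box; treated as near-boundary.",
      sum(outside)))
  }
  near <- outside |
    rowSums(pos - lo < margin_nm | hi - pos < margin_nm) > 0
  flagged <- unique(dn$cell_id[near])
  tibble(cell_id = all_ids, near_boundary = all_ids %in% flagged)
}
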