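#' Per-cell partner-overlap ratios between two cell types
#'
#' For each cell of `type_a`, considers its presynaptic partners of
#' `type_b` (incoming side) and postsynaptic partners of `type_b`
#' (outgoing side). The incoming overlap ratio is the summed synaptic
#' area received from partners that appear on both sides, divided by the
#' total area received from `type_b`; the outgoing ratio is the analogous
#' quantity on the output side. Cells that do not both receive from and
#' project to `type_b` are excluded with an audit count.
#'
#' @param pairs Pair-connection tibble from [pair_connections()].
#' @param cells Cells tibble or [connectome()].
#' @param type_a Focal cell type.
#' @param type_b Partner cell type.
#' @return Tibble `cell_id`, `incoming_ratio`, `outgoing_ratio`,
#'   `strongest_in_partner`, `strongest_out_partner`,
#'   `strongest_partner_reciprocal`; audit attribute counts scored and
#'   excluded cells.
#' @export
overlap_ratios <- function(pairs, cells, type_a, type_b) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  pre_t <- cell_type_of(cells, pairs$pre_id)
  post_t <- cell_type_of(cells, pairs$post_id)
  incoming <- pairs[pre_t == type_b & post_t == type_a, , drop = FALSE]
  outgoing <- pairs[pre_t == type_a & post_t == type_b, , drop = FALSE]
  eligible <- cells$cell_id[cells$type == type_a]
  scored <- intersect(intersect(unique(incoming$post_id), eligible),
                      unique(outgoing$pre_id))
  res <- purrr::map_dfr(scored, function(id) {
    inc <- incoming[incoming$post_id == id, , drop = FALSE]
    out <- outgoing[outgoing$pre_id == id, , drop = FALSE]
    both <- intersect(inc$pre_id, out$post_id)
    s_in <- inc$pre_id[order(-inc$summed_area_um2, inc$pre_id)][1]
    s_out <- out$post_id[order(-out$summed_area_um2, out$post_id)][1]
    tibble(
      cell_id = id,
      incoming_ratio = sum(inc$summed_area_um2[inc$pre_id %in% both]) /
        sum(inc$summed_area_um2),
      outgoing_ratio = sum(out$summed_area_um2[out$post_id %in% both]) /
        sum(out$summed_area_um2),
      strongest_in_partner = s_in,
      strongest_out_partner = s_out,
      strongest_partner_reciprocal = s_in == s_out)
  })
  if (!nrow(res)) {
    res <- tibble(cell_id = eligible[0], incoming_ratio = double(),
                  outgoing_ratio = double(),
                  strongest_in_partner = eligible[0],
                  strongest_out_partner = eligible[0],
                  strongest_partner_reciprocal = logical())
  }
  attr(res, "audit") <- tibble(
    criterion = c("scored", "excluded_one_sided"),
    n = c(length(scored), length(eligible) - length(scored)))
  res
}

#' Strongest-partner reciprocity of one cell
#'
#' `TRUE` iff the partner providing the largest incoming summed synaptic
#' area is also the partner receiving the largest outgoing summed area.
#' Exact-area ties are broken towards the lower cell id.
#'
#' @param pairs Pair-connection tibble.
#' @param cells Cells tibble or [connectome()].
#' @param cell_id Focal cell id.
#' @param partner_type Partner cell type.
#' @return Logical flag; errors if the cell lacks synapses in either
#'   direction with the partner type.
#' @export
strongest_partner_reciprocity <- function(pairs, cells, cell_id,
                                          partner_type) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  type_a <- cell_type_of(cells, cell_id)
  r <- overlap_ratios(pairs, cells, type_a, partner_type)
  row <- r[r$cell_id == cell_id, , drop = FALSE]
  if (!nrow(row)) {
    abort(sprintf(
      "Cell %s does not both receive from and project to type %s.",
      cell_id, partner_type))
  }
  row$strongest_partner_reciprocal
}

#' Population reciprocity summary for a type pairing
#'
#' Runs [overlap_ratios()] in both directions of an ordered type pair
#' (e.g. STN-GPi) and summarises each side by the median incoming and
#' outgoing overlap ratio and the fraction of cells whose strongest
#' incoming partner is also their strongest outgoing partner.
#'
#' @param pairs Pair-connection tibble.
#' @param cells Cells tibble or [connectome()].
#' @param type_a,type_b The two cell types.
#' @return An object of class `reciprocity_stats` with `per_cell` (both
#'   types, tagged by `type`) and `summary` tibbles.
#' @export
reciprocity_stats <- function(pairs, cells, type_a, type_b) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  a <- overlap_ratios(pairs, cells, type_a, type_b)
  b <- overlap_ratios(pairs, cells, type_b, type_a)
  a$type <- rep(type_a, nrow(a))
  b$type <- rep(type_b, nrow(b))
  per_cell <- bind_rows(a, b)
  summ <- function(r, type, partner, audit) {
    tibble(type = type, partner_type = partner,
           n_scored = audit$n[audit$criterion == "scored"],
           n_excluded = audit$n[audit$criterion == "excluded_one_sided"],
           median_incoming_ratio = if (nrow(r)) median(r$incoming_ratio)
             else NA_real_,
           median_outgoing_ratio = if (nrow(r)) median(r$outgoing_ratio)
             else NA_real_,
           reciprocal_fraction = if (nrow(r))
             mean(r$strongest_partner_reciprocal) else NA_real_)
  }
  structure(
    list(per_cell = per_cell,
         summary = bind_rows(summ(a, type_a, type_b, qc_audit(a)),
                             summ(b, type_b, type_a, qc_audit(b))),
         types = c(type_a, type_b)),
    class = "reciprocity_stats")
}

#' @export
print.reciprocity_stats <- function(x, ...) {
  cat(sprintf("<reciprocity_stats> %s <-> %s\n", x$types[1], x$types[2]))
  print(x$summary)
  invisible(x)
}
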