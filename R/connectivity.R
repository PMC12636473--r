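#' Aggregate synapses into pair connections
#'
#' One row per ordered presynaptic/postsynaptic cell pair with the synapse
#' count, summed synaptic area and a per-postsynaptic-compartment area
#' breakdown. The input is expected to be filtered already (see
#' [filter_synapses()]).
#'
#' @param synapses Synapse tibble.
#' @return Tibble `pre_id`, `post_id`, `n_synapses`, `summed_area_um2`,
#'   and `area_<compartment>` breakdown columns summing to the total.
#' @export
pair_connections <- function(synapses) {
  base <- tibble(pre_id = synapses$pre_id[0], post_id = synapses$post_id[0],
                 n_synapses = integer(), summed_area_um2 = double(),
                 area_shaft = double(), area_spine_neck = double(),
                 area_spine_head = double(), area_soma = double())
  if (!nrow(synapses)) return(base)
  wide <- synapses |>
    dplyr::group_by(.data$pre_id, .data$post_id) |>
    summarise(
      n_synapses = dplyr::n(),
      summed_area_um2 = sum(.data$size_um2),
      area_shaft = sum(.data$size_um2[.data$post_compartment == "shaft"]),
      area_spine_neck = sum(.data$size_um2[.data$post_compartment ==
                                             "spine_neck"]),
      area_spine_head = sum(.data$size_um2[.data$post_compartment ==
                                             "spine_head"]),
      area_soma = sum(.data$size_um2[.data$post_compartment == "soma"]),
      .groups = "drop")
  wide
}

#' Cell-type connectivity matrix
#'
#' Sums synaptic area (and synapse counts) from all cells of each
#' presynaptic type to all cells of each postsynaptic type, then
#' normalises: `"global"` divides by the total over the included types so
#' all entries sum to 1; `"output_rows"` divides each row by its sum
#' (outgoing preference of a type); `"input_columns"` divides each column
#' by its sum (input composition of a type). Denominators are computed
#' over the included type set only.
#'
#' @param pairs Pair-connection tibble from [pair_connections()].
#' @param cells Cells tibble (or a [connectome()]) mapping ids to types.
#' @param normalization One of `"global"`, `"output_rows"`,
#'   `"input_columns"`, `"none"`.
#' @param types Optional character vector restricting and ordering the
#'   type set; defaults to the types present among the pairs' endpoints.
#' @return An object of class `type_matrix` with elements `area` and
#'   `count` (normalised matrices), `raw_area`, `raw_count`, `types`,
#'   `normalization`.
#' @export
type_matrix <- function(pairs, cells,
                        normalization = c("global", "output_rows",
                                          "input_columns", "none"),
                        types = NULL) {
  normalization <- match.arg(normalization)
  if (inherits(cells, "connectome")) cells <- cells$cells
  pre_type <- cell_type_of(cells, pairs$pre_id)
  post_type <- cell_type_of(cells, pairs$post_id)
  if (is.null(types)) {
    types <- intersect(cell_type_levels(),
                       unique(c(pre_type, post_type)))
  }
  keep <- pre_type %in% types & post_type %in% types
  k <- length(types)
  raw_area <- matrix(0, k, k, dimnames = list(pre = types, post = types))
  raw_count <- raw_area
  if (any(keep)) {
    idx <- (match(post_type[keep], types) - 1L) * k +
      match(pre_type[keep], types)
    acc_a <- rowsum(pairs$summed_area_um2[keep], idx)
    acc_c <- rowsum(as.numeric(pairs$n_synapses[keep]), idx)
    raw_area[as.integer(rownames(acc_a))] <- acc_a[, 1]
    raw_count[as.integer(rownames(acc_c))] <- acc_c[, 1]
  }
  norm <- function(m) {
    switch(normalization,
           none = m,
           global = if (sum(m) > 0) m / sum(m) else m,
           output_rows = {
             rs <- rowSums(m)
             sweep(m, 1, ifelse(rs > 0, rs, 1), "/")
           },
           input_columns = {
             cs <- colSums(m)
             sweep(m, 2, ifelse(cs > 0, cs, 1), "/")
           })
  }
  structure(list(area = norm(raw_area), count = norm(raw_count),
                 raw_area = raw_area, raw_count = raw_count,
                 types = types, normalization = normalization),
            class = "type_matrix")
}

#' @export
print.type_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<type_matrix> %d types, normalization = %s (area weight)\n",
              length(x$types), x$normalization))
  print(round(x$area, digits))
  invisible(x)
}

#' Fractional input and output synaptic area
#'
#' For each cell (or each cell type), the fraction of its total incoming
#' synaptic area received from every presynaptic partner type, and the
#' fraction of its total outgoing area sent to every postsynaptic type.
#'
#' @param pairs Pair-connection tibble.
#' @param cells Cells tibble or [connectome()].
#' @param by `"type"` (default) aggregates over all cells of each type;
#'   `"cell"` reports per cell.
#' @return Tibble with `direction` (`"incoming"`/`"outgoing"`), the focal
#'   `type` (or `cell_id`), `partner_type`, `area_um2` and `fraction`
#'   (fractions sum to 1 within each focal unit and direction; units with
#'   zero total are absent).
#' @export
io_fractions <- function(pairs, cells, by = c("type", "cell")) {
  by <- match.arg(by)
  if (inherits(cells, "connectome")) cells <- cells$cells
  d <- pairs |>
    mutate(pre_type = cell_type_of(cells, .data$pre_id),
           post_type = cell_type_of(cells, .data$post_id))
  focal_out <- if (by == "type") d$pre_type else d$pre_id
  focal_in <- if (by == "type") d$post_type else d$post_id
  f <- function(focal, partner, direction) {
    t <- tibble(focal = focal, partner_type = partner,
                area = d$summed_area_um2) |>
      dplyr::group_by(.data$focal, .data$partner_type) |>
      summarise(area_um2 = sum(.data$area), .groups = "drop_last") |>
      mutate(fraction = .data$area_um2 / sum(.data$area_um2)) |>
      ungroup() |>
      mutate(direction = direction)
    t
  }
  out <- bind_rows(f(focal_out, d$post_type, "outgoing"),
                   f(focal_in, d$pre_type, "incoming"))
  names(out)[names(out) == "focal"] <-
    if (by == "type") "type" else "cell_id"
  out[, c("direction", setdiff(names(out), "direction"))]
}

#' Median compartment-targeting percentages
#'
#' For a presynaptic and postsynaptic type, computes per postsynaptic cell
#' the percentage of received synaptic area on each postsynaptic
#' compartment, then returns the across-cell median per compartment. The
#' medians are taken independently per compartment and therefore need not
#' sum to 100.
#'
#' @param pairs Pair-connection tibble (with compartment breakdown
#'   columns).
#' @param cells Cells tibble or [connectome()].
#' @param pre_type,post_type Type labels.
#' @return Tibble `compartment`, `median_pct`.
#' @export
compartment_targeting <- function(pairs, cells, pre_type, post_type) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  d <- pairs |>
    filter(cell_type_of(cells, .data$pre_id) == pre_type,
           cell_type_of(cells, .data$post_id) == post_type)
  comps <- c("shaft", "spine_neck", "spine_head", "soma")
  if (!nrow(d)) {
    return(tibble(compartment = comps, median_pct = NA_real_))
  }
  per_cell <- d |>
    dplyr::group_by(.data$post_id) |>
    summarise(across(all_of(paste0("area_", comps)), sum),
              total = sum(.data$summed_area_um2), .groups = "drop")
  tibble(
    compartment = comps,
    median_pct = unname(vapply(comps, function(cmp) {
      median(100 * per_cell[[paste0("area_", cmp)]] / per_cell$total)
    }, numeric(1))))
}

#' Nonparametric group comparison
#'
#' Omnibus Kruskal-Wallis H test across groups followed by pairwise
#' Wilcoxon rank-sum tests, flagged for significance at the conservative
#' p < 0.005 convention.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 groups with
#'   >= 2 values each).
#' @param alpha Significance level (default 0.005).
#' @return A list of class `group_comparison`: `omnibus` (tibble with the
#'   H statistic, df, p) and `pairwise` (tibble with one row per group
#'   pair, W statistic, p, `significant`).
#' @export
compare_groups <- function(values, groups, alpha = 0.005) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) abort("Need at least two groups.")
  if (any(tab < 2)) {
    abort(sprintf("Degenerate group(s) with < 2 values: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  kw <- kruskal.test(values, factor(groups))
  pairs <- utils::combn(sort(names(tab)), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    wt <- suppressWarnings(wilcox.test(values[groups == a],
                                       values[groups == b]))
    tibble(group1 = a, group2 = b, statistic = unname(wt$statistic),
           p_value = wt$p.value)
  })
  pw$significant <- pw$p_value < alpha
  structure(
    list(omnibus = tibble(statistic = unname(kw$statistic),
                          df = unname(kw$parameter),
                          p_value = kw$p.value,
                          significant = kw$p.value < alpha),
         pairwise = pw, alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g%s\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value,
              if (x$omnibus$significant) " *" else ""))
  print(x$pairwise)
  invisible(x)
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Tibble `rho`, `p_value`, `n`; `rho` is `NA` with a warning for
#'   a constant input (undefined rank correlation).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input vector; rank correlation undefined.")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
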