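#' Tidy a permutation null
#'
#' One row per histogram bin with the observed count and the null mean
#' and 95% percentile band.
#'
#' @param x A `gp_shuffle_null`.
#' @param ... Unused.
#' @return A tibble with columns `bin`, `bin_center`, `observed`,
#'   `null_mean`, `null_ci_lower`, `null_ci_upper`.
#' @export
tidy.gp_shuffle_null <- function(x, ...) {
  tibble(
    bin = seq_len(x$n_bins),
    bin_center = (seq_len(x$n_bins) - 0.5) / x$n_bins,
    observed = x$observed_hist,
    null_mean = x$bin_mean,
    null_ci_lower = x$bin_ci_lower,
    null_ci_upper = x$bin_ci_upper)
}

#' Glance at a permutation null
#'
#' @param x A `gp_shuffle_null`.
#' @param ... Unused.
#' @return A one-row tibble: observed selectivity fraction, null mean and
#'   CI, excess, pooled null modal bin centre, iteration and MSN counts.
#' @export
glance.gp_shuffle_null <- function(x, ...) {
  s <- selectivity_excess(x)
  s$pooled_modal_bin_center <- modal_bin_center(colSums(x$iteration_hists))
  s$observed_modal_bin_center <- modal_bin_center(x$observed_hist)
  s$n_iterations <- x$n_iterations
  s$weight <- x$weight
  s
}

#' Tidy a cell-type connectivity matrix
#'
#' @param x A `type_matrix`.
#' @param ... Unused.
#' @return Long tibble `pre_type`, `post_type`, `area`, `count` (values
#'   under the matrix's normalisation).
#' @export
tidy.type_matrix <- function(x, ...) {
  k <- length(x$types)
  tibble(
    pre_type = rep(x$types, k),
    post_type = rep(x$types, each = k),
    area = as.vector(x$area),
    count = as.vector(x$count))
}

#' @export
glance.type_matrix <- function(x, ...) {
  tibble(n_types = length(x$types), normalization = x$normalization,
         total_area_um2 = sum(x$raw_area),
         total_synapses = sum(x$raw_count))
}

#' @export
tidy.reciprocity_stats <- function(x, ...) x$summary

#' @export
glance.reciprocity_stats <- function(x, ...) {
  tibble(type_a = x$types[1], type_b = x$types[2],
         n_scored = sum(x$summary$n_scored),
         reciprocal_fraction =
           mean(x$per_cell$strongest_partner_reciprocal))
}

#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @export
glance.group_comparison <- function(x, ...) x$omnibus
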