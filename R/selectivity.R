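#' Restrict a synapse table to MSN-to-pallidum rows
#'
#' @param synapses Synapse tibble.
#' @param cells Cells tibble or [connectome()].
#' @return The MSN-to-GPe/GPi rows with an added `target` column
#'   (`"GPi"`/`"GPe"`).
#' @export
msn_gp_synapses <- function(synapses, cells) {
  if (inherits(cells, "connectome")) cells <- cells$cells
  pre_t <- cell_type_of(cells, synapses$pre_id)
  post_t <- cell_type_of(cells, synapses$post_id)
  keep <- pre_t == "MSN" & post_t %in% c("GPe", "GPi")
  out <- synapses[keep, , drop = FALSE]
  out$target <- post_t[keep]
  out
}

#' Per-MSN pallidal target ratio (GP ratio)
#'
#' For each MSN the GP ratio is GPi / (GPe + GPi), computed either on
#' summed synaptic area or on synapse counts. MSNs with no pallidal
#' output are excluded and counted in the audit.
#'
#' @param synapses Synapse tibble, or the output of [msn_gp_synapses()].
#' @param cells Cells tibble or [connectome()] (ignored when `synapses`
#'   already carries a `target` column).
#' @param weight `"area"` or `"count"`.
#' @param msn_ids Optional vector of MSN ids defining the population
#'   (defaults to the presynaptic ids present); ids without pallidal
#'   output are reported in the audit.
#' @return Tibble `cell_id`, `n_gpi_synapses`, `n_gpe_synapses`,
#'   `area_gpi_um2`, `area_gpe_um2`, `total_gp_area_um2`, `ratio`; the
#'   `audit` attribute counts scored and zero-output MSNs.
#' @export
gp_ratio <- function(synapses, cells = NULL, weight = c("area", "count"),
                     msn_ids = NULL) {
  weight <- match.arg(weight)
  if (!"target" %in% names(synapses)) {
    if (is.null(cells)) {
      abort("Provide `cells` (or a connectome) to identify MSN-GP rows.")
    }
    synapses <- msn_gp_synapses(synapses, cells)
  }
  msn_ids <- msn_ids %||% sort(unique(synapses$pre_id))
  gpi <- synapses$target == "GPi"
  sum_by <- function(v) {
    t <- rowsum(v, synapses$pre_id)
    out <- t[, 1][as.character(msn_ids)]
    ifelse(is.na(out), 0, out)
  }
  n_i <- sum_by(as.numeric(gpi))
  n_e <- sum_by(as.numeric(!gpi))
  a_i <- sum_by(synapses$size_um2 * gpi)
  a_e <- sum_by(synapses$size_um2 * (!gpi))
  scored <- (n_i + n_e) > 0
  r <- if (weight == "area") a_i / (a_i + a_e) else n_i / (n_i + n_e)
  out <- tibble(cell_id = msn_ids, n_gpi_synapses = as.integer(n_i),
                n_gpe_synapses = as.integer(n_e),
                area_gpi_um2 = unname(a_i), area_gpe_um2 = unname(a_e),
                total_gp_area_um2 = unname(a_i + a_e),
                ratio = unname(r))[scored, , drop = FALSE]
  attr(out, "audit") <- tibble(criterion = c("scored", "zero_gp_output"),
                               n = c(sum(scored), sum(!scored)))
  attr(out, "weight") <- weight
  out
}

bin_ratios <- function(r, n_bins = 30) {
  # left-closed equal bins on [0,1]; the last bin also includes 1
  idx <- pmin(floor(r * n_bins), n_bins - 1L) + 1L
  tabulate(idx, nbins = n_bins)
}

#' Modal bin centre of a histogram
#'
#' Ties between equally tall bins are broken towards the bin whose centre
#' is nearer 0.5.
#'
#' @param counts Vector of bin counts on equal bins over `[0, 1]`.
#' @return The centre of the modal bin.
#' @export
modal_bin_center <- function(counts) {
  n_bins <- length(counts)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  top <- which(counts == max(counts))
  top[which.min(abs(centers[top] - 0.5))] |> (\(i) centers[i])()
}

#' Presynaptic-identity permutation null for pallidal selectivity
#'
#' Tests whether individual MSNs are more selective for one pallidal
#' target type than expected from the population-level connectivity. Each
#' iteration applies one uniform random permutation to the presynaptic-id
#' column of the MSN-to-pallidum synapse table, leaving targets and
#' synapse sizes untouched, so the synaptic area and count received by
#' every target cell, and each MSN's synapse count, are exactly
#' preserved. Per-MSN GP ratios are then recomputed and histogrammed (30
#' equal bins on `[0, 1]` by default); across iterations the per-bin mean
#' and 95% percentile interval are reported, together with the fraction
#' of MSNs at or above the selectivity threshold (0.9) in each iteration.
#'
#' Iteration `i` draws its permutation under the derived seed
#' `seed + i`, so any single iteration is reproducible in isolation.
#'
#' @param synapses Synapse tibble restricted to (or reducible to)
#'   MSN-to-GP rows.
#' @param cells Cells tibble or [connectome()] (optional when `synapses`
#'   has a `target` column).
#' @param n_iterations Number of permutations (default 100).
#' @param n_bins Number of histogram bins (default 30).
#' @param threshold Selectivity threshold on the GP ratio (default 0.9).
#' @param weight `"area"` (default) or `"count"`.
#' @param seed Master seed.
#' @return An object of class `gp_shuffle_null`; see [tidy()] and
#'   [glance()] methods, [selectivity_excess()] and
#'   [autoplot.gp_shuffle_null()].
#' @export
shuffle_null <- function(synapses, cells = NULL, n_iterations = 100,
                         n_bins = 30, threshold = 0.9,
                         weight = c("area", "count"), seed = 0) {
  weight <- match.arg(weight)
  if (!"target" %in% names(synapses)) {
    if (is.null(cells)) {
      abort("Provide `cells` (or a connectome) to identify MSN-GP rows.")
    }
    synapses <- msn_gp_synapses(synapses, cells)
  }
  if (length(unique(synapses$pre_id)) < 2) {
    abort("Permutation null undefined with fewer than 2 presynaptic ids.")
  }
  pre <- synapses$pre_id
  w <- if (weight == "area") synapses$size_um2 else rep(1, nrow(synapses))
  gpi <- synapses$target == "GPi"

  ratios_for <- function(pre_col) {
    num <- rowsum(w * gpi, pre_col)[, 1]
    den <- rowsum(w, pre_col)[, 1]
    num / den
  }
  obs_ratios <- ratios_for(pre)
  obs_hist <- bin_ratios(obs_ratios, n_bins)
  obs_frac <- mean(obs_ratios >= threshold)

  hists <- matrix(0L, n_iterations, n_bins)
  fracs <- numeric(n_iterations)
  mean_ratios <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    set.seed((seed + i) %% .Machine$integer.max)
    r <- ratios_for(sample(pre))
    hists[i, ] <- bin_ratios(r, n_bins)
    fracs[i] <- mean(r >= threshold)
    mean_ratios[i] <- mean(r)
  }
  structure(
    list(n_iterations = n_iterations, n_bins = n_bins,
         threshold = threshold, weight = weight, seed = seed,
         n_msn = length(obs_ratios),
         observed_ratios = obs_ratios, observed_hist = obs_hist,
         observed_fraction = obs_frac,
         iteration_hists = hists, iteration_fractions = fracs,
         iteration_mean_ratios = mean_ratios,
         bin_mean = colMeans(hists),
         bin_ci_lower = apply(hists, 2, quantile, 0.025),
         bin_ci_upper = apply(hists, 2, quantile, 0.975)),
    class = "gp_shuffle_null")
}

#' @export
print.gp_shuffle_null <- function(x, ...) {
  s <- selectivity_excess(x)
  cat(sprintf(
    paste0("<gp_shuffle_null> %d MSNs, %d iterations, %s-weighted\n",
           "  observed fraction >= %.2f: %.3f; null %.3f [%.3f, %.3f]",
           " (excess %.3f)\n"),
    x$n_msn, x$n_iterations, x$weight, x$threshold, s$observed_fraction,
    s$null_mean, s$null_ci_lower, s$null_ci_upper, s$excess))
  cat(sprintf("  pooled null modal bin center: %.4f\n",
              modal_bin_center(colSums(x$iteration_hists))))
  invisible(x)
}

#' Observed selectivity versus its permutation null
#'
#' The fraction of MSNs with GP ratio at or above the threshold in the
#' observed data, the mean and 95% percentile interval of the same
#' fraction under the presynaptic-identity permutation null, and the
#' excess (observed minus null mean).
#'
#' @param null A `gp_shuffle_null`.
#' @param observed_ratios Optional replacement vector of observed per-MSN
#'   ratios; must cover the same number of MSNs as the null.
#' @return One-row tibble.
#' @export
selectivity_excess <- function(null, observed_ratios = NULL) {
  stopifnot(inherits(null, "gp_shuffle_null"))
  if (is.null(observed_ratios)) {
    obs <- null$observed_fraction
  } else {
    if (length(observed_ratios) != null$n_msn) {
      abort("Observed MSN set does not match the null's MSN set.")
    }
    obs <- mean(observed_ratios >= null$threshold)
  }
  tibble(
    observed_fraction = obs,
    null_mean = mean(null$iteration_fractions),
    null_ci_lower = unname(quantile(null$iteration_fractions, 0.025)),
    null_ci_upper = unname(quantile(null$iteration_fractions, 0.975)),
    excess = obs - mean(null$iteration_fractions),
    threshold = null$threshold,
    n_msn = null$n_msn)
}
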