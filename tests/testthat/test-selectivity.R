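test_that("gp_ratio computes per-MSN target ratios with audit", {
  toy <- generate_toy("three_msn")
  gp <- msn_gp_synapses(toy$synapses, toy)
  r <- gp_ratio(gp, weight = "area")
  expect_equal(r$ratio[r$cell_id == 1], 0.3 / 0.5)
  expect_equal(r$ratio[r$cell_id == 2], 1)       # only GPi synapses
  expect_equal(r$ratio[r$cell_id == 3], 0.2 / 0.3)
  # equal areas to both targets -> 0.5
  syn <- tibble::tibble(pre_id = 1L, post_id = c(2L, 3L),
                        size_um2 = c(0.2, 0.2), target = c("GPe", "GPi"))
  expect_equal(gp_ratio(syn)$ratio, 0.5)
  # zero-GP MSNs are excluded and audited
  r2 <- gp_ratio(gp, msn_ids = c(1:3, 99L))
  expect_equal(qc_audit(r2)$n, c(3L, 1L))
  expect_error(gp_ratio(gp, weight = "mass"))
  # population aggregate share of the toy is exactly 0.75
  expect_equal(sum(gp$size_um2[gp$target == "GPi"]) / sum(gp$size_um2),
               0.75)
})

test_that("a single presynaptic id makes the null degenerate or invariant", {
  syn <- tibble::tibble(pre_id = 1L, post_id = c(2L, 3L),
                        size_um2 = c(0.2, 0.4), target = c("GPe", "GPi"))
  expect_error(shuffle_null(syn), "fewer than 2")
})

test_that("every permutation preserves the margins exactly", {
  g <- generate_connectome(small_config(seed = 41))
  gp <- msn_gp_synapses(g$dataset$synapses, g$dataset)
  pre <- gp$pre_id
  total_gpi_area <- sum(gp$size_um2[gp$target == "GPi"])
  total_area <- sum(gp$size_um2)
  for (i in 1:5) {
    set.seed(i)
    perm <- sample(pre)
    # each MSN keeps its synapse count (hence the count multiset too)
    expect_identical(unname(table(perm)), unname(table(pre)))
    # per-MSN area-weighted ratios recombine to the exact global margins:
    # sum over MSNs of ratio * per-MSN area = total GPi area, and the
    # per-MSN areas sum to the total area
    num <- rowsum(gp$size_um2 * (gp$target == "GPi"), perm)[, 1]
    den <- rowsum(gp$size_um2, perm)[, 1]
    expect_equal(sum((num / den) * den), total_gpi_area,
                 tolerance = 1e-9)
    expect_equal(sum(den), total_area, tolerance = 1e-9)
    expect_equal(sum(rowsum(as.numeric(gp$target == "GPi"), perm)[, 1]),
                 sum(gp$target == "GPi"))
  }
})

test_that("Monte-Carlo null matches exhaustive enumeration on the toy", {
  toy <- generate_toy("three_msn")
  gp <- msn_gp_synapses(toy$synapses, toy)
  # exhaustive oracle over all 6! = 720 row permutations
  perms <- all_perms(6)
  expect_length(perms, 720)
  frac_sel <- numeric(720)
  mean_ratio <- numeric(720)
  for (k in seq_along(perms)) {
    pre <- gp$pre_id[perms[[k]]]
    ratios <- vapply(unique(pre), function(id) {
      rows <- pre == id
      sum(gp$size_um2[rows & gp$target == "GPi"]) / sum(gp$size_um2[rows])
    }, numeric(1))
    frac_sel[k] <- mean(ratios >= 0.9)
    mean_ratio[k] <- mean(ratios)
  }
  exact_frac <- mean(frac_sel)
  exact_mean <- mean(mean_ratio)

  nn <- shuffle_null(gp, n_iterations = 10000, seed = 123)
  mc_frac <- mean(nn$iteration_fractions)
  mc_mean <- mean(nn$iteration_mean_ratios)
  se_frac <- sd(frac_sel) / sqrt(10000)
  se_mean <- sd(mean_ratio) / sqrt(10000)
  expect_lt(abs(mc_frac - exact_frac), 3 * se_frac)
  expect_lt(abs(mc_mean - exact_mean), 3 * se_mean)
})

test_that("null statistics are deterministic under the master seed", {
  g <- generate_connectome(small_config(seed = 43))
  gp <- msn_gp_synapses(g$dataset$synapses, g$dataset)
  a <- shuffle_null(gp, n_iterations = 20, seed = 9)
  b <- shuffle_null(gp, n_iterations = 20, seed = 9)
  expect_identical(a$iteration_hists, b$iteration_hists)
  expect_identical(a$iteration_fractions, b$iteration_fractions)
  # iteration histograms each sum to the number of scored MSNs
  expect_true(all(rowSums(a$iteration_hists) == a$n_msn))
  # CI bounds bracket the mean
  expect_true(all(a$bin_ci_lower <= a$bin_mean + 1e-12))
  expect_true(all(a$bin_ci_upper >= a$bin_mean - 1e-12))
})

test_that("pooled shuffled area to GPi stays exactly the aggregate share", {
  g <- generate_connectome(generator_config(
    seed = 44, n_per_type = c(MSN = 2000, GPe = 10, GPi = 20)))
  gp <- msn_gp_synapses(g$dataset$synapses, g$dataset)
  share <- sum(gp$size_um2[gp$target == "GPi"]) / sum(gp$size_um2)
  # the synapse-level margin is permutation-invariant (exact), and the
  # per-MSN mean ratio converges to a value near the share
  nn <- shuffle_null(gp, n_iterations = 30, seed = 2)
  expect_lt(abs(mean(nn$iteration_mean_ratios) - share), 0.03)
})

test_that("modal bin centre uses the toward-0.5 tie-break", {
  counts <- rep(0, 30)
  counts[c(5, 26)] <- 10      # centred at 0.15 and 0.85, tie
  expect_equal(modal_bin_center(counts), 0.15)
  counts[26] <- 11
  expect_equal(modal_bin_center(counts), 26 / 30 - 1 / 60)
})

test_that("selectivity excess flags generator-forced selectivity", {
  cfg <- generator_config(seed = 47,
                          n_per_type = c(MSN = 1500, GPe = 10, GPi = 20),
                          gp_assignment = "pooled",
                          selective_fraction = 0.3)
  g <- generate_connectome(cfg)
  gp <- msn_gp_synapses(g$dataset$synapses, g$dataset)
  nn <- shuffle_null(gp, n_iterations = 50, seed = 3)
  s <- selectivity_excess(nn)
  expect_gt(s$observed_fraction, s$null_ci_upper)
  # forced cells sit at ratio 1
  gt <- g$ground_truth
  expect_true(all(gt$true_gp_ratio_area[gt$forced_selective] == 1,
                  na.rm = TRUE))
  # all MSNs exclusively GPi -> observed fraction 1
  syn <- tibble::tibble(pre_id = rep(1:3, each = 2), post_id = 4L,
                        size_um2 = 0.2, target = "GPi")
  r <- gp_ratio(syn)
  expect_true(all(r$ratio == 1))
})

test_that("an unselective exchangeable population sits inside its null CI", {
  inside <- 0
  for (k in 1:8) {
    cfg <- generator_config(seed = 500 + k,
                            n_per_type = c(MSN = 800, GPe = 10, GPi = 20),
                            gp_assignment = "pooled")
    g <- generate_connectome(cfg)
    gp <- msn_gp_synapses(g$dataset$synapses, g$dataset)
    nn <- shuffle_null(gp, n_iterations = 100, seed = k)
    s <- selectivity_excess(nn)
    inside <- inside + (s$observed_fraction >= s$null_ci_lower &&
                          s$observed_fraction <= s$null_ci_upper)
  }
  expect_gte(inside, 6)
})
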