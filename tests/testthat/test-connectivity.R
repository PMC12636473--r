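test_that("pair aggregation matches a double-loop oracle", {
  syn <- tibble::tibble(
    pre_id = 1L, post_id = 2L, size_um2 = c(0.1, 0.2, 0.3),
    post_compartment = c("shaft", "soma", "shaft"))
  p <- pair_connections(syn)
  expect_equal(nrow(p), 1)
  expect_equal(p$n_synapses, 3L)
  expect_equal(p$summed_area_um2, 0.6)
  expect_equal(p$area_shaft + p$area_spine_neck + p$area_spine_head +
                 p$area_soma, p$summed_area_um2)
  expect_equal(nrow(pair_connections(syn[0, ])), 0)

  set.seed(15)
  n <- 400
  syn <- tibble::tibble(
    pre_id = sample(1:12, n, TRUE), post_id = sample(13:22, n, TRUE),
    size_um2 = runif(n, 0.05, 1),
    post_compartment = sample(c("shaft", "spine_neck", "spine_head",
                                "soma"), n, TRUE))
  p <- pair_connections(syn)
  for (i in sample(nrow(p), 10)) {
    rows <- syn$pre_id == p$pre_id[i] & syn$post_id == p$post_id[i]
    expect_equal(p$n_synapses[i], sum(rows))
    expect_equal(p$summed_area_um2[i], sum(syn$size_um2[rows]))
  }
  expect_equal(sum(p$n_synapses), n)
})

rand_graph <- function(seed, k_types = 5, n = 300) {
  set.seed(seed)
  cells <- tibble::tibble(
    cell_id = 1:40,
    type = sample(c("MSN", "GPe", "GPi", "STN", "TAN")[1:k_types], 40,
                  TRUE),
    is_fragment = FALSE)
  syn <- tibble::tibble(
    pre_id = sample(cells$cell_id, n, TRUE),
    post_id = sample(cells$cell_id, n, TRUE),
    size_um2 = runif(n, 0.05, 1),
    post_compartment = sample(c("shaft", "soma"), n, TRUE))
  list(cells = cells, pairs = pair_connections(syn), syn = syn)
}

test_that("type matrices satisfy their normalization invariants", {
  g <- rand_graph(1)
  glob <- type_matrix(g$pairs, g$cells, "global")
  expect_equal(sum(glob$area), 1, tolerance = 1e-9)
  expect_equal(sum(glob$count), 1, tolerance = 1e-9)
  out <- type_matrix(g$pairs, g$cells, "output_rows")
  rs <- rowSums(out$area)
  expect_true(all(abs(rs[rowSums(out$raw_area) > 0] - 1) < 1e-9))
  inp <- type_matrix(g$pairs, g$cells, "input_columns")
  cs <- colSums(inp$area)
  expect_true(all(abs(cs[colSums(inp$raw_area) > 0] - 1) < 1e-9))
  # identical zero patterns for count and area
  expect_identical(glob$area == 0, glob$count == 0)
})

test_that("type matrix equals oracle summation and ignores row order", {
  g <- rand_graph(2)
  tm <- type_matrix(g$pairs, g$cells, "none")
  for (pre in tm$types) for (post in tm$types) {
    rows <- g$syn$pre_id %in% g$cells$cell_id[g$cells$type == pre] &
      g$syn$post_id %in% g$cells$cell_id[g$cells$type == post]
    expect_equal(tm$raw_area[pre, post], sum(g$syn$size_um2[rows]),
                 tolerance = 1e-9)
  }
  shuffled <- g$pairs[sample(nrow(g$pairs)), ]
  tm2 <- type_matrix(shuffled, g$cells, "none")
  expect_equal(tm$raw_area, tm2$raw_area)
})

test_that("single nonzero pair gives 1.0 in every normalization", {
  cells <- tibble::tibble(cell_id = 1:2, type = c("MSN", "GPi"),
                          is_fragment = FALSE)
  p <- pair_connections(tibble::tibble(
    pre_id = 1L, post_id = 2L, size_um2 = 0.4,
    post_compartment = "shaft"))
  for (nm in c("global", "output_rows", "input_columns")) {
    expect_equal(type_matrix(p, cells, nm)$area["MSN", "GPi"], 1)
  }
})

test_that("removing a type and renormalizing equals the reduced computation", {
  g <- rand_graph(3)
  reduced_types <- c("MSN", "GPe", "GPi")
  a <- type_matrix(g$pairs, g$cells, "global", types = reduced_types)
  keep <- g$cells$cell_id[g$cells$type %in% reduced_types]
  syn2 <- g$syn[g$syn$pre_id %in% keep & g$syn$post_id %in% keep, ]
  b <- type_matrix(pair_connections(syn2),
                   g$cells[g$cells$type %in% reduced_types, ], "global")
  expect_equal(a$area[reduced_types, reduced_types],
               b$area[reduced_types, reduced_types], tolerance = 1e-9)
})

test_that("io fractions normalise per focal unit and match an oracle", {
  g <- rand_graph(4)
  io <- io_fractions(g$pairs, g$cells)
  sums <- io |>
    dplyr::group_by(direction, type) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # spot-check one focal type against direct summation
  t0 <- io$type[1]
  inc <- io[io$direction == "incoming" & io$type == t0, ]
  pre_types <- g$cells$type[match(g$syn$pre_id, g$cells$cell_id)]
  post_types <- g$cells$type[match(g$syn$post_id, g$cells$cell_id)]
  tot <- sum(g$syn$size_um2[post_types == t0])
  for (i in seq_len(nrow(inc))) {
    want <- sum(g$syn$size_um2[post_types == t0 &
                                 pre_types == inc$partner_type[i]]) / tot
    expect_equal(inc$fraction[i], want, tolerance = 1e-9)
  }
  # single input source
  cells <- tibble::tibble(cell_id = 1:2, type = c("MSN", "GPi"),
                          is_fragment = FALSE)
  p <- pair_connections(tibble::tibble(
    pre_id = 1L, post_id = 2L, size_um2 = 0.4,
    post_compartment = "shaft"))
  io1 <- io_fractions(p, cells)
  expect_true(all(io1$fraction == 1))
})

test_that("compartment targeting reports across-cell medians", {
  cells <- tibble::tibble(cell_id = 1:4, type = c("MSN", rep("GPi", 3)),
                          is_fragment = FALSE)
  syn <- tibble::tibble(
    pre_id = 1L, post_id = c(2L, 2L, 3L, 3L, 4L, 4L),
    size_um2 = c(1, 9, 5, 5, 9, 1),
    post_compartment = rep(c("shaft", "soma"), 3))
  ct <- compartment_targeting(pair_connections(syn), cells, "MSN", "GPi")
  expect_equal(ct$median_pct[ct$compartment == "shaft"], 50)
  expect_equal(ct$median_pct[ct$compartment == "soma"], 50)
  expect_equal(ct$median_pct[ct$compartment == "spine_head"], 0)
  # all somatic -> soma 100, others 0
  syn2 <- dplyr::mutate(syn, post_compartment = "soma")
  ct2 <- compartment_targeting(pair_connections(syn2), cells, "MSN",
                               "GPi")
  expect_equal(ct2$median_pct[ct2$compartment == "soma"], 100)
  expect_equal(ct2$median_pct[ct2$compartment == "shaft"], 0)
})

test_that("group comparison wraps the standard nonparametric tests", {
  set.seed(8)
  same <- compare_groups(c(rnorm(30), rnorm(30)),
                         rep(c("a", "b"), each = 30))
  expect_false(same$omnibus$significant)
  shifted <- compare_groups(c(rnorm(100), rnorm(100, 10)),
                            rep(c("a", "b"), each = 100))
  expect_true(shifted$omnibus$significant)
  expect_true(all(shifted$pairwise$significant))
  three <- compare_groups(rnorm(60), rep(c("a", "b", "c"), each = 20))
  expect_equal(nrow(three$pairwise), 3)
  expect_error(compare_groups(rnorm(3), c("a", "a", "b")), "Degenerate")
})

test_that("Spearman correlation matches the rank formula oracle", {
  expect_equal(correlate(1:10, (1:10)^2)$rho, 1)
  expect_equal(correlate(1:10, -(1:10))$rho, -1)
  set.seed(9)
  x <- rnorm(50)
  y <- rnorm(50)   # continuous, ties almost surely absent
  got <- correlate(x, y)
  d <- rank(x) - rank(y)
  want <- 1 - 6 * sum(d^2) / (50 * (50^2 - 1))
  expect_equal(got$rho, want, tolerance = 1e-9)
  expect_warning(out <- correlate(rep(1, 5), rnorm(5)), "Constant")
  expect_true(is.na(out$rho))
})
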