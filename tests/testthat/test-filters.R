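mk_syn <- function(probability = 1, size = 0.2, post = "shaft",
                   pre = "axon") {
  n <- max(length(probability), length(size), length(post), length(pre))
  tibble::tibble(
    synapse_id = seq_len(n), pre_id = 1L, post_id = 2L,
    probability = rep_len(probability, n),
    mesh_area_um2 = rep_len(size, n) * 2,
    size_um2 = rep_len(size, n),
    x_nm = 0, y_nm = 0, z_nm = 0,
    post_compartment = rep_len(post, n),
    pre_compartment = rep_len(pre, n))
}

test_that("synapse thresholds are inclusive and jointly enforced", {
  # large but sub-threshold-size synapse is excluded
  expect_equal(nrow(filter_synapses(mk_syn(probability = 0.95,
                                           size = 0.05))), 0)
  # exactly at both thresholds: retained
  expect_equal(nrow(filter_synapses(mk_syn(probability = 0.6,
                                           size = 0.1))), 1)
  # axo-axonic excluded, unknown labels counted separately with a warning
  expect_warning(
    out <- filter_synapses(mk_syn(probability = 1, size = c(0.2, 0.2, 0.2),
                                  post = c("axon", "shaft", "weird"))),
    "unknown compartment")
  expect_equal(nrow(out), 1)
  a <- qc_audit(out)
  expect_equal(a$n[a$criterion == "geometry"], 1)
  expect_equal(a$n[a$criterion == "unknown_compartment"], 1)
})

test_that("synapse filter equals a row-by-row oracle on generated data", {
  g <- generate_connectome(small_config(seed = 21,
                                        qc_probability_mode = TRUE))
  syn <- g$dataset$synapses
  expect_gt(nrow(syn), 500)
  out <- suppressWarnings(filter_synapses(syn))
  expect_setequal(out$synapse_id, oracle_filter_synapses(syn))
  # audit counts partition the input
  expect_equal(sum(qc_audit(out)$n), nrow(syn))
})

test_that("filters are idempotent and monotone in their thresholds", {
  g <- generate_connectome(small_config(seed = 22,
                                        qc_probability_mode = TRUE))
  syn <- g$dataset$synapses
  once <- suppressWarnings(filter_synapses(syn))
  twice <- suppressWarnings(filter_synapses(once))
  expect_identical(twice$synapse_id, once$synapse_id)
  # loosening any single threshold never shrinks the retained set
  for (cfg in list(filter_config(min_synapse_probability = 0.3),
                   filter_config(min_synapse_size_um2 = 0.02))) {
    loose <- suppressWarnings(filter_synapses(syn, cfg))
    expect_true(all(once$synapse_id %in% loose$synapse_id))
  }
})

test_that("completeness filter enforces compartment presence and 200 um each", {
  short_axon <- bgconnect:::minimal_skeleton(1L, c(5e5, 5e5, 5e5),
                                             axon_um = 150, dend_um = 400)
  ok_cell <- bgconnect:::minimal_skeleton(2L, c(3e5, 3e5, 3e5),
                                          axon_um = 200, dend_um = 200)
  no_soma <- ok_cell |> dplyr::filter(compartment != "soma") |>
    dplyr::mutate(cell_id = 3L,
                  parent_id = ifelse(parent_id == 1L, NA_integer_,
                                     parent_id))
  cells <- tibble::tibble(cell_id = 1:3, type = "MSN",
                          is_fragment = FALSE)
  sk <- dplyr::bind_rows(short_axon, ok_cell, no_soma)
  out <- filter_complete_cells(cells, sk)
  expect_identical(out$cell_id, 2L)  # 150 um axon fails; 200 um passes
  a <- qc_audit(out)
  expect_equal(a$n[a$criterion == "short_axon"], 1)
  expect_equal(a$n[a$criterion == "missing_compartment"], 1)
  expect_equal(sum(a$n), 3)
})

test_that("completeness filter equals an oracle re-check on a cohort", {
  g <- generate_connectome(small_config(seed = 23))
  x <- g$dataset
  out <- filter_complete_cells(x)
  expected <- vapply(x$cells$cell_id, function(id) {
    sk <- x$skeletons[x$skeletons$cell_id == id, ]
    tp <- x$cells$type[x$cells$cell_id == id]
    frag <- x$cells$is_fragment[x$cells$cell_id == id]
    tp %in% c("MSN", "GPe", "GPi", "STN", "TAN", "LTS", "INT1", "INT2",
              "INT3") && !frag &&
      all(c("axon", "dendrite", "soma") %in% sk$compartment) &&
      oracle_edge_sum(sk, "axon") >= 200 &&
      oracle_edge_sum(sk, "dendrite") >= 200
  }, logical(1))
  expect_setequal(out$cell_id, x$cells$cell_id[expected])
})

test_that("fragment filter honours the 0/50/200 um sensitivity modes", {
  # one fragment of 49.9 um, one of 60 um
  mk_frag <- function(id, len_um) {
    k <- 11
    tibble::tibble(cell_id = id, node_id = 1:k,
                   parent_id = c(NA, 1:(k - 1)),
                   x_nm = (0:(k - 1)) * len_um * 100, y_nm = 0, z_nm = 0,
                   radius_um = 0.08, compartment = "axon",
                   myelinated = FALSE)
  }
  cells <- tibble::tibble(cell_id = 1:2, type = "HVC_axon",
                          is_fragment = TRUE)
  sk <- dplyr::bind_rows(mk_frag(1L, 49.9), mk_frag(2L, 60))
  expect_identical(filter_projecting_fragments(cells, sk)$cell_id, 2L)
  expect_setequal(
    filter_projecting_fragments(cells, sk, min_length_um = 0)$cell_id,
    1:2)
  expect_equal(
    nrow(filter_projecting_fragments(cells, sk, min_length_um = 200)), 0)
})

test_that("fragment filter matches the oracle at all three modes", {
  g <- generate_connectome(small_config(seed = 24))
  x <- g$dataset
  frag_ids <- x$cells$cell_id[x$cells$is_fragment]
  lens <- vapply(frag_ids, function(id)
    oracle_edge_sum(x$skeletons[x$skeletons$cell_id == id, ], "total"),
    numeric(1))
  for (thr in c(0, 50, 200)) {
    got <- filter_projecting_fragments(x, min_length_um = thr)$cell_id
    expect_setequal(got, frag_ids[lens >= thr])
  }
})

test_that("dendrite boundary flag matches a per-node distance oracle", {
  geom <- dataset_geometry(c(0, 0, 0), c(1e5, 1e5, 1e5),
                           boundary_margin_um = 7)
  # node 6 um from the x-min face -> flagged
  sk1 <- tibble::tibble(cell_id = 1L, node_id = 1:2,
                        parent_id = c(NA, 1L),
                        x_nm = c(50000, 6000), y_nm = 5e4, z_nm = 5e4,
                        radius_um = 0.3, compartment = "dendrite",
                        myelinated = FALSE)
  # all nodes >= 10 um inside -> not flagged
  sk2 <- sk1 |> dplyr::mutate(cell_id = 2L, x_nm = c(50000, 40000))
  out <- dendrite_near_boundary(dplyr::bind_rows(sk1, sk2), geom)
  expect_identical(out$near_boundary, c(TRUE, FALSE))

  set.seed(77)
  sk <- tibble::tibble(
    cell_id = rep(1:20, each = 5), node_id = rep(1:5, 20),
    parent_id = rep(c(NA, 1:4), 20),
    x_nm = runif(100, -2000, 1.02e5), y_nm = runif(100, 0, 1e5),
    z_nm = runif(100, 0, 1e5), radius_um = 0.3,
    compartment = sample(c("dendrite", "axon"), 100, TRUE),
    myelinated = FALSE)
  got <- suppressWarnings(dendrite_near_boundary(sk, geom))
  oracle <- vapply(1:20, function(id) {
    d <- sk[sk$cell_id == id & sk$compartment == "dendrite", ]
    if (!nrow(d)) return(FALSE)
    any(apply(cbind(d$x_nm, d$y_nm, d$z_nm), 1, function(p) {
      min(p - c(0, 0, 0), c(1e5, 1e5, 1e5) - p) < 7000
    }))
  }, logical(1))
  expect_identical(got$near_boundary, oracle)
})
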