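test_that("soma radius: median distance to the median vertex", {
  v <- tibble::tibble(x_nm = c(1000, -1000, 0, 0),
                      y_nm = c(0, 0, 1000, -1000), z_nm = 0)
  expect_equal(soma_radius(v), 1)
  expect_equal(soma_radius(v[1, ]), 0)
  expect_true(is.na(soma_radius(v[0, ])))
})

test_that("soma radius recovers a sphere radius within 1% and is rigid-motion invariant", {
  set.seed(13)
  d <- matrix(rnorm(3000), ncol = 3)
  d <- d / sqrt(rowSums(d^2)) * 5000
  v <- tibble::tibble(x_nm = d[, 1], y_nm = d[, 2], z_nm = d[, 3])
  r <- soma_radius(v)
  expect_lt(abs(r - 5) / 5, 0.01)
  # translation
  vt <- dplyr::mutate(v, x_nm = x_nm + 1e6, y_nm = y_nm - 3e5)
  expect_equal(soma_radius(vt), r, tolerance = 1e-9)
  # rotation about z by 30 degrees
  th <- pi / 6
  vr <- tibble::tibble(x_nm = v$x_nm * cos(th) - v$y_nm * sin(th),
                       y_nm = v$x_nm * sin(th) + v$y_nm * cos(th),
                       z_nm = v$z_nm)
  expect_lt(abs(soma_radius(vr) - r) / r, 0.02)
})

test_that("axon median radius uses the even-count middle-mean convention", {
  mk <- function(r) tibble::tibble(
    cell_id = 1L, node_id = seq_along(r), parent_id = NA_integer_,
    x_nm = 0, y_nm = 0, z_nm = 0, radius_um = r, compartment = "axon",
    myelinated = FALSE)
  expect_equal(axon_median_radius(mk(c(0.1, 0.1, 0.3))), 0.1)
  expect_equal(axon_median_radius(mk(c(0.1, 0.3))), 0.2)
  expect_true(is.na(axon_median_radius(
    dplyr::mutate(mk(0.1), compartment = "soma"))))
  set.seed(3)
  r <- runif(31, 0.01, 1)
  expect_equal(axon_median_radius(mk(r)), sort(r)[16])
})

test_that("organelle mapping equals a brute-force nearest-node scan", {
  x <- make_fixture()
  for (id in c(1, 5, 9)) {
    sk <- x$skeletons[x$skeletons$cell_id == id, ]
    set.seed(id)
    org <- tibble::tibble(
      organelle_id = 1:200, kind = "mitochondrion", voxel_count = 100,
      x_nm = runif(200, 0, 1e6), y_nm = runif(200, 0, 1e6),
      z_nm = runif(200, 0, 1e6), owner_cell_id = id)
    mapped <- organelle_compartment_map(sk, org)
    oracle <- vapply(1:200, function(i)
      oracle_nearest_node(sk, org$x_nm[i], org$y_nm[i], org$z_nm[i]),
      integer(1))
    expect_identical(mapped$nearest_node_id, oracle)
    expect_identical(mapped$compartment,
                     sk$compartment[match(oracle, sk$node_id)])
  }
})

test_that("equidistant organelle ties resolve to the lowest node id", {
  sk <- tibble::tibble(cell_id = 1L, node_id = c(2L, 1L),
                       parent_id = c(NA, 2L),
                       x_nm = c(-1000, 1000), y_nm = 0, z_nm = 0,
                       radius_um = 0.1,
                       compartment = c("axon", "dendrite"),
                       myelinated = FALSE)
  org <- tibble::tibble(organelle_id = 1L, kind = "mitochondrion",
                        voxel_count = 10, x_nm = 0, y_nm = 0, z_nm = 0,
                        owner_cell_id = 1L)
  expect_identical(organelle_compartment_map(sk, org)$nearest_node_id, 1L)
})

test_that("mitochondrial density follows the closed-form voxel arithmetic", {
  # 100 um axon, one mitochondrion of 40,000 voxels at 10 x 10 x 25 nm
  sk <- tibble::tibble(
    cell_id = 1L, node_id = 1:11, parent_id = c(NA, 1:10),
    x_nm = (0:10) * 10000, y_nm = 0, z_nm = 0, radius_um = 0.1,
    compartment = "axon", myelinated = FALSE)
  org <- tibble::tibble(organelle_id = 1L, kind = "mitochondrion",
                        voxel_count = 40000, x_nm = 50000, y_nm = 0,
                        z_nm = 0, owner_cell_id = 1L)
  expect_equal(mito_volume_density(sk, org, "axon"), 0.001)
  expect_equal(mito_volume_density(sk, org[0, ], "axon"), 0)
  expect_true(is.na(mito_volume_density(sk, org, "dendrite")))
  # linear in voxel count, inverse in path length
  org2 <- dplyr::mutate(org, voxel_count = 80000)
  expect_equal(mito_volume_density(sk, org2, "axon"), 0.002)
  sk2 <- dplyr::mutate(sk, x_nm = x_nm * 2)
  expect_equal(mito_volume_density(sk2, org, "axon"), 0.0005)
})

test_that("mito density equals an independent sum oracle on random input", {
  x <- make_fixture()
  sk <- x$skeletons[x$skeletons$cell_id == 2, ]
  set.seed(29)
  org <- tibble::tibble(
    organelle_id = 1:50,
    kind = sample(c("mitochondrion", "vesicle_cloud"), 50, TRUE),
    voxel_count = sample(1e3:1e6, 50),
    x_nm = runif(50, 2e5, 8e5), y_nm = runif(50, 2e5, 8e5),
    z_nm = runif(50, 2e5, 8e5), owner_cell_id = 2L)
  got <- mito_volume_density(sk, org, "axon")
  nearest <- vapply(1:50, function(i)
    oracle_nearest_node(sk, org$x_nm[i], org$y_nm[i], org$z_nm[i]),
    integer(1))
  cmp <- sk$compartment[match(nearest, sk$node_id)]
  want <- sum(org$voxel_count[org$kind == "mitochondrion" &
                                cmp == "axon"]) * 2.5e-6 /
    oracle_edge_sum(sk, "axon")
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("spine density and myelin fraction are simple exact ratios", {
  sk <- bgconnect:::minimal_skeleton(1L, c(0, 0, 0), axon_um = 100,
                                     dend_um = 100)
  expect_equal(spine_density(10, sk), 10 / path_length(sk, "dendrite"))
  expect_equal(spine_density(0, sk), 0)
  expect_equal(myelin_fraction(sk), 0)
  sk_my <- dplyr::mutate(sk, myelinated = compartment == "axon")
  expect_equal(myelin_fraction(sk_my), 1)
  no_dend <- dplyr::filter(sk, compartment != "dendrite")
  expect_true(is.na(spine_density(3, no_dend)))
})

test_that("zscore_embed standardises, fixes signs and drops undefined rows", {
  f <- tibble::tibble(cell_id = 1:2, a = c(1, 1), b = c(2, 2))
  emb <- zscore_embed(dplyr::mutate(f, a = c(0, 1), b = c(5, 5 + 1e-9)),
                      feature_subset = c("a", "b"))
  expect_equal(nrow(emb), 2)
  expect_error(zscore_embed(f, feature_subset = c("a", "b")),
               "Constant feature")
  # one feature: embedding equals the z-score up to sign, largest loading
  # positive
  f1 <- tibble::tibble(cell_id = 1:5, v = c(1, 2, 3, 4, 10))
  e1 <- zscore_embed(f1, feature_subset = "v")
  z <- (f1$v - mean(f1$v)) / sqrt(mean((f1$v - mean(f1$v))^2))
  expect_equal(e1$PC1, z, tolerance = 1e-12)
  # z-scoring makes the embedding invariant to affine feature rescaling
  f2 <- tibble::tibble(cell_id = 1:6, a = rnorm(6), b = rnorm(6))
  e2 <- zscore_embed(f2, feature_subset = c("a", "b"), n_components = 2)
  f3 <- dplyr::mutate(f2, a = 100 * a - 7)
  e3 <- zscore_embed(f3, feature_subset = c("a", "b"), n_components = 2)
  expect_equal(abs(e2$PC1), abs(e3$PC1), tolerance = 1e-9)
  # undefined rows are dropped with an audit
  f4 <- tibble::tibble(cell_id = 1:4, a = c(1, 2, NA, 3), b = c(4, 3, 2, 1))
  e4 <- zscore_embed(f4, feature_subset = c("a", "b"))
  expect_equal(nrow(e4), 3)
  expect_equal(qc_audit(e4)$n[2], 1)
})

test_that("the 1-D projection separates well-separated synthetic classes", {
  set.seed(5)
  n <- 40
  f <- tibble::tibble(
    cell_id = 1:(2 * n),
    class = rep(c("A", "B"), each = n),
    m1 = c(rnorm(n, 0, 1), rnorm(n, 5, 1)),
    m2 = c(rnorm(n, 0, 1), rnorm(n, 5, 1)),
    m3 = c(rnorm(n, 0, 1), rnorm(n, -5, 1)),
    m4 = c(rnorm(n, 0, 1), rnorm(n, 5, 1)))
  emb <- zscore_embed(f, feature_subset = c("m1", "m2", "m3", "m4"))
  a <- emb$PC1[f$class == "A"]
  b <- emb$PC1[f$class == "B"]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("interneuron classification: strict sides, equality unassigned", {
  thr <- int_thresholds()
  f <- tibble::tibble(
    cell_id = 1:4,
    axon_mito_density = c(0.015, 0.015, 0.040, 0.025),
    axon_median_radius_um = c(0.08, 0.08, 0.15, 0.08),
    soma_radius_um = c(12.5, 9.0, 14.0, 12.5),
    spine_density_per_um = c(0.01, 0.045, 0.01, 0.01))
  out <- classify_int(f, thr)
  # cell 4 sits exactly on the mito threshold -> unassigned
  expect_identical(out$int_class, c("INT1", "INT2", "INT3", "unassigned"))
  # INT1-like on three features but INT3 side on one -> unassigned
  f5 <- tibble::tibble(cell_id = 5L, axon_mito_density = 0.04,
                       axon_median_radius_um = 0.08,
                       soma_radius_um = 12.5,
                       spine_density_per_um = 0.01)
  expect_identical(classify_int(f5, thr)$int_class, "unassigned")
  # incomplete side table is a configuration error
  expect_error(int_thresholds(side_table =
                                default_int_side_table()[-1, ]),
               "side_table")
})

test_that("generator-made interneuron clusters are recovered at >= 99%", {
  cfg <- generator_config(seed = 61,
                          n_per_type = c(INT1 = 120, INT2 = 120,
                                         INT3 = 120),
                          boundary_clip_fraction = 0)
  g <- generate_connectome(cfg)
  f <- morphometry_features(g$dataset)
  out <- classify_int(f)
  correct <- mean(out$int_class == out$type)
  expect_gte(correct, 0.99)
})

test_that("assignment rate is monotone in cluster separation", {
  rate_at <- function(scale, seed) {
    base <- default_int_clusters()
    base$sds <- base$sds * scale
    cfg <- generator_config(seed = seed,
                            n_per_type = c(INT1 = 60, INT2 = 60,
                                           INT3 = 60),
                            int_clusters = base,
                            boundary_clip_fraction = 0)
    g <- generate_connectome(cfg)
    out <- classify_int(morphometry_features(g$dataset))
    mean(out$int_class != "unassigned")
  }
  tight <- rate_at(0.5, 71)
  loose <- rate_at(3, 72)
  expect_gte(tight, loose)
})
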