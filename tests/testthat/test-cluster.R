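test_that("one cluster holding all glomeruli needs no rebalancing", {
  cfg <- network_config()
  set.seed(4)
  glo <- matrix(runif(24, 0, 100), 8, 3)
  cl <- cluster_mf_rosettes(glo, n_clusters = 1, config = cfg)
  expect_identical(cl$sizes, 8L)
  expect_true(all(cl$cluster == 1L))
})

test_that("initial assignment matches the brute-force nearest centroid", {
  cfg <- network_config()
  set.seed(9)
  glo <- matrix(runif(90, 0, 200), 30, 3)
  ## relax the size band so no rebalancing happens (4 clusters of ~7.5)
  cfg$cluster_target <- 8L; cfg$cluster_delta <- 7L
  set.seed(21)
  cl <- cluster_mf_rosettes(glo, n_clusters = 4, config = cfg)
  ## independent oracle: argmin over the full distance matrix
  d <- as.matrix(stats::dist(rbind(cl$centroids, glo)))[-(1:4), 1:4]
  expect_identical(cl$primary$ID_primary, unname(apply(d, 1, which.min)))
  expect_equal(cl$primary$dist_primary, unname(apply(d, 1, min)))
})

test_that("clustering partitions the glomeruli within the size band", {
  net <- fixture_network()
  cl <- net$clusters
  cfg <- net$config
  expect_identical(sum(cl$sizes), length(cl$cluster))   # partition
  expect_true(all(cl$sizes >= cfg$cluster_target - cfg$cluster_delta))
  expect_true(all(cl$sizes <= cfg$cluster_target + cfg$cluster_delta))
  expect_lte(max(cl$dist_to_centroid), cfg$cluster_max_radius)
  ## K-nearest lists sorted ascending
  expect_true(all(diff(t(cl$k_nearest_dist)) >= -1e-12))
})

test_that("infeasible cluster counts are rejected", {
  cfg <- network_config()
  glo <- matrix(runif(300), 100, 3)
  expect_error(cluster_mf_rosettes(glo, n_clusters = 2, config = cfg),
               "invalid config")   # 2 * 12 < 100
  expect_error(cluster_mf_rosettes(glo, n_clusters = 50, config = cfg),
               "invalid config")   # 50 * 4 > 100
})
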