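test_that("a single Golgi cell lands inside the volume in a valid box", {
  cfg <- network_config(length_um = 60, height_um = 30, depth_um = 60,
                        density_goc = 1.01 / (60 * 30 * 60 * 1e-9),
                        density_grc = 0, density_glo = 0, seed = 3L)
  pl <- place_elements(cfg)
  expect_identical(nrow(pl$c_goc), 1L)
  xyz <- pl$c_goc[1, ]
  expect_true(all(xyz > 0) && xyz[1] < 60 && xyz[2] < 60 && xyz[3] < 30)
  ## x and y sit at a box center (box side = GOC diameter)
  expect_equal((xyz[["x"]] / 15) %% 1, 0.5)
  expect_equal((xyz[["y"]] / 15) %% 1, 0.5)
})

test_that("no glomerulus or granule soma intersects a Golgi soma", {
  mp <- mini_placement()
  pl <- mp$pl; cfg <- mp$cfg
  ## brute-force O(n^2) pairwise scan
  for (cl in c("c_glo", "c_grc")) {
    pts <- pl[[cl]]
    min_allowed <- (cfg$diameter_goc + cfg$diameter_glo) / 2
    for (i in seq_len(nrow(pl$c_goc))) {
      d <- sqrt(rowSums((pts - matrix(pl$c_goc[i, ], nrow(pts), 3,
                                      byrow = TRUE))^2))
      expect_gte(min(d), min_allowed - 1e-9)
    }
  }
})

test_that("placement fills the volume and respects per-box occupancy", {
  pl <- fixture_network()$placement
  cfg <- pl$config
  expect_identical(pl$placed[["goc"]], pl$target[["goc"]])
  expect_identical(pl$placed[["glo"]], pl$target[["glo"]])
  expect_gte(pl$placed[["grc"]] / pl$target[["grc"]], 0.98)
  for (cl in c("c_goc", "c_glo", "c_grc")) {
    pts <- pl[[cl]]
    expect_true(all(pts[, 1] > 0 & pts[, 1] < cfg$length_um))
    expect_true(all(pts[, 2] > 0 & pts[, 2] < cfg$depth_um))
    expect_true(all(pts[, 3] > 0 & pts[, 3] < cfg$height_um))
  }
  ## one element per box on the shared fine grid
  d <- max(cfg$diameter_glo, cfg$diameter_grc)
  both <- rbind(pl$c_glo, pl$c_grc)
  key <- paste(floor(both[, 1] / d), floor(both[, 2] / d),
               floor(both[, 3] / d))
  expect_false(anyDuplicated(key) > 0)
})

test_that("placement is deterministic under the seed", {
  cfg <- network_config(length_um = 100, height_um = 60, depth_um = 100,
                        seed = 17L)
  a <- place_elements(cfg)
  b <- place_elements(cfg)
  expect_identical(a$c_grc, b$c_grc)
  expect_identical(a$c_goc, b$c_goc)
  cfg2 <- cfg; cfg2$seed <- 18L
  c <- place_elements(cfg2)
  expect_false(identical(a$c_grc, c$c_grc))
})

test_that("a volume too small for one box is rejected", {
  expect_error(place_elements(network_config(length_um = 10, height_um = 20,
                                             depth_um = 20, diameter_goc = 15,
                                             diameter_grc = 5,
                                             diameter_glo = 5)),
               "too small|invalid config")
})
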