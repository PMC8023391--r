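test_that("element counts follow density x volume with round-down", {
  cfg <- network_config()
  n <- compute_element_counts(cfg)
  expect_equal(n$volume_mm3, 0.108)
  expect_identical(n$n_goc, 972L)
  expect_identical(n$n_grc, 432000L)
  expect_identical(n$n_glo, 32400L)

  zero <- network_config(density_glo = 0)
  expect_identical(compute_element_counts(zero)$n_glo, 0L)

  expect_error(network_config(length_um = -1), "invalid config")
  expect_error(network_config(density_grc = -5), "invalid config")
  expect_error(network_config(diameter_goc = 200), "invalid config")
})

test_that("halving the footprint quarters the counts (within rounding)", {
  full <- compute_element_counts(network_config())
  half <- compute_element_counts(make_fixture(0.5))
  for (f in c("n_goc", "n_grc", "n_glo"))
    expect_lte(abs(half[[f]] - full[[f]] / 4), 1)
  expect_identical(half$n_goc, 243L)
  expect_identical(half$n_grc, 108000L)
  expect_identical(half$n_glo, 8100L)
})

test_that("fixture configurations preserve densities and parameters", {
  base <- network_config()
  tst <- make_fixture("test")
  n <- compute_element_counts(tst)
  expect_identical(n$n_goc, 30L)
  expect_identical(n$n_grc, 13500L)
  expect_identical(n$n_glo, 1012L)
  expect_identical(tst$density_grc, base$density_grc)
  expect_identical(tst$glo_grc_capacity, base$glo_grc_capacity)

  same <- make_fixture(1.0)
  expect_identical(same$length_um, base$length_um)
  expect_identical(same$depth_um, base$depth_um)

  expect_error(make_fixture(0.01), "invalid config")
  expect_error(make_fixture(-2), "invalid config")
})

test_that("config files round-trip through JSON", {
  cfg <- network_config(seed = 99L, aa_per_goc = 123L)
  p <- file.path(tempdir(), "cfg.json")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back, cfg)
})
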