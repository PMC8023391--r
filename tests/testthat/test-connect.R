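test_that("granule-glomerulus links obey reach, caps and distinctness", {
  net <- fixture_network()
  pl <- net$placement; cfg <- net$config
  lg <- net$link_grc_glo
  lens <- adj_lengths(lg)
  expect_true(all(lens <= cfg$grc_dendrites_target))
  ## exhaustive verification: every link within 40 um, fan-in <= 50,
  ## distinct glomeruli per granule
  pairs <- adj_pairs(lg)
  d <- sqrt(rowSums((pl$c_grc[pairs$source_id, ] -
                       pl$c_glo[pairs$target_id, ])^2))
  expect_lte(max(d), cfg$max_dendrite_reach + 1e-9)
  fan_in <- tabulate(lg$targets, nbins = lg$n_tgt)
  expect_lte(max(fan_in), cfg$glo_grc_capacity)
  expect_false(any(duplicated(pairs[c("source_id", "target_id")])))
})

test_that("a granule with exactly 4 reachable glomeruli links to all 4", {
  ## 1 GRC at the center, 4 GLOs within 40 um: forced saturation
  pl <- list(
    c_grc = matrix(c(50, 50, 50), 1, 3,
                   dimnames = list(NULL, c("x", "y", "z"))),
    c_glo = cbind(x = c(30, 70, 50, 50), y = c(50, 50, 30, 70),
                  z = c(50, 50, 50, 50)))
  cfg <- network_config(length_um = 100, height_um = 100, depth_um = 100)
  set.seed(1)
  lg <- connect_grc_glo(pl, cfg)
  expect_identical(sort(adj_row(lg, 1)), 1:4)
})

test_that("Golgi axon inhibition never hits a granule twice per Golgi cell", {
  net <- fixture_network()
  glo_grc <- granlayer:::adj_invert(net$link_grc_glo)
  for (i in seq_len(net$counts$n_goc)) {
    glos <- adj_row(net$link_goca_glo, i)
    expect_lte(length(glos), net$config$goc_axon_max_glo)
    grcs <- unlist(lapply(glos, function(g) adj_row(glo_grc, g)))
    expect_false(any(duplicated(grcs)))
    ## axonal field bounds
    if (length(glos)) {
      dx <- abs(net$placement$c_glo[glos, 1] - net$placement$c_goc[i, 1])
      expect_lte(max(dx), net$config$goc_axon_field[1] / 2)
    }
  }
})

test_that("an isolated Golgi cell gets an empty axon list", {
  pl <- list(c_goc = matrix(c(50, 50, 50), 1, 3),
             c_glo = matrix(numeric(0), 0, 3),
             c_grc = matrix(numeric(0), 0, 3))
  cfg <- network_config()
  lg <- granlayer:::new_adj(list(), 0, 0, name = "link_grc_glo")
  set.seed(1)
  out <- connect_goc_axon_glo(pl, lg, cfg)
  expect_identical(adj_row(out, 1), integer(0))
})

test_that("basal dendrites link at most 40 glomeruli, all inside the disk", {
  net <- fixture_network()
  basal <- net$link_gocdb_glo
  lens <- adj_lengths(basal)
  expect_true(all(lens <= net$config$goc_basal_mf_target))
  expect_true(all(lens >= 1))   # every GOC hears at least one MF
  pairs <- adj_pairs(basal)
  dxy <- sqrt(rowSums((net$placement$c_goc[pairs$source_id, 1:2] -
                         net$placement$c_glo[pairs$target_id, 1:2])^2))
  expect_lte(max(dxy), net$config$basal_radius + 1e-9)
  dz <- abs(net$placement$c_goc[pairs$source_id, 3] -
              net$placement$c_glo[pairs$target_id, 3])
  expect_lte(max(dz), net$config$basal_halfheight + 1e-9)
})

test_that("ascending-axon picks lie in the ellipse, outside the exclusion", {
  net <- fixture_network()
  cfg <- net$config
  a <- cfg$apical_major / 2; b <- cfg$apical_minor / 2
  for (i in seq_len(net$counts$n_goc)) {
    sel <- adj_row(net$aa_goc_link, i)
    expect_identical(length(sel), length(unique(sel)))
    dx <- net$placement$c_grc[sel, 1] - net$placement$c_goc[i, 1]
    dy <- net$placement$c_grc[sel, 2] - net$placement$c_goc[i, 2]
    expect_true(all((dx / a)^2 + (dy / b)^2 <= 1 + 1e-9))
    expect_true(all(dx^2 + dy^2 > cfg$aa_exclusion_radius^2))
  }
  ## parallel-fiber tracks run along depth: |dx| bounded by the semi-major
  pf <- adj_pairs(net$pf_goc_link)
  dx <- abs(net$placement$c_grc[pf$target_id, 1] -
              net$placement$c_goc[pf$source_id, 1])
  expect_lte(max(dx), a + 1e-9)
  ## local tag inside the ellipse, distal outside
  dy <- net$placement$c_grc[pf$target_id, 2] -
    net$placement$c_goc[pf$source_id, 2]
  dxs <- net$placement$c_grc[pf$target_id, 1] -
    net$placement$c_goc[pf$source_id, 1]
  inside <- (dxs / a)^2 + (dy / b)^2 <= 1 + 1e-9
  expect_true(all(inside[pf$tag == 1]))
  expect_true(all(!inside[pf$tag == 2]))
})

test_that("full quotas are reached at fixture scale", {
  net <- fixture_network()
  expect_true(all(adj_lengths(net$aa_goc_link) == net$config$aa_per_goc))
  expect_true(all(adj_lengths(net$pf_goc_link) ==
                    net$config$local_pf_per_goc +
                      net$config$distal_pf_per_goc))
})

test_that("gap junctions are symmetric with degree at most 2", {
  net <- fixture_network()
  gj <- net$gap_junction
  deg <- adj_lengths(gj)
  expect_true(all(deg <= net$config$gap_junctions_per_goc))
  for (i in seq_len(gj$n_src))
    for (j in adj_row(gj, i))
      expect_true(i %in% adj_row(gj, j))
  ## distance bound
  pairs <- adj_pairs(gj)
  d <- sqrt(rowSums((net$placement$c_goc[pairs$source_id, ] -
                       net$placement$c_goc[pairs$target_id, ])^2))
  expect_lte(max(d), net$config$gap_reach + 1e-9)
})

test_that("two reachable Golgi cells form a single mutual link", {
  pl <- list(c_goc = rbind(c(10, 10, 10), c(40, 10, 10)))
  cfg <- network_config()
  gj <- connect_gap_junctions(pl, cfg)
  expect_identical(adj_row(gj, 1), 2L)
  expect_identical(adj_row(gj, 2), 1L)
})

test_that("design_network is deterministic under the seed", {
  cfg <- tiny_config(seed = 31L)
  a <- design_network(cfg, stages = c("grc_glo", "gap"))
  b <- design_network(cfg, stages = c("grc_glo", "gap"))
  expect_identical(a$placement$c_grc, b$placement$c_grc)
  expect_identical(a$link_grc_glo, b$link_grc_glo)
  expect_identical(a$gap_junction, b$gap_junction)
})
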