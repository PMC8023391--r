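## Shared fixtures, built once per test session.

## tiny volume for geometric brute-force checks
tiny_config <- function(seed = 5L) {
  make_fixture("test", seed = seed)
}

## cache the 150 um cube design (placement + all matrices)
fixture_network <- local({
  cache <- NULL
  function(seed = 5L) {
    if (is.null(cache) || cache$config$seed != seed)
      cache <<- design_network(tiny_config(seed))
    cache
  }
})

## small hand-checkable placement: a few cells in a 100 um cube
mini_placement <- function(seed = 2L) {
  cfg <- network_config(length_um = 100, height_um = 100, depth_um = 100,
                        density_goc = 9000, density_grc = 4e5,
                        density_glo = 3e5, seed = seed)
  list(cfg = cfg, pl = place_elements(cfg))
}

## minimal hand-built network: 1 GOC (isolated), 1 GRC whose 4 dendrites
## tap 4 glomeruli fed by a single mossy fiber; no inhibition, no
## feedback. Used to cross-check the engine against the R stepper.
micro_network <- function() {
  adj <- granlayer:::new_adj
  net <- list(
    placement = list(c_goc = matrix(c(50, 50, 50), 1, 3),
                     c_grc = matrix(c(60, 60, 50), 1, 3),
                     c_glo = matrix(runif(12, 40, 60), 4, 3)),
    link_grc_glo = adj(list(1:4), 1, 4, name = "link_grc_glo"),
    link_goca_glo = adj(list(integer(0)), 1, 4, name = "link_goca_glo"),
    link_gocdb_glo = adj(list(integer(0)), 1, 4, name = "link_gocdb_glo"),
    aa_goc_link = adj(list(integer(0)), 1, 1, name = "aa_goc_link"),
    pf_goc_link = adj(list(integer(0)), 1, 1, name = "pf_goc_link"),
    gap_junction = adj(list(integer(0)), 1, 1, name = "gap_junction"),
    clusters = structure(list(cluster = rep(1L, 4),
                              centroids = matrix(50, 1, 3),
                              n_clusters = 1L, sizes = 4L,
                              dist_to_centroid = rep(1, 4)),
                         class = "gl_clusters"),
    counts = list(n_goc = 1L, n_grc = 1L, n_glo = 4L, n_mf = 1L),
    config = make_fixture("test")
  )
  net$mf_glom_clustering <- net$clusters$cluster
  class(net) <- "gl_network"
  net
}

## schedule driving the micro network's single MF at given times (ms)
micro_schedule <- function(times_ms, t_end_s) {
  structure(list(times = list(times_ms), n_mf = 1L,
                 n_spikes = length(times_ms), burst_mfs = integer(0),
                 spec = protocol_spec("custom", t_end = t_end_s),
                 dt = 0.025),
            class = "gl_schedule")
}
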