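test_that("zero-duration simulations give an empty raster", {
  net <- micro_network()
  res <- run_simulation(net, micro_schedule(numeric(0), 0),
                        sim_params(t_end_s = 0))
  expect_identical(nrow(res$raster), 0L)
  expect_equal(res$events_delivered, 0)
})

test_that("the network engine reproduces the R single-cell stepper", {
  net <- micro_network()
  ev <- c(50, 60, 70, 80, 90)       # 100 Hz burst on the single MF
  p <- sim_params(t_end_s = 0.15, record_goc = 1L, record_grc = 1L,
                  record_stride = 1L, use_tables = FALSE)
  res <- run_simulation(net, micro_schedule(ev, 0.15), p)

  ## R reference: isolated GOC; GRC with 4 excitatory synapses whose
  ## events arrive after the mossy-fiber delay
  syn <- load_synapse_model("exc")
  syns <- rep(list(list(model = syn, events = ev + p$delay_mf)), 4)
  ref_grc <- simulate_cell(load_cell_model("GRC"), duration = 150,
                           synapses = syns)
  ref_goc <- simulate_cell(load_cell_model("GOC"), duration = 150)

  expect_equal(res$traces$grc[, 1], ref_grc$vm, tolerance = 1e-8)
  expect_equal(res$traces$goc[, 1], ref_goc$vm, tolerance = 1e-8)

  ## identical spike trains
  eng_grc <- res$raster$time_ms[res$raster$cell_class == "GRC"]
  eng_goc <- res$raster$time_ms[res$raster$cell_class == "GOC"]
  expect_equal(eng_grc, ref_grc$spikes, tolerance = 1e-9)
  expect_equal(eng_goc, ref_goc$spikes, tolerance = 1e-9)

  ## gating-table mode preserves the spike pattern of the analytic mode
  res_tab <- run_simulation(net, micro_schedule(ev, 0.15),
                            sim_params(t_end_s = 0.15, record_grc = 1L,
                                       record_stride = 1L))
  tab_grc <- res_tab$raster$time_ms[res_tab$raster$cell_class == "GRC"]
  expect_identical(length(tab_grc), length(ref_grc$spikes))
  expect_lt(max(abs(tab_grc - ref_grc$spikes)), 1)
})

test_that("reruns with identical inputs are bit-identical", {
  net <- fixture_network()
  sched <- build_protocol(protocol_spec("Prot2", t_end = 0.05, seed = 2L),
                          net$counts$n_mf)
  p <- sim_params(t_end_s = 0.05, record_stride = 0L)
  a <- run_simulation(net, sched, p)
  b <- run_simulation(net, sched, p)
  expect_identical(a$raster, b$raster)
  expect_identical(a$final_vm, b$final_vm)
})

test_that("every spike is delivered once and never consumed same-step", {
  net <- fixture_network()
  sched <- build_protocol(protocol_spec("Prot2", t_end = 0.1, seed = 9L),
                          net$counts$n_mf)
  res <- run_simulation(net, sched, sim_params(t_end_s = 0.1,
                                               record_stride = 0L))
  ## accounting: all emitted MF spikes enter the engine
  expect_equal(res$mf_spikes, res$schedule_size)
  ## conservation: delivered = consumed + still queued
  expect_equal(res$events_delivered, res$events_consumed +
                 res$events_pending)
  expect_gt(res$events_delivered, 0)
  ## causality: delays below one step are rejected up front
  expect_error(sim_params(delay_mf = 0.01), "at least one time step")
})

test_that("granule spikes reach Golgi apical buffers (feedback loop)", {
  ## micro network with an aa link: the granule's spike must excite the GOC
  net <- micro_network()
  net$aa_goc_link <- granlayer:::new_adj(list(1L), 1, 1, name = "aa_goc_link")
  ev <- seq(50, 145, by = 10)
  res <- run_simulation(net, micro_schedule(ev, 0.2),
                        sim_params(t_end_s = 0.2, record_stride = 0L))
  expect_gt(sum(res$raster$cell_class == "GRC"), 0)
  ## the GRC spike fan-out was enqueued (delivered > MF fan-out alone)
  mf_fanout <- res$mf_spikes * 4
  expect_gt(res$events_delivered, mf_fanout)
})
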