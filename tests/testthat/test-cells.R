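test_that("a cell with no conductances and no input conserves Vm exactly", {
  m <- load_cell_model("GRC")
  for (k in seq_along(m$channels)) m$channels[[k]]$gbar <- 0
  st <- init_cell_state(m)
  v0 <- st$vm
  for (i in seq_len(400)) st <- step_cell(m, st, dt = 0.025)$state
  expect_identical(st$vm, v0)
})

test_that("a leak-only cell relaxes to E_leak with the RC time constant", {
  m <- load_cell_model("GRC")
  keep <- vapply(m$channels, function(ch) ch$name == "leak", TRUE)
  for (k in which(!keep)) m$channels[[k]]$gbar <- 0
  g_leak <- m$channels[[which(keep)]]$gbar
  e_leak <- m$channels[[which(keep)]]$erev
  st <- init_cell_state(m)
  st$vm <- e_leak + 20
  tau <- m$cm_pF / g_leak           # ms
  half <- tau * log(2)
  n_half <- round(half / 0.025)
  for (i in seq_len(n_half)) st <- step_cell(m, st, dt = 0.025)$state
  expect_equal(st$vm - e_leak, 10, tolerance = 0.01)
})

test_that("gating variables stay in [0, 1] along a spiking trajectory", {
  m <- load_cell_model("GOC")
  st <- init_cell_state(m)
  ok <- TRUE
  for (i in seq_len(8000)) {
    st <- step_cell(m, st, dt = 0.025)$state
    g <- unlist(st$gates)
    if (any(g < 0 | g > 1)) { ok <- FALSE; break }
  }
  expect_true(ok)
  expect_true(all(st$markov >= 0))
  expect_equal(sum(st$markov), 1, tolerance = 1e-9)
})

test_that("the granule cell is silent at rest, the Golgi cell pacemakes", {
  grc <- simulate_cell(load_cell_model("GRC"), duration = 1000,
                       record = FALSE)
  expect_identical(length(grc$spikes), 0L)

  goc <- simulate_cell(load_cell_model("GOC"), duration = 1000,
                       record = FALSE)
  expect_gt(goc$rate_hz, 1)
  expect_lt(goc$rate_hz, 40)
  ## regular pacemaking: low ISI coefficient of variation
  isi <- diff(goc$spikes)
  expect_lt(sd(isi) / mean(isi), 0.25)
})

test_that("a burst-driven granule cell needs at least 3 stimuli to fire", {
  grc <- load_cell_model("GRC")
  syn <- load_synapse_model("exc")
  ev <- 100 + (0:4) * 10             # one 100 Hz, 50 ms burst
  syns <- rep(list(list(model = syn, events = ev)), 4)
  r <- simulate_cell(grc, duration = 300, synapses = syns)
  expect_gt(length(r$spikes), 0)
  expect_gte(sum(ev < r$spikes[1]), 3)
})

test_that("numerical divergence is reported with the cell class", {
  m <- load_cell_model("GRC")
  st <- init_cell_state(m)
  st$vm <- Inf
  expect_error(step_cell(m, st, dt = 0.025), "divergence")
})
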