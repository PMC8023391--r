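test_that("spike delivery adds the pathway delay and keeps order", {
  q <- deliver_spike(numeric(0), 10.0, 0.5)
  expect_equal(q, 10.5)
  ## round trip: N random spikes pop out in time order with their delays
  set.seed(6)
  em <- runif(200, 0, 100)
  dl <- sample(c(0.5, 1, 2), 200, replace = TRUE)
  q <- numeric(0)
  for (i in seq_along(em)) q <- deliver_spike(q, em[i], dl[i])
  expect_equal(q, sort(em + dl))
  ## consume step by step and compare the multiset
  got <- numeric(0)
  for (t in seq(0, 103, by = 0.5)) {
    out <- pop_due(q, t, 0.5)
    got <- c(got, out$due)
    q <- out$queue
  }
  expect_equal(got, sort(em + dl))
})

test_that("gap currents are zero at equal potentials and antisymmetric", {
  gj <- granlayer:::adj_from_flat(c(1L, 2L), c(2L, 1L), 2, 2)
  expect_equal(gap_currents(c(-60, -60), gj, 0.2), c(0, 0))
  i <- gap_currents(c(-50, -70), gj, 0.2)
  expect_equal(i[1], -i[2])
  expect_equal(i[1], 0.2 * 20)
})

test_that("gap currents match a brute-force double loop", {
  set.seed(11)
  n <- 40
  pl <- list(c_goc = matrix(runif(n * 3, 0, 200), n, 3))
  cfg <- network_config(gap_junctions_per_goc = 3L, gap_reach = 120)
  gj <- connect_gap_junctions(pl, cfg)
  vm <- runif(n, -80, -40)
  fast <- gap_currents(vm, gj, 0.33)
  slow <- numeric(n)
  for (i in seq_len(n))
    for (j in adj_row(gj, i)) slow[i] <- slow[i] + 0.33 * (vm[i] - vm[j])
  expect_equal(fast, slow)
  expect_equal(sum(fast), 0, tolerance = 1e-10)   # pairwise cancellation
})
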