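test_that("Prot2 delivers exactly 5 spikes per bursting MF", {
  spec <- protocol_spec("Prot2", t_end = 10, seed = 12L)
  sch <- build_protocol(spec, n_mf = 4051)
  expect_identical(length(sch$burst_mfs), 405L)           # floor(10% of 4051)
  lens <- lengths(sch$times)
  expect_true(all(lens[sch$burst_mfs] == 5L))             # 100 Hz x 50 ms
  expect_true(all(lens[-sch$burst_mfs] == 0L))
  expect_identical(sch$n_spikes, 2025L)
})

test_that("Prot1 and Prot3 input accounting matches the periodic trains", {
  s1 <- build_protocol(protocol_spec("Prot1", t_end = 10, seed = 1L), 4051)
  ## 1 Hz from 350 ms: spikes at 350, 1350, ..., 9350 ms -> 10 per MF
  expect_identical(lengths(s1$times)[1], 10L)
  expect_identical(s1$n_spikes, 40510L)

  s3 <- build_protocol(protocol_spec("Prot3", t_end = 10, seed = 1L), 4051)
  expect_identical(s3$n_spikes, 40510L + 5L * 4051L)
})

test_that("schedules are sorted, grid-aligned and inside the horizon", {
  sch <- build_protocol(protocol_spec("Prot4", t_end = 2, seed = 8L), 200)
  for (tt in sch$times) {
    expect_true(!is.unsorted(tt))
    expect_true(all(tt >= 0 & tt < 2000))
    expect_equal(tt, round(tt / 0.025) * 0.025)
  }
  ## burst onsets differ across MFs (random T_rand)
  b <- sch$burst_mfs
  expect_identical(length(b), 2L)                          # 1% of 200
})

test_that("degenerate protocols behave", {
  expect_identical(build_protocol(protocol_spec("Prot1", t_end = 1),
                                  0)$n_spikes, 0L)
  expect_error(build_protocol(protocol_spec("custom", t_end = 1,
                                            background_hz = 1e6), 10),
               "invalid protocol")
  expect_error(protocol_spec("custom", frac_burst = 2), "invalid protocol")
})

test_that("protocol generation is reproducible under its seed", {
  a <- build_protocol(protocol_spec("Prot2", t_end = 5, seed = 4L), 500)
  b <- build_protocol(protocol_spec("Prot2", t_end = 5, seed = 4L), 500)
  expect_identical(a$times, b$times)
  c <- build_protocol(protocol_spec("Prot2", t_end = 5, seed = 5L), 500)
  expect_false(identical(a$times, c$times))
})
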