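test_that("a silent synapse emits no transmitter and keeps occupancy", {
  m <- load_synapse_model("exc")
  st <- init_synapse_state(m)
  s <- 0
  for (i in seq_len(2000)) {
    out <- presynaptic_step(st, FALSE, 0.025, m$presyn)
    st <- out$state
    s <- s + out$T
  }
  expect_identical(s, 0)
  expect_equal(sum(st$presyn), 1, tolerance = 1e-12)
})

test_that("presynaptic occupancy is conserved through release events", {
  m <- load_synapse_model("exc")
  st <- init_synapse_state(m)
  for (i in seq_len(100000)) {
    spike <- i %% 4000 == 1
    st <- presynaptic_step(st, spike, 0.025, m$presyn)$state
    }
  expect_equal(sum(st$presyn), 1, tolerance = 1e-9)
  expect_true(all(st$presyn >= 0))
})

test_that("a single release pulse matches a dense-step oracle", {
  m <- load_synapse_model("exc")
  run <- function(dt) {
    st <- init_synapse_state(m)
    y <- numeric(0)
    n <- round(20 / dt)
    for (i in seq_len(n)) {
      st <- presynaptic_step(st, i == 1, dt, m$presyn)$state
      y <- c(y, st$presyn[["y"]])
    }
    y
  }
  coarse <- run(0.025)
  fine <- run(0.0025)
  ## compare the active-state time course at matching times
  idx <- seq(10, length(coarse), by = 40)
  expect_equal(coarse[idx], fine[idx * 10], tolerance = 0.01)
})

test_that("receptor currents obey driving force and open probability", {
  m <- load_synapse_model("exc")
  ampa <- m$schemes$ampa
  occ <- c(1, 0, 0)
  out <- receptor_step(ampa, occ, T = 0, vm = -70, dt = 0.025)
  expect_equal(out$i, 0)                       # open probability 0
  occ <- c(0, 1, 0)
  out <- receptor_step(ampa, occ, T = 0, vm = ampa$vrev, dt = 0.025)
  expect_equal(out$i, 0)                       # at the reversal potential
})

test_that("AMPA kinetics match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  m <- load_synapse_model("exc")
  sc <- m$schemes$ampa
  T_const <- 1
  ## generator matrix under constant transmitter
  Q <- matrix(0, 3, 3)
  for (t in seq_along(sc$from)) {
    r <- sc$rate_base[t] + sc$rate_t[t] * T_const
    Q[sc$from[t], sc$to[t]] <- Q[sc$from[t], sc$to[t]] + r
    Q[sc$from[t], sc$from[t]] <- Q[sc$from[t], sc$from[t]] - r
  }
  run_euler <- function(dt, t_tot) {
    occ <- c(1, 0, 0)
    for (i in seq_len(round(t_tot / dt)))
      occ <- receptor_step(sc, occ, T_const, -70, dt)$occ
    occ
  }
  target <- as.numeric(c(1, 0, 0) %*% Matrix::expm(Q * 2))
  e1 <- run_euler(0.025, 2)
  e2 <- run_euler(0.0125, 2)
  err1 <- max(abs(e1 - target))
  err2 <- max(abs(e2 - target))
  expect_lt(err1, 0.01)
  expect_lt(err2, err1)          # first-order convergence: halving dt helps
})

test_that("receptor occupancies stay conserved over 1e6 steps", {
  m <- load_synapse_model("inh")
  sc <- m$schemes$gaba_a1
  occ <- c(1, rep(0, 7))
  for (i in seq_len(1e6)) {
    T_now <- if (i %% 40000 < 12) 1 else 0    # a pulse every second
    occ <- receptor_step(sc, occ, T_now, -70, 0.025)$occ
  }
  expect_equal(sum(occ), 1, tolerance = 1e-9)
  expect_true(all(occ >= -1e-12))
})

test_that("with no transmitter all receptors relax to the unbound state", {
  m <- load_synapse_model("inh")
  for (nm in names(m$schemes)) {
    sc <- m$schemes[[nm]]
    ns <- length(sc$states)
    occ <- rep(1 / ns, ns)            # start spread over all states
    for (i in seq_len(400000)) occ <- receptor_step(sc, occ, 0, -70, 0.025)$occ
    ## slow desensitized pools keep a small residue; the unbound closed
    ## state dominates and the open probability is negligible
    expect_gt(occ[1], 0.97)
    expect_lt(sum(occ[sc$open]), 1e-3)
  }
})

test_that("the magnesium block is sigmoidal in voltage", {
  expect_gt(mg_block(60), 0.95)
  expect_lt(mg_block(-100), 0.01)
  b <- mg_block(seq(-100, 60, by = 1))
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b < 1))
})

test_that("the synaptic current decomposition is an exact sum", {
  expect_identical(total_synaptic_current(0, 0, 0), 0)
  expect_identical(total_synaptic_current(-5, -3, 2), -6)
  set.seed(2)
  x <- matrix(rnorm(300), ncol = 3)
  expect_equal(total_synaptic_current(x[, 1], x[, 2], x[, 3]),
               x[, 1] + x[, 2] + x[, 3])
})
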