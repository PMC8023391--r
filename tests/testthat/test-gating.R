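test_that("gating equilibrium and relaxation follow the closed forms", {
  eq <- gating_equilibrium(1, 1)
  expect_equal(eq$n_inf, 0.5)
  expect_equal(eq$tau_n, 0.5)
  eq <- gating_equilibrium(0, 2)
  expect_equal(eq$n_inf, 0)
  expect_equal(eq$tau_n, 0.5)
  expect_error(gating_equilibrium(0, 0), "degenerate")

  ## random grid vs direct recomputation
  set.seed(1)
  a <- runif(50, 0.01, 5); b <- runif(50, 0.01, 5)
  eq <- gating_equilibrium(a, b)
  expect_equal(eq$n_inf, a / (a + b))
  expect_equal(eq$tau_n, 1 / (a + b))

  ## exact exponential update
  expect_equal(update_gating(0.3, 0.3, 2, 100), 0.3)     # fixed point
  expect_equal(update_gating(0, 1, 1, 1e6), 1)           # asymptote
  expect_equal(update_gating(0, 1, 1, 0.025), 1 - exp(-0.025))
  expect_equal(update_gating(0, 1, 1, 0.025), 0.0246901, tolerance = 1e-5)
})

test_that("channel conductance and current follow g = gbar x^z y^k", {
  out <- channel_current(10, x = 0.7, z = 2, y = 0.9, k = 1, vm = -64,
                         erev = -64)
  expect_equal(out$i, 0)                       # reversal potential
  out <- channel_current(8, x = 1, z = 3, y = 1, k = 1, vm = 0, erev = -70)
  expect_equal(out$g, 8)                       # fully open
  out <- channel_current(10, x = 0.5, z = 4, y = 1, k = 0, vm = 20, erev = 0)
  expect_equal(out$g, 0.625)
  expect_equal(out$i, 12.5)
})

test_that("the calcium shell obeys its linear ODE", {
  p <- list(area = 300, depth = 0.2, beta = 1.5, ca0 = 1e-4)
  ## rest is a fixed point with no calcium current
  expect_equal(update_calcium(p$ca0, 0, p$area, p$depth, p$beta, p$ca0,
                              0.025), p$ca0)
  ## free decay matches the analytic exponential as dt -> 0
  ca <- 5e-4
  dt <- 1e-4
  for (i in seq_len(10000)) ca <- update_calcium(ca, 0, p$area, p$depth,
                                                 p$beta, p$ca0, dt)
  analytic <- p$ca0 + (5e-4 - p$ca0) * exp(-p$beta * 1)
  expect_equal(ca, analytic, tolerance = 1e-4)
  ## constant inward current settles at ca0 - I/(2 F A d beta) (Euler)
  i_ca <- -10
  ca <- p$ca0
  for (i in seq_len(2000)) ca <- update_calcium(ca, i_ca, p$area, p$depth,
                                                  p$beta, p$ca0, 0.025)
  influx <- -i_ca * 1e3 / (2 * 96485.33212 * p$area * p$depth)
  expect_equal(ca, p$ca0 + influx / p$beta, tolerance = 1e-6)
})

test_that("the calcium Nernst potential behaves", {
  expect_equal(nernst_calcium(2, 2), 0)
  expect_equal(nernst_calcium(0.2, 2, 310.15), 30.75, tolerance = 1e-3)
  ## strictly decreasing in the internal concentration
  e <- nernst_calcium(seq(1e-4, 2, length.out = 50), 2)
  expect_true(all(diff(e) < 0))
  expect_error(nernst_calcium(0, 2), "invalid state")
})

test_that("Markov stepping conserves occupancy and matches two-state theory", {
  goc <- load_cell_model("GOC")
  mk <- goc$markov
  occ <- c(1, 0, 0, 0, 0, 0)
  ## conservation over 1e4 steps at elevated calcium
  for (i in seq_len(10000)) occ <- step_markov(mk, occ, -60, 5e-4, 0.025)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  expect_true(all(occ >= 0))

  ## frozen scheme: zero rates leave occupancy unchanged
  mk0 <- mk
  mk0$rate_base[] <- 0; mk0$rate_ca[] <- 0
  occ2 <- step_markov(mk0, occ, -60, 5e-4, 0.025)
  expect_identical(occ2, occ)

  ## two-state scheme with constant rates vs the analytic solution
  two <- list(states = c("c", "o"), open = 2L, from = c(1L, 2L),
              to = c(2L, 1L), rate_base = c(0.3, 0.7), rate_ca = c(0, 0))
  occ <- c(1, 0)
  dt <- 0.001
  for (i in seq_len(2000)) occ <- step_markov(two, occ, 0, 0, dt)
  t <- 2
  p_inf <- 0.3 / 1
  analytic <- p_inf - (p_inf - 0) * exp(-1 * t)
  expect_equal(occ[2], analytic, tolerance = 1e-3)
})

test_that("rate laws evaluate their functional forms", {
  v <- seq(-100, 60, by = 5)
  expect_equal(eval_rate(list(form = "exponential", A = 2, V0 = -10, K = 20), v),
               2 * exp((v + 10) / 20))
  expect_equal(eval_rate(list(form = "sigmoid", A = 3, V0 = -40, K = -5), v),
               3 / (1 + exp((v + 40) / -5)))
  ## linoid limit at v = V0 equals A * K
  expect_equal(eval_rate(list(form = "linoid", A = -0.3, V0 = -19, K = -10),
                         -19), 3)
  expect_error(eval_rate(list(form = "nope", A = 1), 0), "unknown rate-law")
})
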