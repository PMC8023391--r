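#' Hodgkin-Huxley gating-particle primitives
#'
#' Each ionic channel carries activation/inactivation particles whose
#' permissive probability `n` follows `dn/dt = alpha(1 - n) - beta n`.
#' `gating_equilibrium` returns the steady state `n_inf = alpha/(alpha +
#' beta)` and time constant `tau = 1/(alpha + beta)`; `update_gating`
#' advances a particle by the exact exponential relaxation
#' `n(t) = n_inf - (n_inf - n0) exp(-t/tau)`.
#'
#' @param alpha,beta nonnegative transition rates (1/ms); vectorized.
#' @return `gating_equilibrium`: list with `n_inf` and `tau_n`.
#' @export
gating_equilibrium <- function(alpha, beta) {
  if (any(alpha < 0 | beta < 0))
    stop("degenerate rate: alpha and beta must be nonnegative", call. = FALSE)
  s <- alpha + beta
  if (any(s == 0))
    stop("degenerate rate: alpha + beta must be positive", call. = FALSE)
  list(n_inf = alpha / s, tau_n = 1 / s)
}

#' @rdname gating_equilibrium
#' @param n0 initial particle value in [0, 1].
#' @param n_inf,tau_n steady state and time constant at the current voltage.
#' @param dt time step (ms), >= 0.
#' @export
update_gating <- function(n0, n_inf, tau_n, dt) {
  stopifnot(all(tau_n > 0), all(dt >= 0))
  n_inf - (n_inf - n0) * exp(-dt / tau_n)
}

#' Channel conductance and current
#'
#' `g = gbar * x^z * y^k` and `I = g (Vm - E)`; positive current is
#' outward.
#'
#' @param gbar maximum conductance (nS).
#' @param x,y activation / inactivation particle values in [0, 1].
#' @param z,k particle counts (nonnegative integers).
#' @param vm membrane potential (mV).
#' @param erev reversal potential (mV).
#' @return list with `g` (nS) and `i` (pA).
#' @export
channel_current <- function(gbar, x, z, y = 1, k = 0, vm, erev) {
  g <- gbar * x^z * y^k
  list(g = g, i = g * (vm - erev))
}

## Faraday constant (C/mol) and gas constant (J/mol/K)
.FARADAY <- 96485.33212
.RGAS <- 8.31446262

#' Intracellular calcium dynamics
#'
#' First-order Euler step of
#' `d[Ca]/dt = -I_Ca / (2 F A d) - beta_Ca ([Ca] - [Ca]_0)` for a thin
#' submembrane shell of area `A` (um^2) and depth `d` (um); the result is
#' clamped at zero. `i_ca` is the (inward-negative) calcium current in pA.
#'
#' @param ca calcium concentration (mM).
#' @param i_ca calcium current (pA; inward negative).
#' @param area_um2,depth_um shell area and depth.
#' @param beta_ca leak rate (1/ms).
#' @param ca0 resting concentration (mM).
#' @param dt time step (ms).
#' @return updated concentration (mM).
#' @export
update_calcium <- function(ca, i_ca, area_um2, depth_um, beta_ca, ca0, dt) {
  stopifnot(area_um2 > 0, depth_um > 0, beta_ca > 0)
  ## pA over a shell volume in um^3: 1e3/(2F) converts pA/um^3 to mM/ms
  influx <- -i_ca * 1e3 / (2 * .FARADAY * area_um2 * depth_um)
  ca_new <- ca + dt * (influx - beta_ca * (ca - ca0))
  pmax(ca_new, 0)
}

#' Calcium Nernst potential
#'
#' `E_Ca = (R T / 2 F) ln([Ca]_out / [Ca]_in)` in mV.
#'
#' @param ca_in,ca_out concentrations (mM), both positive.
#' @param temperature_K absolute temperature (K).
#' @return reversal potential (mV).
#' @export
nernst_calcium <- function(ca_in, ca_out, temperature_K = 310.15) {
  if (any(ca_in <= 0) || any(ca_out <= 0))
    stop("invalid state: calcium concentrations must be positive",
         call. = FALSE)
  1000 * .RGAS * temperature_K / (2 * .FARADAY) * log(ca_out / ca_in)
}

#' Advance a Markov gating scheme one Euler step
#'
#' Integrates the master equation `dP/dt = Q(Vm, Ca)^T P` with first-order
#' Euler written as pairwise probability fluxes (which conserves total
#' occupancy to machine precision) and renormalizes. The K-AHP (SK-type)
#' channel of the Golgi cell uses a six-state scheme, four closed and two
#' open, with calcium-dependent forward rates.
#'
#' @param scheme a Markov scheme as built by [load_cell_model()]: fields
#'   `states`, `open` (open-state indices), `from`, `to`, `rate_base`,
#'   `rate_ca` (per-transition rate = `rate_base + rate_ca * ca`, 1/ms,
#'   already temperature-corrected).
#' @param occ occupancy vector (probability over states).
#' @param vm membrane potential (mV); unused by purely calcium-gated
#'   schemes but part of the contract.
#' @param ca calcium concentration (mM).
#' @param dt time step (ms).
#' @return updated occupancy vector.
#' @export
step_markov <- function(scheme, occ, vm, ca, dt) {
  stopifnot(length(occ) == length(scheme$states))
  rates <- scheme$rate_base + scheme$rate_ca * ca
  flux <- occ[scheme$from] * rates * dt
  new <- occ
  for (t in seq_along(flux)) {
    new[scheme$from[t]] <- new[scheme$from[t]] - flux[t]
    new[scheme$to[t]] <- new[scheme$to[t]] + flux[t]
  }
  if (any(new < 0))
    stop("integration step too large: negative Markov occupancy",
         call. = FALSE)
  new / sum(new)
}

#' Evaluate a rate-law specification
#'
#' Rate laws are stored in the cell parameter files as a functional-form
#' identifier plus coefficients. Supported forms (all rates in 1/ms,
#' voltages in mV):
#' \describe{
#'   \item{exponential}{`A exp((v - V0)/K)`}
#'   \item{sigmoid}{`A / (1 + exp((v - V0)/K))`}
#'   \item{linoid}{`A (v - V0) / (exp((v - V0)/K) - 1)`, with the limit
#'     `A K` at `v = V0`}
#'   \item{constant}{`A`}
#'   \item{ca_on}{`A / (1 + B exp(v/K) / ca)` — calcium/voltage dependent
#'     binding (K-Ca activation)}
#'   \item{ca_off}{`A / (1 + ca / (B exp(v/K)))` — unbinding}
#' }
#'
#' @param law list with `form` and coefficients `A`, `V0`, `K`, `B`.
#' @param v membrane potential (mV), vectorized.
#' @param ca calcium (mM) for the calcium-dependent forms.
#' @return rate (1/ms), same length as `v`.
#' @export
eval_rate <- function(law, v, ca = NULL) {
  switch(law$form,
    exponential = law$A * exp((v - law$V0) / law$K),
    sigmoid = law$A / (1 + exp((v - law$V0) / law$K)),
    linoid = {
      x <- (v - law$V0) / law$K
      out <- ifelse(abs(x) < 1e-6, law$A * law$K * (1 - x / 2),
                    law$A * (v - law$V0) / (exp(x) - 1))
      out
    },
    constant = rep_len(law$A, length(v)),
    ca_on = law$A / (1 + law$B * exp(v / law$K) / ca),
    ca_off = law$A / (1 + ca / (law$B * exp(v / law$K))),
    stop("unknown rate-law form: ", law$form, call. = FALSE)
  )
}

## tau laws for inf/tau-style gates:
##   constant: A;  bi_exp_inv: A0 + A/(exp((v-V1)/K1) + exp((v-V2)/K2))
##   exponential: A exp((v - V0)/K)
eval_tau <- function(law, v) {
  switch(law$form,
    constant = rep_len(law$A, length(v)),
    exponential = law$A * exp((v - law$V0) / law$K),
    bi_exp_inv = law$A0 + law$A /
      (exp((v - law$V1) / law$K1) + exp((v - law$V2) / law$K2)),
    stop("unknown tau-law form: ", law$form, call. = FALSE)
  )
}

## steady-state/time-constant pair for one gate description at voltage v
## (and calcium ca); q10f is the temperature factor multiplying rates
## (dividing tau).
gate_inf_tau <- function(gate, v, ca, q10f) {
  if (identical(gate$kind, "alpha_beta")) {
    a <- eval_rate(gate$alpha, v, ca) * q10f
    b <- eval_rate(gate$beta, v, ca) * q10f
    s <- a + b
    list(inf = a / s, tau = 1 / s)
  } else {
    inf <- eval_rate(gate$inf, v, ca)
    tau <- eval_tau(gate$tau, v) / q10f
    list(inf = inf, tau = pmax(tau, 1e-6))
  }
}
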