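#' Load the synapse models from the shipped parameter file
#'
#' The presynaptic terminal is a three-state release scheme (recovered /
#' active / inactive): a presynaptic spike moves a fraction `u` of the
#' recovered pool into the active state, which decays to the inactive
#' state with `tau_in` and recovers with `tau_rec`; while a release event
#' is active the transmitter concentration `T` is a rectangular pulse of
#' `t_max_mM` lasting `t_dur_ms`, and `T = 0` otherwise. Receptors are
#' kinetic schemes of first-order reactions whose binding transitions
#' scale linearly with `T`: AMPA (C/O/D), NMDA (C1/C2/C3/O/D, current
#' scaled by the voltage-dependent magnesium block) and GABA-A in alpha1
#' and alpha6 variants (C/CA1/CA2/OA1/OA2/DA1/DA2/DA2f).
#'
#' @param path optional path to an alternative parameter file.
#' @param kind `"exc"` (AMPA + NMDA) or `"inh"` (GABA alpha1 + alpha6).
#' @return object of class `gl_synapse_model`: `presyn` parameters and a
#'   list of compiled receptor `schemes`.
#' @export
load_synapse_model <- function(kind = c("exc", "inh"), path = NULL) {
  kind <- match.arg(kind)
  if (is.null(path))
    path <- system.file("extdata", "synapses.json", package = "granlayer",
                        mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("presyn", "mg_block", "receptors"))
    if (is.null(raw[[f]])) stop("synapse parameter file missing field: ", f,
                                call. = FALSE)
  wanted <- if (kind == "exc") c("ampa", "nmda") else c("gaba_a1", "gaba_a6")
  schemes <- lapply(wanted, function(nm) {
    rc <- raw$receptors[[nm]]
    if (is.null(rc)) stop("missing receptor scheme: ", nm, call. = FALSE)
    states <- unlist(rc$states)
    sc <- list(name = nm,
               gmax_nS = rc$gmax_pS / 1000,
               vrev = rc$vrev_mV,
               mg_block = isTRUE(rc$mg_block),
               states = states,
               open = match(unlist(rc$open), states),
               from = vapply(rc$transitions, function(t) match(t$from, states), 0L),
               to = vapply(rc$transitions, function(t) match(t$to, states), 0L),
               rate_base = vapply(rc$transitions, function(t) t$base, 0),
               rate_t = vapply(rc$transitions, function(t) t$t_mult, 0))
    if (anyNA(sc$from) || anyNA(sc$to))
      stop("receptor scheme ", nm, " references unknown states",
           call. = FALSE)
    sc
  })
  names(schemes) <- wanted
  model <- list(kind = kind, presyn = raw$presyn, mg = raw$mg_block,
                schemes = schemes, source = path)
  class(model) <- "gl_synapse_model"
  model
}

#' Initial state of one synapse
#'
#' @param model a [load_synapse_model()] object.
#' @return list with the presynaptic occupancy (`x`, `y`, `z`), the time
#'   since the last release (`since_rel`, ms) and one occupancy vector per
#'   receptor scheme (all probability in the first, unbound closed state).
#' @export
init_synapse_state <- function(model) {
  occ <- lapply(model$schemes, function(s) {
    o <- numeric(length(s$states)); o[1] <- 1; o
  })
  list(presyn = c(x = 1, y = 0, z = 0), since_rel = Inf, occ = occ,
       i_last = stats::setNames(numeric(length(occ)), names(occ)))
}

#' Advance the presynaptic release scheme one step
#'
#' @param state synapse state (see [init_synapse_state()]); only the
#'   presynaptic fields are used.
#' @param spike_now logical: did a presynaptic spike arrive this step?
#' @param dt time step (ms).
#' @param presyn presynaptic parameter list.
#' @return list with updated `state` and the transmitter concentration `T`
#'   (mM) for this step.
#' @export
presynaptic_step <- function(state, spike_now, dt,
                             presyn = load_synapse_model("exc")$presyn) {
  p <- state$presyn
  if (isTRUE(spike_now)) {
    rel <- presyn$u * p["x"]
    p["x"] <- p["x"] - rel
    p["y"] <- p["y"] + rel
    state$since_rel <- 0
  } else {
    state$since_rel <- state$since_rel + dt
  }
  dy <- p[["y"]] / presyn$tau_in_ms
  dz <- p[["z"]] / presyn$tau_rec_ms
  p["y"] <- p[["y"]] - dt * dy
  p["z"] <- p[["z"]] + dt * (dy - dz)
  p["x"] <- p[["x"]] + dt * dz
  state$presyn <- p
  T_now <- if (state$since_rel < presyn$t_dur_ms) presyn$t_max_mM else 0
  list(state = state, T = T_now)
}

#' Advance one receptor scheme and compute its current
#'
#' One first-order Euler step of the scheme's master equation with
#' transition rates `base + t_mult * T`, written as pairwise fluxes so the
#' occupancy sum is conserved to machine precision. The current is
#' `I = gmax * sum(open occupancies) * (Vm - Vrev)`, multiplied by the
#' magnesium block `B(Vm)` for NMDA.
#'
#' @param scheme one compiled receptor scheme from [load_synapse_model()].
#' @param occ occupancy vector.
#' @param T transmitter concentration (mM), >= 0.
#' @param vm membrane potential (mV).
#' @param dt time step (ms).
#' @param mg magnesium-block parameter list (used when the scheme has
#'   `mg_block`).
#' @return list with updated `occ` and the receptor current `i` (pA).
#' @export
receptor_step <- function(scheme, occ, T, vm, dt,
                          mg = list(mg_mM = 1, slope_per_mV = 0.062,
                                    k_mM = 3.57)) {
  stopifnot(T >= 0)
  rates <- scheme$rate_base + scheme$rate_t * T
  flux <- occ[scheme$from] * rates * dt
  for (t in seq_along(flux)) {
    occ[scheme$from[t]] <- occ[scheme$from[t]] - flux[t]
    occ[scheme$to[t]] <- occ[scheme$to[t]] + flux[t]
  }
  if (any(occ < -1e-12))
    stop("integration step too large: negative receptor occupancy",
         call. = FALSE)
  po <- sum(occ[scheme$open])
  i <- scheme$gmax_nS * po * (vm - scheme$vrev)
  if (scheme$mg_block)
    i <- i * mg_block(vm, mg$mg_mM, mg$slope_per_mV, mg$k_mM)
  list(occ = occ, i = i)
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' `B(Vm) = 1 / (1 + exp(-slope * Vm) * [Mg] / k)`: close to 0 at strongly
#' hyperpolarized potentials, approaching 1 with depolarization.
#'
#' @param vm membrane potential (mV), vectorized.
#' @param mg_mM external magnesium concentration (mM).
#' @param slope_per_mV,k_mM sigmoid parameters.
#' @return blocking factor in (0, 1).
#' @export
mg_block <- function(vm, mg_mM = 1, slope_per_mV = 0.062, k_mM = 3.57) {
  1 / (1 + exp(-slope_per_mV * vm) * mg_mM / k_mM)
}

#' Total synaptic current
#'
#' `I_syn = I_NMDA + I_AMPA + I_GABA`, exactly.
#'
#' @param i_ampa,i_nmda,i_gaba receptor currents (pA).
#' @return summed current (pA).
#' @export
total_synaptic_current <- function(i_ampa, i_nmda, i_gaba) {
  i_nmda + i_ampa + i_gaba
}

## advance a full synapse (presyn + all receptor schemes); returns the
## summed current
synapse_step <- function(model, state, spike_now, vm, dt) {
  pres <- presynaptic_step(state, spike_now, dt, model$presyn)
  state <- pres$state
  i_total <- 0
  for (nm in names(model$schemes)) {
    rs <- receptor_step(model$schemes[[nm]], state$occ[[nm]], pres$T, vm, dt,
                        model$mg)
    state$occ[[nm]] <- rs$occ
    state$i_last[[nm]] <- rs$i
    i_total <- i_total + rs$i
  }
  list(state = state, i = i_total, T = pres$T)
}
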