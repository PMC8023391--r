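#' Load a conductance-based cell model from a parameter file
#'
#' Reads one of the shipped cell parameter files (granule or Golgi soma),
#' validates the schema, converts channel densities to whole-cell
#' conductances (nS) with the cell area, and precomputes temperature
#' factors `q10^((celsius - temp0)/10)` for every channel.
#'
#' The granule cell carries fast/persistent/resurgent Na, delayed-rectifier
#' / A-type / inward-rectifier / calcium-dependent / slow K, an HVA Ca
#' channel with a dynamic calcium Nernst potential, and leak; the Golgi
#' cell additionally carries the h current, LVA Ca and the SK-type K-AHP
#' channel modeled as a six-state Markov scheme (four closed, two open).
#'
#' @param class `"GRC"` or `"GOC"`, or a path to a parameter file with the
#'   same schema.
#' @param celsius simulation temperature; default from the file.
#' @return object of class `gl_cell_model`.
#' @export
load_cell_model <- function(class = c("GRC", "GOC"), celsius = NULL) {
  path <- if (file.exists(class[1L])) class[1L] else {
    class <- match.arg(class)
    system.file("extdata",
                if (class == "GRC") "grc_soma.json" else "goc_soma.json",
                package = "granlayer", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("class", "area_um2", "cm_uF_cm2", "celsius", "v_init",
              "spike_threshold_mV", "calcium", "channels"))
    if (is.null(raw[[f]])) stop("cell parameter file missing field: ", f,
                                call. = FALSE)
  if (!is.null(celsius)) raw$celsius <- celsius
  area_cm2 <- raw$area_um2 * 1e-8
  nS <- function(g_S_cm2) g_S_cm2 * area_cm2 * 1e9

  channels <- lapply(raw$channels, function(ch) {
    if (is.null(ch$name) || is.null(ch$gbar_S_cm2) || is.null(ch$erev))
      stop("malformed channel entry in ", path, call. = FALSE)
    list(name = ch$name,
         gbar = nS(ch$gbar_S_cm2),
         erev = if (identical(ch$erev, "ca")) NA_real_ else ch$erev,
         dynamic_ca = identical(ch$erev, "ca"),
         q10f = ch$q10^((raw$celsius - ch$temp0) / 10),
         gates = ch$gates)
  })

  markov <- NULL
  if (!is.null(raw$markov)) {
    mk <- raw$markov
    states <- unlist(mk$states)
    q10f <- mk$q10^((raw$celsius - mk$temp0) / 10)
    markov <- list(
      name = mk$name,
      gbar = nS(mk$gbar_S_cm2),
      erev = mk$erev,
      states = states,
      open = match(unlist(mk$open), states),
      from = vapply(mk$transitions, function(t) match(t$from, states), 0L),
      to = vapply(mk$transitions, function(t) match(t$to, states), 0L),
      rate_base = vapply(mk$transitions, function(t) t$base, 0) * q10f,
      rate_ca = vapply(mk$transitions, function(t) t$ca_mult, 0) * q10f
    )
    if (anyNA(markov$from) || anyNA(markov$to))
      stop("Markov scheme references unknown states in ", path,
           call. = FALSE)
  }

  model <- list(
    class = raw$class,
    area_um2 = raw$area_um2,
    cm_pF = raw$cm_uF_cm2 * area_cm2 * 1e12 * 1e-6,  # uF/cm2 -> pF
    celsius = raw$celsius,
    temperature_K = raw$celsius + 273.15,
    v_init = raw$v_init,
    spike_threshold = raw$spike_threshold_mV,
    min_isi = if (!is.null(raw$min_isi_ms)) raw$min_isi_ms else 1,
    calcium = raw$calcium,
    channels = channels,
    markov = markov,
    source = path
  )
  class(model) <- "gl_cell_model"
  model
}

#' @export
print.gl_cell_model <- function(x, ...) {
  cat(sprintf("%s cell model: %d channels%s, area %.0f um2, Cm %.2f pF\n",
              x$class, length(x$channels),
              if (!is.null(x$markov)) " + Markov K-AHP" else "",
              x$area_um2, x$cm_pF))
  invisible(x)
}

#' Initialize the state of a single cell
#'
#' Gating particles start at their steady state for `v_init`, Markov
#' occupancy in the first (fully closed) state, calcium at rest.
#'
#' @param model a [load_cell_model()] object.
#' @return object of class `gl_cell_state`.
#' @export
init_cell_state <- function(model) {
  ca0 <- model$calcium$ca0_mM
  gates <- lapply(model$channels, function(ch) {
    vapply(ch$gates, function(g) {
      it <- gate_inf_tau(g, model$v_init, ca0, ch$q10f)
      it$inf
    }, 0)
  })
  names(gates) <- vapply(model$channels, `[[`, "", "name")
  markov_occ <- if (!is.null(model$markov)) {
    occ <- numeric(length(model$markov$states)); occ[1] <- 1; occ
  }
  st <- list(vm = model$v_init, ca = ca0,
             eca = nernst_calcium(ca0, model$calcium$cao_mM,
                                  model$temperature_K),
             gates = gates, markov = markov_occ,
             t = 0, last_spike = -Inf)
  class(st) <- "gl_cell_state"
  st
}

#' Advance a cell one Euler time step
#'
#' Updates every gating particle with the exact exponential relaxation at
#' the current voltage, advances the Markov scheme and the calcium shell,
#' then takes one first-order Euler step of the membrane equation
#' `Cm dVm/dt = -(I_ions + I_syn + I_gap) + I_ext`. A spike is reported on
#' an upward crossing of the spike threshold provided the last spike is at
#' least the refractory interval in the past.
#'
#' @param model a [load_cell_model()] object.
#' @param state a [init_cell_state()] object.
#' @param i_syn,i_gap synaptic and gap-junction currents (pA, outward
#'   positive).
#' @param dt time step (ms).
#' @param i_ext injected current (pA, depolarizing positive).
#' @return list with `state` (advanced) and `spiked` (logical).
#' @export
step_cell <- function(model, state, i_syn = 0, i_gap = 0, dt = 0.025,
                      i_ext = 0) {
  vm <- state$vm
  if (!is.finite(vm))
    stop(sprintf("numerical divergence in %s cell at t = %.3f ms",
                 model$class, state$t), call. = FALSE)
  ca <- state$ca
  i_total <- 0
  i_ca_total <- 0
  for (k in seq_along(model$channels)) {
    ch <- model$channels[[k]]
    g <- ch$gbar
    if (length(ch$gates)) {
      gv <- state$gates[[k]]
      for (j in seq_along(ch$gates)) {
        gd <- ch$gates[[j]]
        it <- gate_inf_tau(gd, vm, ca, ch$q10f)
        gv[j] <- it$inf - (it$inf - gv[j]) * exp(-dt / it$tau)
        g <- g * gv[j]^gd$power
      }
      state$gates[[k]] <- gv
    }
    e <- if (ch$dynamic_ca) state$eca else ch$erev
    i <- g * (vm - e)
    i_total <- i_total + i
    if (ch$dynamic_ca) i_ca_total <- i_ca_total + i
  }
  if (!is.null(model$markov)) {
    state$markov <- step_markov(model$markov, state$markov, vm, ca, dt)
    po <- sum(state$markov[model$markov$open])
    i_total <- i_total + model$markov$gbar * po * (vm - model$markov$erev)
  }
  state$ca <- update_calcium(ca, i_ca_total, model$area_um2,
                             model$calcium$depth_um, model$calcium$beta_ms,
                             model$calcium$ca0_mM, dt)
  state$eca <- nernst_calcium(max(state$ca, 1e-12), model$calcium$cao_mM,
                              model$temperature_K)
  vm_new <- vm + dt * (i_ext - i_syn - i_gap - i_total) / model$cm_pF
  if (!is.finite(vm_new))
    stop(sprintf("numerical divergence in %s cell at t = %.3f ms",
                 model$class, state$t), call. = FALSE)
  spiked <- vm < model$spike_threshold && vm_new >= model$spike_threshold &&
    (state$t - state$last_spike) >= model$min_isi
  state$t <- state$t + dt
  state$vm <- vm_new
  if (spiked) state$last_spike <- state$t
  list(state = state, spiked = spiked)
}

#' Simulate a single cell, optionally with driven synapses
#'
#' Integrates one isolated cell for `duration` ms at step `dt`, with an
#' optional constant injected current and an optional list of synapses,
#' each a list with fields `model` (a [load_synapse_model()] receptor
#' bundle, `"exc"` or `"inh"`) and `events` (presynaptic spike times, ms).
#'
#' @param model a [load_cell_model()] object.
#' @param duration total time (ms).
#' @param dt time step (ms).
#' @param i_ext constant injected current (pA).
#' @param synapses optional synapse list (see details).
#' @param record logical: keep the Vm trace.
#' @return list with `spikes` (times, ms), `vm` (trace or NULL), `t`
#'   (trace times), `state` (final state), `rate_hz`.
#' @export
simulate_cell <- function(model, duration = 1000, dt = 0.025, i_ext = 0,
                          synapses = NULL, record = TRUE) {
  state <- init_cell_state(model)
  n <- round(duration / dt)
  spikes <- numeric(0)
  vm_trace <- if (record) numeric(n) else NULL
  syn_states <- lapply(synapses, function(s) init_synapse_state(s$model))
  syn_steps <- lapply(synapses, function(s) {
    sort(unique(round(s$events / dt)))
  })
  for (step in seq_len(n)) {
    i_syn <- 0
    t_now <- (step - 1) * dt
    for (si in seq_along(syn_states)) {
      spike_now <- length(syn_steps[[si]]) && (step - 1L) %in% syn_steps[[si]]
      res <- synapse_step(synapses[[si]]$model, syn_states[[si]], spike_now,
                          state$vm, dt)
      syn_states[[si]] <- res$state
      i_syn <- i_syn + res$i
    }
    out <- step_cell(model, state, i_syn = i_syn, dt = dt, i_ext = i_ext)
    state <- out$state
    if (out$spiked) spikes <- c(spikes, state$t)
    if (record) vm_trace[step] <- state$vm
  }
  list(spikes = spikes, vm = vm_trace,
       t = if (record) seq_len(n) * dt else NULL,
       state = state, rate_hz = length(spikes) / duration * 1000)
}
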