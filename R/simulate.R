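#' Simulation parameters
#'
#' @param t_end_s simulated time (s).
#' @param dt integration step (ms); 0.025 ms throughout.
#' @param delay_mf,delay_goc,delay_aa,delay_pf axonal/dendritic
#'   transmission delays (ms) for the mossy-fiber-to-dendrite, Golgi-axon,
#'   ascending-axon and parallel-fiber pathways; all must be >= `dt` so no
#'   spike can be consumed in its emission step.
#' @param g_gap gap-junction conductance (nS).
#' @param record_goc,record_grc cell ids whose Vm traces to keep.
#' @param record_stride trace subsampling stride in steps (0 = no traces).
#' @param use_tables use precomputed gating tables (set `FALSE` for exact
#'   analytic rates, e.g. when cross-checking against the R stepper).
#' @return object of class `gl_sim_params`.
#' @export
sim_params <- function(t_end_s = 1, dt = 0.025, delay_mf = 0.5,
                       delay_goc = 0.5, delay_aa = 0.5, delay_pf = 1.0,
                       g_gap = 0.2, record_goc = integer(0),
                       record_grc = integer(0), record_stride = 40L,
                       use_tables = TRUE) {
  stopifnot(dt > 0, t_end_s >= 0)
  delays <- c(delay_mf, delay_goc, delay_aa, delay_pf)
  if (any(delays < dt))
    stop("invalid params: delays must be at least one time step",
         call. = FALSE)
  p <- list(t_end_s = t_end_s, dt = dt, delay_mf = delay_mf,
            delay_goc = delay_goc, delay_aa = delay_aa,
            delay_pf = delay_pf, g_gap = g_gap,
            record_goc = as.integer(record_goc),
            record_grc = as.integer(record_grc),
            record_stride = as.integer(record_stride),
            use_tables = isTRUE(use_tables))
  class(p) <- "gl_sim_params"
  p
}

## Build the flattened 0-based fan-out maps the engine consumes.
## Dendrite slot encoding: (grc - 1) * 4 + (dendrite - 1).
build_engine_network <- function(network) {
  stopifnot(inherits(network, "gl_network"))
  for (nm in c("link_grc_glo", "link_goca_glo", "link_gocdb_glo",
               "aa_goc_link", "pf_goc_link", "gap_junction", "clusters"))
    if (is.null(network[[nm]]))
      stop("network is missing stage '", nm,
           "'; run design_network(stages = \"all\")", call. = FALSE)
  n_goc <- network$counts$n_goc
  n_grc <- network$counts$n_grc
  n_glo <- network$counts$n_glo
  n_mf <- network$counts$n_mf

  ## glomerulus -> (granule, dendrite) slots
  lg <- network$link_grc_glo
  lens <- diff(lg$ptr)
  grc_of_link <- rep.int(seq_len(n_grc), lens)
  dend_of_link <- sequence(lens)
  slot_of_link <- (grc_of_link - 1L) * 4L + (dend_of_link - 1L)
  glo_slots <- split(slot_of_link, factor(lg$targets, levels = seq_len(n_glo)))

  flat0 <- function(rows, n_src) {
    lens <- lengths(rows)
    list(ptr = as.integer(c(0L, cumsum(lens))),
         targets = as.integer(unlist(rows, use.names = FALSE)))
  }

  ## MF -> granule dendrite slots and MF -> Golgi basal targets
  mf_glos <- split(seq_len(n_glo),
                   factor(network$clusters$cluster, levels = seq_len(n_mf)))
  glo_gocb <- adj_invert(network$link_gocdb_glo)
  mf_grc <- lapply(mf_glos, function(gs)
    unlist(glo_slots[gs], use.names = FALSE))
  mf_gocb <- lapply(mf_glos, function(gs)
    unlist(lapply(gs, function(g) adj_row(glo_gocb, g) - 1L),
           use.names = FALSE))

  ## GOC -> granule dendrite slots (inhibition through its glomeruli)
  goc_grc <- lapply(seq_len(n_goc), function(i)
    unlist(glo_slots[adj_row(network$link_goca_glo, i)], use.names = FALSE))

  ## GRC -> GOC apical contacts (tag 1 = ascending axon, 2 = parallel fiber)
  aa_inv <- adj_pairs(network$aa_goc_link)
  pf_inv <- adj_pairs(network$pf_goc_link)
  src <- c(aa_inv$target_id, pf_inv$target_id)   # granule id
  tgt <- c(aa_inv$source_id, pf_inv$source_id)   # Golgi id
  tag <- c(rep.int(1L, nrow(aa_inv)), rep.int(2L, nrow(pf_inv)))
  o <- order(src, method = "radix")
  src <- src[o]; tgt <- tgt[o]; tag <- tag[o]
  counts <- tabulate(src, nbins = n_grc)
  grc_goc <- list(ptr = as.integer(c(0L, cumsum(counts))),
                  targets = as.integer(tgt - 1L), tag = as.integer(tag))

  list(
    n_goc = n_goc, n_grc = n_grc,
    mf_grc = flat0(mf_grc, n_mf),
    mf_gocb = flat0(mf_gocb, n_mf),
    goc_grc = flat0(goc_grc, n_goc),
    grc_goc = grc_goc,
    gap = list(ptr = network$gap_junction$ptr,
               targets = network$gap_junction$targets - 1L)
  )
}

## synapse model in the layout the engine expects
engine_synapses <- function() {
  exc <- load_synapse_model("exc")
  inh <- load_synapse_model("inh")
  list(schemes_exc = exc$schemes, schemes_inh = inh$schemes,
       presyn = exc$presyn, mg = exc$mg)
}

#' Run a network simulation
#'
#' Time-stepped simulation of a designed network driven by a mossy-fiber
#' protocol. Each step evaluates (in this order) the due mossy-fiber
#' spikes, every Golgi cell (synapses, channels, membrane), the
#' gap-junction currents, then every granule cell; spikes are exchanged
#' through delayed queues, so identical inputs and seed give bit-identical
#' rasters regardless of evaluation order within a population.
#'
#' @param network a [design_network()] result with all stages.
#' @param protocol a [protocol_spec()] or a prebuilt [build_protocol()]
#'   schedule.
#' @param params a [sim_params()].
#' @return object of class `gl_sim_result`: `raster` (data.frame with
#'   `cell_class`, `cell_id`, `time_ms`), Vm `traces`, input accounting
#'   (`mf_spikes`, `events_delivered`, `events_consumed`) and the run
#'   metadata.
#' @export
run_simulation <- function(network, protocol, params = sim_params()) {
  stopifnot(inherits(params, "gl_sim_params"))
  schedule <- if (inherits(protocol, "gl_protocol"))
    build_protocol(protocol, network$counts$n_mf, params$dt)
  else protocol
  stopifnot(inherits(schedule, "gl_schedule"))
  if (schedule$n_mf != network$counts$n_mf)
    stop("schedule was built for ", schedule$n_mf, " MFs but the network has ",
         network$counts$n_mf, call. = FALSE)

  eng_net <- build_engine_network(network)
  n_steps <- as.integer(round(params$t_end_s * 1000 / params$dt))

  ## flatten the schedule to sorted (step, mf) pairs
  lens <- lengths(schedule$times)
  mf_of <- rep.int(seq_along(schedule$times), lens)
  t_of <- unlist(schedule$times, use.names = FALSE)
  step_of <- as.integer(round(t_of / params$dt))
  keep <- step_of < n_steps
  mf_of <- mf_of[keep]; step_of <- step_of[keep]
  o <- order(step_of, mf_of, method = "radix")

  eng_params <- list(
    dt = params$dt, n_steps = n_steps, g_gap = params$g_gap,
    use_tables = params$use_tables,
    delay_mf_steps = as.integer(round(params$delay_mf / params$dt)),
    delay_goc_steps = as.integer(round(params$delay_goc / params$dt)),
    delay_aa_steps = as.integer(round(params$delay_aa / params$dt)),
    delay_pf_steps = as.integer(round(params$delay_pf / params$dt)),
    record_goc = params$record_goc, record_grc = params$record_grc,
    record_stride = params$record_stride
  )
  grc_model <- load_cell_model("GRC")
  goc_model <- load_cell_model("GOC")
  raw <- .sim_engine(eng_net, grc_model, goc_model, engine_synapses(),
                     step_of[o], mf_of[o] - 1L, eng_params)

  raster <- data.frame(
    cell_class = c("GOC", "GRC")[raw$raster_class + 1L],
    cell_id = raw$raster_id, time_ms = raw$raster_t
  )
  raster <- raster[order(raster$time_ms, raster$cell_class,
                         raster$cell_id), , drop = FALSE]
  rownames(raster) <- NULL
  out <- list(
    raster = raster,
    traces = list(goc = raw$vm_goc, grc = raw$vm_grc,
                  t_ms = if (params$record_stride > 0)
                    seq(0, by = params$dt * params$record_stride,
                        length.out = nrow(raw$vm_goc))),
    mf_spikes = raw$mf_spikes_emitted,
    schedule_size = length(step_of),
    events_delivered = raw$events_delivered,
    events_consumed = raw$events_consumed,
    events_pending = raw$events_pending,
    final_vm = list(goc = raw$final_vm_goc, grc = raw$final_vm_grc),
    params = params, protocol = schedule$spec, t_end_s = params$t_end_s,
    counts = network$counts
  )
  class(out) <- "gl_sim_result"
  out
}

#' @export
print.gl_sim_result <- function(x, ...) {
  tab <- table(factor(x$raster$cell_class, levels = c("GOC", "GRC")))
  cat(sprintf("simulation result: %g s, %d spikes (%d GOC, %d GRC), %g MF input spikes\n",
              x$t_end_s, nrow(x$raster), tab[["GOC"]], tab[["GRC"]],
              x$mf_spikes))
  invisible(x)
}

#' Center-surround stimulation
#'
#' Selects the mossy fibers whose cluster centroid falls inside a disk
#' (default 50 um diameter) on the x-y plane, drives each with one burst
#' (default 150 Hz for 50 ms), runs the simulation and bins the granule
#' spike counts on the x-y plane. Granule-layer physiology predicts an
#' excited core surrounded by an annulus where Golgi inhibition dominates.
#'
#' @param network full design.
#' @param params a [sim_params()].
#' @param center disk center `c(x, y)` (um); default the volume center.
#' @param disk_diameter_um stimulated-area diameter (um).
#' @param burst_hz,burst_dur_s,burst_start_s burst shape and onset.
#' @param bin_um spatial bin for the activity map.
#' @return list with `result` (a `gl_sim_result`), `map` (an
#'   [activity_map()]), `stim_mfs` (ids of the driven MFs).
#' @export
run_center_surround <- function(network, params = sim_params(t_end_s = 0.4),
                                center = NULL, disk_diameter_um = 50,
                                burst_hz = 150, burst_dur_s = 0.05,
                                burst_start_s = 0.1, bin_um = 25) {
  cfg <- network$config
  if (is.null(center)) center <- c(cfg$length_um / 2, cfg$depth_um / 2)
  ctr <- network$clusters$centroids
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2
  stim <- which(d2 <= (disk_diameter_um / 2)^2)
  if (length(stim) == 0L)
    warning("no mossy-fiber cluster centroid inside the stimulus disk; ",
            "baseline activity only")

  n_mf <- network$counts$n_mf
  times <- rep(list(numeric(0)), n_mf)
  if (length(stim)) {
    period <- 1000 / burst_hz
    n_in_burst <- ceiling(burst_dur_s * 1000 / period)
    b <- round((burst_start_s * 1000 + (seq_len(n_in_burst) - 1) * period) /
                 params$dt) * params$dt
    b <- b[b < params$t_end_s * 1000]
    for (i in stim) times[[i]] <- b
  }
  schedule <- structure(
    list(times = times, n_mf = n_mf, n_spikes = sum(lengths(times)),
         burst_mfs = stim,
         spec = protocol_spec("custom", t_end = params$t_end_s,
                              burst_hz = burst_hz, frac_burst = 0),
         dt = params$dt),
    class = "gl_schedule")
  res <- run_simulation(network, schedule, params)
  grc_spk <- res$raster[res$raster$cell_class == "GRC", , drop = FALSE]
  map <- activity_map(grc_spk$cell_id, network$placement$c_grc,
                      window_ms = c(burst_start_s * 1000,
                                    params$t_end_s * 1000),
                      spike_times = grc_spk$time_ms,
                      bin_um = bin_um, config = cfg)
  list(result = res, map = map, stim_mfs = stim, center = center,
       disk_diameter_um = disk_diameter_um)
}
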