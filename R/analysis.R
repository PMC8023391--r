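#' Analytic memory-occupancy estimators
#'
#' Closed-form byte counts for the three stages of the simulator, as
#' linear functions of the element counts (exact integer arithmetic):
#' \describe{
#'   \item{design}{`600 + 15432 n_goc + 32 n_grc + 1292 n_glo + 296 n_mf`}
#'   \item{cpu}{`42542 n_goc + 12220 n_grc + 204 n_glo + 8004 n_mf`}
#'   \item{gpu}{`580 + 2788 n_goc + 7172 n_grc` (per device; divide the
#'     cell counts by the number of boards for multi-GPU runs)}
#' }
#' Reported MB/GB figures use binary units (MiB/GiB).
#'
#' @param counts list or vector with `n_goc`, `n_grc`, `n_glo`, `n_mf`
#'   (the latter two ignored for the gpu stage).
#' @param stage `"design"`, `"cpu"` or `"gpu"`.
#' @return object of class `gl_mem_estimate`: `bytes`, `mib`, `gib`,
#'   `stage`, `counts`.
#' @export
estimate_memory <- function(counts, stage = c("design", "cpu", "gpu")) {
  stage <- match.arg(stage)
  cnt <- as.list(counts)
  n_goc <- as.numeric(cnt$n_goc)
  n_grc <- as.numeric(cnt$n_grc)
  n_glo <- if (!is.null(cnt$n_glo)) as.numeric(cnt$n_glo) else 0
  n_mf <- if (!is.null(cnt$n_mf)) as.numeric(cnt$n_mf) else 0
  stopifnot(n_goc >= 0, n_grc >= 0, n_glo >= 0, n_mf >= 0)
  bytes <- switch(stage,
    design = 600 + 15432 * n_goc + 32 * n_grc + 1292 * n_glo + 296 * n_mf,
    cpu = 42542 * n_goc + 12220 * n_grc + 204 * n_glo + 8004 * n_mf,
    gpu = 580 + 2788 * n_goc + 7172 * n_grc)
  out <- list(bytes = bytes, mib = bytes / 2^20, gib = bytes / 2^30,
              mb = bytes / 1e6, gb = bytes / 1e9,
              stage = stage,
              counts = list(n_goc = n_goc, n_grc = n_grc, n_glo = n_glo,
                            n_mf = n_mf))
  class(out) <- "gl_mem_estimate"
  out
}

#' @export
print.gl_mem_estimate <- function(x, ...) {
  cat(sprintf("%s-stage memory: %s bytes (%.2f MiB / %.3f GiB; %.2f MB / %.3f GB)\n",
              x$stage, format(x$bytes, big.mark = ","), x$mib, x$gib,
              x$mb, x$gb))
  invisible(x)
}

#' Largest volume a GPU can host
#'
#' Inverts the gpu-stage estimator for given device RAM and densities:
#' `V <= (RAM - 580) / (2788 d_goc + 7172 d_grc)` with densities per mm^3,
#' volume in mm^3.
#'
#' @param ram_bytes available device RAM (bytes).
#' @param config a [network_config()] providing the densities.
#' @return maximum volume (mm^3).
#' @export
max_gpu_volume <- function(ram_bytes, config = network_config()) {
  stopifnot(ram_bytes > 580)
  (ram_bytes - 580) /
    (2788 * config$density_goc + 7172 * config$density_grc)
}

#' Connection statistics of a designed network
#'
#' Reproduces the standard design-quality summaries: per-glomerulus
#' dendrite occupancy (full = 50 / 25-49 / 1-24 / 0), granule dendrite
#' counts (0..4), Golgi basal fan-in, Golgi axon link totals,
#' ascending-axon/parallel-fiber quota fill, gap-junction degrees, and the
#' rosette-cluster size and member-distance distributions.
#'
#' @param network a [design_network()] result (stages may be missing;
#'   their summaries are omitted).
#' @return object of class `gl_connection_summary`.
#' @export
connection_stats <- function(network) {
  stopifnot(inherits(network, "gl_network"))
  cfg <- network$config
  out <- list(counts = network$counts)

  if (!is.null(network$link_grc_glo)) {
    lg <- network$link_grc_glo
    fan_in <- tabulate(lg$targets, nbins = lg$n_tgt)
    cap <- cfg$glo_grc_capacity
    out$glo_occupancy <- c(
      full = sum(fan_in == cap), partial_high = sum(fan_in >= 25 & fan_in < cap),
      partial_low = sum(fan_in >= 1 & fan_in < 25), none = sum(fan_in == 0))
    out$glo_occupancy_pct <- 100 * out$glo_occupancy / max(lg$n_tgt, 1L)
    dend <- adj_lengths(lg)
    out$grc_dendrites <- tabulate(dend + 1L,
                                  nbins = cfg$grc_dendrites_target + 1L)
    names(out$grc_dendrites) <- 0:cfg$grc_dendrites_target
    out$grc_dendrites_pct <- 100 * out$grc_dendrites / max(lg$n_src, 1L)
    out$glo_fan_in_hist <- fan_in
  }
  if (!is.null(network$link_gocdb_glo)) {
    basal <- adj_lengths(network$link_gocdb_glo)
    out$goc_basal <- c(full = sum(basal == cfg$goc_basal_mf_target),
                       partial = sum(basal > 0 &
                                       basal < cfg$goc_basal_mf_target),
                       none = sum(basal == 0))
    out$goc_basal_pct <- 100 * out$goc_basal / max(length(basal), 1L)
  }
  if (!is.null(network$link_goca_glo)) {
    axon <- adj_lengths(network$link_goca_glo)
    target <- cfg$goc_axon_max_glo * length(axon)
    out$goc_axon_links <- sum(axon)
    out$goc_axon_pct_of_target <- 100 * sum(axon) / max(target, 1L)
  }
  if (!is.null(network$aa_goc_link)) {
    aa <- adj_lengths(network$aa_goc_link)
    pf <- adj_lengths(network$pf_goc_link)
    out$aa_full_pct <- 100 * mean(aa == cfg$aa_per_goc)
    out$pf_full_pct <- 100 * mean(pf == cfg$local_pf_per_goc +
                                    cfg$distal_pf_per_goc)
    out$aa_counts <- aa
    out$pf_counts <- pf
  }
  if (!is.null(network$gap_junction)) {
    deg <- adj_lengths(network$gap_junction)
    out$gap_degree <- tabulate(deg + 1L, nbins = 3L)
    names(out$gap_degree) <- 0:2
    out$gap_degree_pct <- 100 * out$gap_degree / max(length(deg), 1L)
  }
  if (!is.null(network$clusters)) {
    out$cluster_sizes <- network$clusters$sizes
    out$cluster_size_hist <- table(network$clusters$sizes)
    out$cluster_dist_summary <- summary(network$clusters$dist_to_centroid)
    out$cluster_max_dist <- max(network$clusters$dist_to_centroid)
  }
  class(out) <- "gl_connection_summary"
  out
}

#' @export
print.gl_connection_summary <- function(x, ...) {
  cat("Connection statistics\n")
  if (!is.null(x$glo_occupancy_pct)) {
    p <- x$glo_occupancy_pct
    cat(sprintf("  GLO slots : %.2f%% full, %.2f%% 25-49, %.2f%% 1-24, %.2f%% empty\n",
                p[["full"]], p[["partial_high"]], p[["partial_low"]],
                p[["none"]]))
    d <- x$grc_dendrites_pct
    cat("  GRC dendrites:",
        paste(sprintf("%s:%.2f%%", names(d), d), collapse = " "), "\n")
  }
  if (!is.null(x$goc_basal_pct))
    cat(sprintf("  GOC basal : %.2f%% with full quota, %.2f%% unconnected\n",
                x$goc_basal_pct[["full"]], x$goc_basal_pct[["none"]]))
  if (!is.null(x$goc_axon_pct_of_target))
    cat(sprintf("  GOC axon  : %.2f%% of target links\n",
                x$goc_axon_pct_of_target))
  if (!is.null(x$aa_full_pct))
    cat(sprintf("  AA/PF     : %.2f%% / %.2f%% of GOCs with full quota\n",
                x$aa_full_pct, x$pf_full_pct))
  if (!is.null(x$gap_degree_pct)) {
    g <- x$gap_degree_pct
    cat(sprintf("  gap junctions: %.2f%% with 2, %.2f%% with 1, %.2f%% with 0\n",
                g[["2"]], g[["1"]], g[["0"]]))
  }
  if (!is.null(x$cluster_sizes))
    cat(sprintf("  clusters  : sizes %d..%d, max member distance %.1f um\n",
                min(x$cluster_sizes), max(x$cluster_sizes),
                x$cluster_max_dist))
  invisible(x)
}

#' Spatial activity map
#'
#' Bins spikes of one cell class on the x-y plane and converts them to a
#' mean firing rate (Hz per cell) per spatial bin over a time window.
#'
#' @param cell_ids raster cell ids (one entry per spike).
#' @param coords coordinate matrix for the class (row = cell id).
#' @param spike_times spike times (ms), same length as `cell_ids`.
#' @param window_ms analysis window `c(from, to)` (ms).
#' @param bin_um spatial bin side (um).
#' @param config the network configuration (for the volume extent).
#' @return object of class `gl_activity_map`: `rate_hz` matrix, bin
#'   centers `x_um` / `y_um`, `n_cells` per bin, `n_spikes`.
#' @export
activity_map <- function(cell_ids, coords, spike_times, window_ms,
                         bin_um = 25, config) {
  xb <- seq(0, config$length_um, by = bin_um)
  yb <- seq(0, config$depth_um, by = bin_um)
  if (xb[length(xb)] < config$length_um) xb <- c(xb, config$length_um)
  if (yb[length(yb)] < config$depth_um) yb <- c(yb, config$depth_um)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  cell_bin <- function(xy) {
    ix <- pmin(pmax(findInterval(xy[, 1], xb, rightmost.closed = TRUE), 1L), nx)
    iy <- pmin(pmax(findInterval(xy[, 2], yb, rightmost.closed = TRUE), 1L), ny)
    (iy - 1L) * nx + ix
  }
  bins_all <- cell_bin(coords)
  n_cells <- tabulate(bins_all, nbins = nx * ny)
  keep <- spike_times >= window_ms[1] & spike_times <= window_ms[2]
  ids <- cell_ids[keep]
  spk <- tabulate(bins_all[ids], nbins = nx * ny)
  dur_s <- (window_ms[2] - window_ms[1]) / 1000
  rate <- ifelse(n_cells > 0, spk / n_cells / dur_s, NA_real_)
  out <- list(rate_hz = matrix(rate, nx, ny),
              n_cells = matrix(n_cells, nx, ny),
              n_spikes = matrix(spk, nx, ny),
              x_um = (xb[-1] + xb[-length(xb)]) / 2,
              y_um = (yb[-1] + yb[-length(yb)]) / 2,
              window_ms = window_ms, bin_um = bin_um)
  class(out) <- "gl_activity_map"
  out
}

open_device <- function(file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    pdf = grDevices::pdf(file, width = width, height = height),
    png = grDevices::png(file, width = width * 100, height = height * 100),
    svg = grDevices::svg(file, width = width, height = height),
    stop("unsupported figure format: .", ext, call. = FALSE))
}

#' Render a spike raster / an activity map to a figure file
#'
#' `render_raster` draws the raster (time vs cell id, class-colored);
#' `render_activity_map` draws the binned firing-rate heat map. The
#' format follows the file extension (pdf, png or svg). Empty inputs give
#' an empty-axes figure rather than an error.
#'
#' @param result a `gl_sim_result` (or its `raster` data.frame).
#' @param file output path (.pdf, .png or .svg).
#' @return the file path, invisibly.
#' @export
render_raster <- function(result, file) {
  raster <- if (inherits(result, "gl_sim_result")) result$raster else result
  open_device(file, 8, 5)
  on.exit(grDevices::dev.off())
  if (nrow(raster) == 0L) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "time (ms)",
                   ylab = "cell id", main = "spike raster (empty)")
  } else {
    cls <- factor(raster$cell_class, levels = c("GOC", "GRC"))
    graphics::plot(raster$time_ms, raster$cell_id,
                   col = c("#1f77b4", "#d62728")[as.integer(cls)],
                   pch = "|", cex = 0.6, xlab = "time (ms)",
                   ylab = "cell id", main = "spike raster")
    graphics::legend("topright", legend = levels(cls),
                     col = c("#1f77b4", "#d62728"), pch = "|", bty = "n")
  }
  invisible(file)
}

#' @rdname render_raster
#' @param map a [activity_map()] result.
#' @export
render_activity_map <- function(map, file) {
  stopifnot(inherits(map, "gl_activity_map"))
  open_device(file, 6, 6)
  on.exit(grDevices::dev.off())
  z <- map$rate_hz
  z[is.na(z)] <- 0
  graphics::image(map$x_um, map$y_um, z, col = grDevices::hcl.colors(64,
                  "YlOrRd", rev = TRUE), xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("GRC firing rate (Hz), %g-%g ms",
                                 map$window_ms[1], map$window_ms[2]))
  invisible(file)
}
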