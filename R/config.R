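#' Network configuration for the granular-layer design stage
#'
#' Builds and validates the parameter set that drives neuron placement and
#' connectivity. Defaults reproduce the reference configuration: a
#' 600 x 150 x 1200 um volume with rat granular-layer densities
#' (9,000 Golgi cells / 4,000,000 granule cells / 300,000 glomeruli per mm^3).
#'
#' Axis convention: `x` runs along the volume length, `y` along the depth
#' (the direction parallel fibers travel), and `z` along the height. The
#' origin sits at one corner of the volume, all coordinates in micrometers.
#'
#' @param length_um,height_um,depth_um volume dimensions (um).
#' @param density_goc,density_grc,density_glo cell/element densities (mm^-3).
#' @param diameter_goc,diameter_grc,diameter_glo soma diameters (um).
#' @param grc_dendrites_target dendrites per granule cell (each ends in a
#'   distinct glomerulus).
#' @param max_dendrite_reach maximum granule dendrite length (um).
#' @param mean_dendrite_length mean granule dendrite length (um), kept for
#'   reporting.
#' @param glo_grc_capacity granule-dendrite slots per glomerulus.
#' @param goc_axon_max_glo maximum glomeruli inhibited by one Golgi axon.
#' @param goc_basal_mf_target mossy-fiber inputs targeted per Golgi cell
#'   basal dendrites.
#' @param aa_per_goc ascending-axon inputs per Golgi cell.
#' @param local_pf_per_goc,distal_pf_per_goc local/distal parallel-fiber
#'   inputs per Golgi cell.
#' @param gap_junctions_per_goc gap junction partners per Golgi cell.
#' @param cluster_target,cluster_delta rosette-cluster size target and
#'   half-width: final cluster sizes lie in
#'   `[cluster_target - cluster_delta, cluster_target + cluster_delta]`.
#' @param cluster_k_nearest number of nearest centroids stored per glomerulus
#'   for the rebalancing step.
#' @param cluster_max_radius maximum member-to-centroid distance (um).
#' @param n_clusters number of mossy-fiber clusters; `NA` means
#'   `floor(n_glo / cluster_target)` computed at design time.
#' @param goc_axon_field axonal field of a Golgi cell: axis-aligned box
#'   extents (um) centered on the soma, `c(x, y, z)`; the long side follows
#'   the length axis because Golgi axons spread longitudinally.
#' @param apical_major,apical_minor full axes (um) of the elliptical cylinder
#'   bounding the Golgi apical-dendrite field (major along x, minor along y).
#' @param aa_exclusion_radius radius (um) of the inner cylinder under the
#'   Golgi soma excluded from ascending-axon candidates.
#' @param basal_radius radius (um) of the basal-dendrite disk in the x-y
#'   plane.
#' @param basal_halfheight half-height (um) of the basal-dendrite slab.
#' @param gap_reach maximum Golgi-Golgi gap-junction distance (um).
#' @param placement_retry attempts per element before it is recorded as
#'   skipped.
#' @param seed integer seed controlling every random choice in the design.
#'
#' @return an object of class `gl_config` (a named list).
#' @export
network_config <- function(length_um = 600, height_um = 150, depth_um = 1200,
                           density_goc = 9000, density_grc = 4e6,
                           density_glo = 3e5,
                           diameter_goc = 15, diameter_grc = 5,
                           diameter_glo = 5,
                           grc_dendrites_target = 4L,
                           max_dendrite_reach = 40,
                           mean_dendrite_length = 13.6,
                           glo_grc_capacity = 50L,
                           goc_axon_max_glo = 40L,
                           goc_basal_mf_target = 40L,
                           aa_per_goc = 400L,
                           local_pf_per_goc = 400L,
                           distal_pf_per_goc = 1200L,
                           gap_junctions_per_goc = 2L,
                           cluster_target = 8L,
                           cluster_delta = 4L,
                           cluster_k_nearest = 100L,
                           cluster_max_radius = 350,
                           n_clusters = NA_integer_,
                           goc_axon_field = c(650, 80, 80),
                           apical_major = 150, apical_minor = 50,
                           aa_exclusion_radius = 15,
                           basal_radius = 80, basal_halfheight = 7.5,
                           gap_reach = 100,
                           placement_retry = 200L,
                           seed = 1L) {
  cfg <- list(
    length_um = length_um, height_um = height_um, depth_um = depth_um,
    density_goc = density_goc, density_grc = density_grc,
    density_glo = density_glo,
    diameter_goc = diameter_goc, diameter_grc = diameter_grc,
    diameter_glo = diameter_glo,
    grc_dendrites_target = as.integer(grc_dendrites_target),
    max_dendrite_reach = max_dendrite_reach,
    mean_dendrite_length = mean_dendrite_length,
    glo_grc_capacity = as.integer(glo_grc_capacity),
    goc_axon_max_glo = as.integer(goc_axon_max_glo),
    goc_basal_mf_target = as.integer(goc_basal_mf_target),
    aa_per_goc = as.integer(aa_per_goc),
    local_pf_per_goc = as.integer(local_pf_per_goc),
    distal_pf_per_goc = as.integer(distal_pf_per_goc),
    gap_junctions_per_goc = as.integer(gap_junctions_per_goc),
    cluster_target = as.integer(cluster_target),
    cluster_delta = as.integer(cluster_delta),
    cluster_k_nearest = as.integer(cluster_k_nearest),
    cluster_max_radius = cluster_max_radius,
    n_clusters = if (is.na(n_clusters)) NA_integer_ else as.integer(n_clusters),
    goc_axon_field = goc_axon_field,
    apical_major = apical_major, apical_minor = apical_minor,
    aa_exclusion_radius = aa_exclusion_radius,
    basal_radius = basal_radius, basal_halfheight = basal_halfheight,
    gap_reach = gap_reach,
    placement_retry = as.integer(placement_retry),
    seed = as.integer(seed)
  )
  class(cfg) <- "gl_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  dims <- c(cfg$length_um, cfg$height_um, cfg$depth_um)
  dens <- c(cfg$density_goc, cfg$density_grc, cfg$density_glo)
  diam <- c(cfg$diameter_goc, cfg$diameter_grc, cfg$diameter_glo)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid config: volume dimensions must be positive", call. = FALSE)
  if (any(!is.finite(dens)) || any(dens < 0))
    stop("invalid config: densities must be nonnegative", call. = FALSE)
  if (any(diam <= 0))
    stop("invalid config: soma diameters must be positive", call. = FALSE)
  if (any(diam > min(dims)))
    stop("invalid config: a soma diameter exceeds the smallest volume dimension",
         call. = FALSE)
  if (cfg$cluster_delta < 0 || cfg$cluster_delta >= cfg$cluster_target)
    stop("invalid config: cluster_delta must lie in [0, cluster_target)",
         call. = FALSE)
  if (cfg$placement_retry < 1L)
    stop("invalid config: placement_retry must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.gl_config <- function(x, ...) {
  v <- volume_mm3(x)
  cat("Granular-layer network configuration\n")
  cat(sprintf("  volume : %g x %g x %g um (%.6g mm^3)\n",
              x$length_um, x$height_um, x$depth_um, v))
  n <- compute_element_counts(x)
  cat(sprintf("  counts : %d GOC, %d GRC, %d GLO\n",
              n$n_goc, n$n_grc, n$n_glo))
  cat(sprintf("  seed   : %d\n", x$seed))
  invisible(x)
}

volume_mm3 <- function(cfg) {
  cfg$length_um * cfg$height_um * cfg$depth_um / 1e9
}

#' Element counts that a configured volume can host
#'
#' Applies the density rule `count = floor(density * volume)` per element
#' class. For the reference volume (0.108 mm^3) this gives 972 Golgi cells,
#' 432,000 granule cells and 32,400 glomeruli.
#'
#' @param config a [network_config()] object.
#' @return list with `n_goc`, `n_grc`, `n_glo` and the volume in mm^3.
#' @export
compute_element_counts <- function(config) {
  validate_config(config)
  v <- volume_mm3(config)
  list(n_goc = as.integer(floor(config$density_goc * v)),
       n_grc = as.integer(floor(config$density_grc * v)),
       n_glo = as.integer(floor(config$density_glo * v)),
       volume_mm3 = v)
}

#' Scaled network configurations
#'
#' Emits a configuration whose length and depth (the x and y footprint) are
#' scaled by `scale`, keeping height, densities and every connectivity
#' parameter unchanged. `scale = 0.5` gives the quarter-volume variant used
#' in scalability checks; `make_fixture("test")` gives the reduced
#' 150 x 150 x 150 um volume used throughout the test suite.
#'
#' @param scale a positive scale factor, or the string `"test"` for the
#'   150 um cube fixture.
#' @param base configuration to scale, default the reference one.
#' @param seed seed stored in the scaled configuration.
#' @return a `gl_config`.
#' @export
make_fixture <- function(scale = 1, base = network_config(), seed = base$seed) {
  if (identical(scale, "test")) {
    cfg <- base
    cfg$length_um <- 150
    cfg$height_um <- 150
    cfg$depth_um <- 150
  } else {
    if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
      stop("invalid config: scale must be a positive number", call. = FALSE)
    cfg <- base
    cfg$length_um <- base$length_um * scale
    cfg$depth_um <- base$depth_um * scale
  }
  cfg$seed <- as.integer(seed)
  if (min(cfg$length_um, cfg$depth_um, cfg$height_um) < cfg$diameter_goc)
    stop("invalid config: scaled volume smaller than one Golgi box",
         call. = FALSE)
  validate_config(cfg)
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as flat JSON (or YAML if the file extension is
#' `.yml`/`.yaml` and the yaml package is available) mirroring the
#' [network_config()] field names.
#'
#' @param path file path.
#' @param config a `gl_config` object (for writing).
#' @return `read_config` returns a `gl_config`.
#' @export
read_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fields <- fields[!vapply(fields, function(x)
    is.null(x) || length(x) == 0L, TRUE)]
  if (is.null(fields$n_clusters)) fields$n_clusters <- NA_integer_
  do.call(network_config, fields)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to write YAML configs", call. = FALSE)
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  }
  invisible(path)
}
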