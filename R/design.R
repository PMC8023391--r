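#' Design a granular-layer network
#'
#' Runs the full network-design stage: element placement, the six
#' connection matrices and the mossy-fiber rosette clustering, in a fixed
#' order under `config$seed` so identical configurations give bit-identical
#' networks.
#'
#' Stage order (RNG consumption order): placement; granule-glomerulus
#' dendrites; Golgi-axon inhibition; Golgi basal dendrites;
#' ascending-axon/parallel-fiber contacts; gap junctions; rosette
#' clustering.
#'
#' @param config a [network_config()].
#' @param stages which stages to run: `"all"` or a subset of
#'   `c("grc_glo", "goca_glo", "gocdb_glo", "grc_goc", "gap", "clusters")`
#'   (placement always runs). Skipped stages are `NULL` in the result;
#'   `"goca_glo"` implies `"grc_glo"`.
#' @return object of class `gl_network`: the placement, connection matrices
#'   (`link_grc_glo`, `link_goca_glo`, `link_gocdb_glo`, `aa_goc_link`,
#'   `pf_goc_link`, `gap_junction`, `mf_glom_clustering`), the cluster
#'   assignment, counts (including `n_mf` = number of clusters) and the
#'   configuration.
#' @export
design_network <- function(config = network_config(), stages = "all") {
  validate_config(config)
  all_stages <- c("grc_glo", "goca_glo", "gocdb_glo", "grc_goc", "gap",
                  "clusters")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if ("goca_glo" %in% stages) stages <- union(stages, "grc_glo")

  placement <- place_elements(config)   # seeds the RNG with config$seed

  link_grc_glo <- if ("grc_glo" %in% stages)
    connect_grc_glo(placement, config)
  link_goca_glo <- if ("goca_glo" %in% stages)
    connect_goc_axon_glo(placement, link_grc_glo, config)
  link_gocdb_glo <- if ("gocdb_glo" %in% stages)
    connect_goc_basal_glo(placement, config)
  grc_goc <- if ("grc_goc" %in% stages) connect_grc_goc(placement, config)
  gap_junction <- if ("gap" %in% stages)
    connect_gap_junctions(placement, config)

  clusters <- NULL
  mf_glo <- NULL
  n_mf <- 0L
  if ("clusters" %in% stages) {
    n_glo <- nrow(placement$c_glo)
    n_clusters <- if (is.na(config$n_clusters))
      floor(n_glo / config$cluster_target) else config$n_clusters
    clusters <- cluster_mf_rosettes(placement$c_glo, n_clusters, config)
    n_mf <- clusters$n_clusters
    mf_glo <- adj_from_flat(clusters$cluster, seq_len(n_glo),
                            n_src = n_mf, n_tgt = n_glo,
                            name = "mf_glo")
  }

  net <- list(
    placement = placement,
    link_grc_glo = link_grc_glo,
    link_goca_glo = link_goca_glo,
    link_gocdb_glo = link_gocdb_glo,
    aa_goc_link = grc_goc$aa_goc_link,
    pf_goc_link = grc_goc$pf_goc_link,
    gap_junction = gap_junction,
    clusters = clusters,
    mf_glom_clustering = if (!is.null(clusters)) clusters$cluster,
    mf_glo = mf_glo,
    counts = list(n_goc = nrow(placement$c_goc),
                  n_grc = nrow(placement$c_grc),
                  n_glo = nrow(placement$c_glo),
                  n_mf = n_mf),
    config = config
  )
  class(net) <- "gl_network"
  net
}

#' @export
print.gl_network <- function(x, ...) {
  cat("Granular-layer network\n")
  cat(sprintf("  %d GOC, %d GRC, %d GLO, %d MF (volume %g x %g x %g um)\n",
              x$counts$n_goc, x$counts$n_grc, x$counts$n_glo, x$counts$n_mf,
              x$config$length_um, x$config$height_um, x$config$depth_um))
  for (nm in c("link_grc_glo", "link_goca_glo", "link_gocdb_glo",
               "aa_goc_link", "pf_goc_link", "gap_junction")) {
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-15s %d links\n", nm, length(x[[nm]]$targets)))
  }
  invisible(x)
}

#' @export
summary.gl_network <- function(object, ...) {
  connection_stats(object)
}
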