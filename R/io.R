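#' Write / read a designed network container
#'
#' The network container is a single hierarchical JSON file holding the
#' configuration and seed (provenance), the coordinate arrays (um) and
#' every connection matrix as ragged integer id lists with per-row
#' offsets. `read_network` validates the schema and every stored id
#' against the element counts, naming the offending matrix on failure;
#' the write-read round trip is exact for integers and stored floats.
#'
#' @param network a [design_network()] result.
#' @param path file path (`.json`).
#' @return `read_network` returns the reconstructed `gl_network`.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "gl_network"))
  ser_adj <- function(a) if (!is.null(a))
    list(targets = a$targets, ptr = a$ptr, tag = a$tag,
         n_src = a$n_src, n_tgt = a$n_tgt, name = a$name)
  payload <- list(
    format = "granlayer-network", version = 1L,
    config = unclass(network$config),
    seed = network$config$seed,
    counts = network$counts,
    coordinates = list(c_goc = network$placement$c_goc,
                       c_glo = network$placement$c_glo,
                       c_grc = network$placement$c_grc),
    placement = list(placed = as.list(network$placement$placed),
                     skipped = as.list(network$placement$skipped),
                     target = as.list(network$placement$target)),
    matrices = list(link_grc_glo = ser_adj(network$link_grc_glo),
                    link_goca_glo = ser_adj(network$link_goca_glo),
                    link_gocdb_glo = ser_adj(network$link_gocdb_glo),
                    aa_goc_link = ser_adj(network$aa_goc_link),
                    pf_goc_link = ser_adj(network$pf_goc_link),
                    gap_junction = ser_adj(network$gap_junction)),
    clusters = if (!is.null(network$clusters)) list(
      cluster = network$clusters$cluster,
      centroids = network$clusters$centroids,
      n_clusters = network$clusters$n_clusters,
      sizes = network$clusters$sizes,
      dist_to_centroid = network$clusters$dist_to_centroid)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "granlayer-network"))
    stop("format error: not a granlayer network container", call. = FALSE)
  for (f in c("config", "counts", "coordinates", "matrices"))
    if (is.null(raw[[f]]))
      stop("format error: container missing field '", f, "'",
           call. = FALSE)
  cfgl <- raw$config
  cfgl <- cfgl[!vapply(cfgl, function(x) is.null(x) || all(is.na(x)), TRUE)]
  if (is.null(cfgl$n_clusters)) cfgl$n_clusters <- NA_integer_
  cfg <- do.call(network_config, cfgl)
  counts <- raw$counts
  mk_coords <- function(m, nm) {
    m <- as.matrix(m)
    if (ncol(m) != 3)
      stop("format error: coordinate array '", nm, "' must have 3 columns",
           call. = FALSE)
    colnames(m) <- c("x", "y", "z")
    m
  }
  pl <- list(
    c_goc = mk_coords(raw$coordinates$c_goc, "c_goc"),
    c_glo = mk_coords(raw$coordinates$c_glo, "c_glo"),
    c_grc = mk_coords(raw$coordinates$c_grc, "c_grc"),
    placed = unlist(raw$placement$placed),
    skipped = unlist(raw$placement$skipped),
    target = unlist(raw$placement$target),
    config = cfg
  )
  class(pl) <- "gl_placement"

  de_adj <- function(x, nm) {
    if (is.null(x)) return(NULL)
    a <- list(targets = as.integer(x$targets), ptr = as.integer(x$ptr),
              tag = if (!is.null(x$tag) && length(x$tag))
                as.integer(x$tag),
              n_src = as.integer(x$n_src), n_tgt = as.integer(x$n_tgt),
              name = nm)
    class(a) <- "gl_adj"
    if (length(a$ptr) != a$n_src + 1L ||
        utils::tail(a$ptr, 1L) != length(a$targets))
      stop("format error: matrix '", nm, "' has inconsistent offsets",
           call. = FALSE)
    if (length(a$targets) &&
        (min(a$targets) < 1L || max(a$targets) > a$n_tgt))
      stop("format error: matrix '", nm, "' holds an id outside 1..",
           a$n_tgt, call. = FALSE)
    a
  }
  mats <- raw$matrices
  clusters <- NULL
  if (!is.null(raw$clusters)) {
    clusters <- list(cluster = as.integer(raw$clusters$cluster),
                     centroids = as.matrix(raw$clusters$centroids),
                     n_clusters = as.integer(raw$clusters$n_clusters),
                     sizes = as.integer(raw$clusters$sizes),
                     dist_to_centroid = raw$clusters$dist_to_centroid)
    class(clusters) <- "gl_clusters"
    if (length(clusters$cluster) &&
        max(clusters$cluster) > clusters$n_clusters)
      stop("format error: matrix 'mf_glom_clustering' holds an id outside 1..",
           clusters$n_clusters, call. = FALSE)
  }
  net <- list(
    placement = pl,
    link_grc_glo = de_adj(mats$link_grc_glo, "link_grc_glo"),
    link_goca_glo = de_adj(mats$link_goca_glo, "link_goca_glo"),
    link_gocdb_glo = de_adj(mats$link_gocdb_glo, "link_gocdb_glo"),
    aa_goc_link = de_adj(mats$aa_goc_link, "aa_goc_link"),
    pf_goc_link = de_adj(mats$pf_goc_link, "pf_goc_link"),
    gap_junction = de_adj(mats$gap_junction, "gap_junction"),
    clusters = clusters,
    mf_glom_clustering = if (!is.null(clusters)) clusters$cluster,
    mf_glo = if (!is.null(clusters))
      adj_from_flat(clusters$cluster, seq_along(clusters$cluster),
                    n_src = clusters$n_clusters,
                    n_tgt = length(clusters$cluster), name = "mf_glo"),
    counts = counts,
    config = cfg
  )
  class(net) <- "gl_network"
  net
}

#' Export connection matrices / rasters as CSV
#'
#' One CSV per connection matrix with columns `source_id`, `target_id`,
#' `tag`; the raster export has columns `cell_class`, `cell_id`,
#' `spike_time_ms`.
#'
#' @param network a `gl_network`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
export_matrices_csv <- function(network, dir) {
  stopifnot(inherits(network, "gl_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- c("link_grc_glo", "link_goca_glo", "link_gocdb_glo",
           "aa_goc_link", "pf_goc_link", "gap_junction")
  paths <- character(0)
  for (nm in nms) {
    if (is.null(network[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(adj_pairs(network[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(network$mf_glom_clustering)) {
    p <- file.path(dir, "mf_glom_clustering.csv")
    utils::write.csv(data.frame(source_id = network$mf_glom_clustering,
                                target_id = seq_along(network$mf_glom_clustering),
                                tag = NA_integer_),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname export_matrices_csv
#' @param path CSV file to read back into a connection matrix.
#' @param n_src,n_tgt matrix dimensions.
#' @export
import_adjacency_csv <- function(path, n_src, n_tgt) {
  d <- utils::read.csv(path)
  adj_from_flat(d$source_id, d$target_id, n_src, n_tgt,
                tag = if (!all(is.na(d$tag))) d$tag,
                name = sub("\\.csv$", "", basename(path)))
}

#' @rdname export_matrices_csv
#' @param result a `gl_sim_result`.
#' @param file output CSV path.
#' @export
write_raster_csv <- function(result, file) {
  raster <- if (inherits(result, "gl_sim_result")) result$raster else result
  out <- data.frame(cell_class = raster$cell_class,
                    cell_id = raster$cell_id,
                    spike_time_ms = raster$time_ms)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
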