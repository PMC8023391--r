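#' Cluster glomeruli into mossy-fiber rosette groups
#'
#' Mossy fibers branch into clusters of rosettes; each rosette is the
#' presynaptic element of one glomerulus, so glomeruli are grouped into
#' `n_clusters` balanced clusters of size `cluster_target +/-
#' cluster_delta` (default 8 +/- 4), every member within
#' `cluster_max_radius` (350 um) of its cluster centroid.
#'
#' Procedure: centroids are initialized pseudo-randomly on glomerulus
#' positions; every glomerulus is assigned to its nearest centroid and its
#' `cluster_k_nearest` (100) nearest centroids are recorded, sorted by
#' distance. Over-full clusters (size above `target + delta`, the
#' `buffer_high` set) then shed their farthest members: a shed glomerulus
#' moves preferentially to one of its K-nearest clusters that is under-full
#' (size below `target - delta`, the `buffer_low` set), otherwise to the
#' nearest cluster with size below `target + delta/2`, otherwise to the
#' nearest still below `target + delta`; moves never exceed the 350 um
#' radius. A final pass pulls the nearest spare glomeruli into clusters
#' still below `target - delta`.
#'
#' @param glo_coords matrix of glomerulus coordinates (um).
#' @param n_clusters number of clusters; default `floor(n_glo /
#'   cluster_target)`.
#' @param config a [network_config()].
#' @return object of class `gl_clusters`: `cluster` (per-glomerulus cluster
#'   id), `centroids`, `sizes`, `dist_to_centroid`, `k_nearest_id` /
#'   `k_nearest_dist` matrices, and the initial `primary` assignment record.
#' @export
cluster_mf_rosettes <- function(glo_coords,
                                n_clusters = floor(nrow(glo_coords) /
                                                     config$cluster_target),
                                config = network_config()) {
  n_glo <- nrow(glo_coords)
  target <- config$cluster_target
  delta <- config$cluster_delta
  max_r <- config$cluster_max_radius
  if (n_clusters < 1L)
    stop("invalid config: n_clusters must be >= 1", call. = FALSE)
  if (n_clusters * (target + delta) < n_glo ||
      n_clusters * (target - delta) > n_glo)
    stop("invalid config: cluster size bounds cannot partition the glomeruli",
         call. = FALSE)

  centroids <- glo_coords[sample.int(n_glo, n_clusters), , drop = FALSE]
  K <- min(config$cluster_k_nearest, n_clusters)

  ## chunked distance computation: nearest centroid + K-nearest lists
  cluster <- integer(n_glo)
  dmin <- numeric(n_glo)
  kn_id <- matrix(0L, n_glo, K)
  kn_d <- matrix(0, n_glo, K)
  chunk <- max(1L, floor(2e7 / n_clusters))
  ctr_sq <- rowSums(centroids^2)
  for (i0 in seq(1L, n_glo, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n_glo)
    g <- glo_coords[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(g^2), ctr_sq, "+") - 2 * tcrossprod(g, centroids)
    d2[d2 < 0] <- 0
    for (r in seq_len(nrow(d2))) {
      ord <- order(d2[r, ])[seq_len(K)]
      kn_id[i0 + r - 1L, ] <- ord
      kn_d[i0 + r - 1L, ] <- sqrt(d2[r, ord])
    }
  }
  cluster <- kn_id[, 1]
  dmin <- kn_d[, 1]
  primary <- list(ID_glo = seq_len(n_glo), ID_primary = cluster,
                  dist_primary = dmin)
  sizes <- tabulate(cluster, nbins = n_clusters)

  members <- split(seq_len(n_glo), factor(cluster, levels = seq_len(n_clusters)))

  buffer_high <- which(sizes > target + delta)
  buffer_low <- which(sizes < target - delta)

  ## shed the farthest members of over-full clusters
  for (cl in buffer_high) {
    mem <- members[[cl]]
    ord <- mem[order(kn_dist_to(kn_id, kn_d, mem, cl), decreasing = TRUE)]
    j <- 1L
    while (sizes[cl] > target + delta && j <= length(ord)) {
      g <- ord[j]; j <- j + 1L
      dest <- pick_destination(g, cl, sizes, kn_id, kn_d, centroids,
                               glo_coords, target, delta, max_r)
      if (is.na(dest)) next
      sizes[cl] <- sizes[cl] - 1L
      sizes[dest] <- sizes[dest] + 1L
      cluster[g] <- dest
      members[[cl]] <- setdiff(members[[cl]], g)
      members[[dest]] <- c(members[[dest]], g)
    }
  }

  ## pull spare glomeruli into clusters still under-full
  for (cl in which(sizes < target - delta)) {
    while (sizes[cl] < target - delta) {
      d <- sqrt(colSums((t(glo_coords) - centroids[cl, ])^2))
      ord <- order(d)
      took <- FALSE
      for (g in ord) {
        if (cluster[g] == cl) next
        if (d[g] > max_r) break
        donor <- cluster[g]
        if (sizes[donor] <= target - delta) next
        sizes[donor] <- sizes[donor] - 1L
        sizes[cl] <- sizes[cl] + 1L
        members[[donor]] <- setdiff(members[[donor]], g)
        members[[cl]] <- c(members[[cl]], g)
        cluster[g] <- cl
        took <- TRUE
        break
      }
      if (!took) break   # no reachable spare member; leave under-full
    }
  }

  dist_final <- sqrt(rowSums((glo_coords - centroids[cluster, , drop = FALSE])^2))
  out <- list(cluster = cluster, centroids = centroids,
              sizes = tabulate(cluster, nbins = n_clusters),
              dist_to_centroid = dist_final,
              k_nearest_id = kn_id, k_nearest_dist = kn_d,
              primary = primary, n_clusters = as.integer(n_clusters),
              buffer_high = buffer_high, buffer_low = buffer_low)
  class(out) <- "gl_clusters"
  out
}

## distance from members to a given centroid, read off the K-nearest table
## (falls back to direct computation when the centroid is not in the list)
kn_dist_to <- function(kn_id, kn_d, mem, cl) {
  d <- numeric(length(mem))
  for (i in seq_along(mem)) {
    hit <- match(cl, kn_id[mem[i], ])
    d[i] <- if (is.na(hit)) Inf else kn_d[mem[i], hit]
  }
  d
}

pick_destination <- function(g, from, sizes, kn_id, kn_d, centroids,
                             glo_coords, target, delta, max_r) {
  ids <- kn_id[g, ]; ds <- kn_d[g, ]
  ok <- ids != from & ds <= max_r
  ## 1) K-nearest cluster that is under-full
  cand <- which(ok & sizes[ids] < target - delta)
  if (length(cand)) return(ids[cand[1L]])
  ## 2) nearest cluster below target + delta/2, then 3) below target + delta
  d_all <- sqrt(colSums((t(centroids) - glo_coords[g, ])^2))
  d_all[from] <- Inf
  for (bound in c(target + delta / 2, target + delta)) {
    cand <- which(sizes < bound & d_all <= max_r)
    if (length(cand)) return(cand[which.min(d_all[cand])])
  }
  NA_integer_
}

#' @export
print.gl_clusters <- function(x, ...) {
  cat(sprintf("mossy-fiber clustering: %d glomeruli in %d clusters\n",
              length(x$cluster), x$n_clusters))
  cat(sprintf("  sizes %d..%d (mean %.2f), max member-centroid distance %.1f um\n",
              min(x$sizes), max(x$sizes), mean(x$sizes),
              max(x$dist_to_centroid)))
  invisible(x)
}
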