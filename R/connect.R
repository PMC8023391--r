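#' Connect granule dendrites to glomeruli
#'
#' Links every granule cell to up to `grc_dendrites_target` (default 4)
#' distinct glomeruli lying within `max_dendrite_reach` (40 um), each
#' glomerulus offering `glo_grc_capacity` (50) dendrite slots. Candidate
#' order is random under the current RNG state; when local capacity runs out
#' a granule cell keeps a partial dendrite set, which is valid output rather
#' than an error.
#'
#' The assignment is computed by batched random-priority matching: every
#' candidate granule-glomerulus pair inside the 40 um reach receives an
#' i.i.d. priority, granule cells repeatedly propose their best-priority
#' candidates and glomeruli accept proposals in priority order up to their
#' free capacity, until no proposal can be accepted.
#'
#' @param placement a [place_elements()] result.
#' @param config the [network_config()].
#' @param max_candidates how many (randomly chosen) in-reach glomeruli each
#'   granule cell keeps as candidates; bounds memory at full scale.
#' @return `gl_adj` connection matrix, granule -> glomerulus.
#' @export
connect_grc_glo <- function(placement, config, max_candidates = 24L) {
  grc <- placement$c_grc; glo <- placement$c_glo
  n_grc <- nrow(grc); n_glo <- nrow(glo)
  if (n_grc == 0L || n_glo == 0L)
    return(new_adj(rep(list(integer(0)), n_grc), n_grc, n_glo,
                   name = "link_grc_glo"))
  reach <- config$max_dendrite_reach

  pairs <- candidate_pairs(grc, glo, reach, max_candidates)

  need <- rep.int(config$grc_dendrites_target, n_grc)
  cap <- rep.int(config$glo_grc_capacity, n_glo)
  acc_src <- vector("list", 64); acc_tgt <- vector("list", 64); k <- 0L

  src <- pairs$src; tgt <- pairs$tgt; pri <- pairs$pri
  repeat {
    keep <- need[src] > 0L & cap[tgt] > 0L
    src <- src[keep]; tgt <- tgt[keep]; pri <- pri[keep]
    if (length(src) == 0L) break
    ## proposals: each source's `need` best-priority candidates
    o <- order(src, pri, method = "radix")
    src <- src[o]; tgt <- tgt[o]; pri <- pri[o]
    rk <- sequence(rle_lengths(src))
    prop <- rk <= need[src]
    ## acceptance: each target takes proposals in priority order up to cap
    ps <- src[prop]; pt <- tgt[prop]; pp <- pri[prop]
    o2 <- order(pt, pp, method = "radix")
    ps <- ps[o2]; pt <- pt[o2]
    rk2 <- sequence(rle_lengths(pt))
    ok <- rk2 <= cap[pt]
    if (!any(ok)) break
    a_src <- ps[ok]; a_tgt <- pt[ok]
    k <- k + 1L
    acc_src[[k]] <- a_src; acc_tgt[[k]] <- a_tgt
    need_dec <- tabulate(a_src, nbins = n_grc)
    cap_dec <- tabulate(a_tgt, nbins = n_glo)
    need <- need - need_dec
    cap <- cap - cap_dec
    ## drop accepted pairs from the pool
    key_all <- (as.double(src) - 1) * n_glo + as.double(tgt)
    key_acc <- (as.double(a_src) - 1) * n_glo + as.double(a_tgt)
    drop <- key_all %in% key_acc
    src <- src[!drop]; tgt <- tgt[!drop]; pri <- pri[!drop]
  }
  links_src <- unlist(acc_src[seq_len(k)], use.names = FALSE)
  links_tgt <- unlist(acc_tgt[seq_len(k)], use.names = FALSE)
  adj_from_flat(links_src, links_tgt, n_grc, n_glo, name = "link_grc_glo")
}

## run-lengths of a sorted integer vector (group sizes in order)
rle_lengths <- function(x) {
  if (length(x) == 0L) return(integer(0))
  brk <- c(which(x[-1L] != x[-length(x)]), length(x))
  diff(c(0L, brk))
}

## All (source point, target point) pairs within `reach`, thinned to at most
## `max_candidates` random targets per source; columns src, tgt, pri.
## Cell-list search: targets are registered in every cubic cell their reach
## ball touches; sources then only scan their own cell.
candidate_pairs <- function(src_xyz, tgt_xyz, reach, max_candidates,
                            chunk = 25000L) {
  cs <- reach / 2
  lo <- floor((tgt_xyz - reach) / cs)
  hi <- floor((tgt_xyz + reach) / cs)
  steps_x <- max(hi[, 1] - lo[, 1]) ; steps_y <- max(hi[, 2] - lo[, 2])
  steps_z <- max(hi[, 3] - lo[, 3])
  offs <- as.matrix(expand.grid(dx = 0:steps_x, dy = 0:steps_y,
                                dz = 0:steps_z))
  n_tgt <- nrow(tgt_xyz)
  reg <- vector("list", nrow(offs))
  for (j in seq_len(nrow(offs))) {
    cx <- lo[, 1] + offs[j, 1]; cy <- lo[, 2] + offs[j, 2]
    cz <- lo[, 3] + offs[j, 3]
    keep <- cx <= hi[, 1] & cy <= hi[, 2] & cz <= hi[, 3]
    reg[[j]] <- data.table::data.table(
      cx = cx[keep], cy = cy[keep], cz = cz[keep],
      tgt = which(keep),
      tx = tgt_xyz[keep, 1], ty = tgt_xyz[keep, 2], tz = tgt_xyz[keep, 3])
  }
  reg <- data.table::rbindlist(reg)
  data.table::setkey(reg, cx, cy, cz)

  n_src <- nrow(src_xyz)
  out <- vector("list", ceiling(n_src / chunk))
  r2 <- reach^2
  for (ci in seq_along(out)) {
    i0 <- (ci - 1L) * chunk + 1L
    i1 <- min(ci * chunk, n_src)
    idx <- i0:i1
    q <- data.table::data.table(
      cx = floor(src_xyz[idx, 1] / cs), cy = floor(src_xyz[idx, 2] / cs),
      cz = floor(src_xyz[idx, 3] / cs),
      src = idx, sx = src_xyz[idx, 1], sy = src_xyz[idx, 2],
      sz = src_xyz[idx, 3])
    m <- reg[q, on = c("cx", "cy", "cz"), allow.cartesian = TRUE,
             nomatch = NULL]
    d2 <- (m$sx - m$tx)^2 + (m$sy - m$ty)^2 + (m$sz - m$tz)^2
    m <- m[d2 <= r2, list(src, tgt)]
    if (nrow(m) == 0L) { out[[ci]] <- m[, list(src, tgt, pri = numeric(0))]; next }
    m[, pri := stats::runif(.N)]
    data.table::setorder(m, src, pri)
    m <- m[, utils::head(.SD, max_candidates), by = src]
    out[[ci]] <- m
  }
  res <- data.table::rbindlist(out)
  list(src = res$src, tgt = res$tgt, pri = res$pri)
}

#' Connect Golgi axons to glomeruli (granule inhibition)
#'
#' Each Golgi axon may inhibit at most `goc_axon_max_glo` (40) glomeruli
#' inside its axonal field, an axis-aligned box centered on the soma and
#' elongated along the length axis. A glomerulus is only accepted when it
#' shares no granule cell with the glomeruli already chosen for that Golgi
#' cell, so no granule cell is inhibited twice by the same Golgi cell.
#' Candidates are visited in random order.
#'
#' @param placement a [place_elements()] result.
#' @param link_grc_glo granule-to-glomerulus matrix (needed for the
#'   no-double-inhibition rule).
#' @param config the [network_config()].
#' @return `gl_adj`, Golgi -> glomerulus.
#' @export
connect_goc_axon_glo <- function(placement, link_grc_glo, config) {
  goc <- placement$c_goc; glo <- placement$c_glo
  n_goc <- nrow(goc); n_glo <- nrow(glo); n_grc <- nrow(placement$c_grc)
  glo_grc <- adj_invert(link_grc_glo, "glo_grc")
  half <- config$goc_axon_field / 2
  cap <- config$goc_axon_max_glo
  rows <- vector("list", n_goc)
  seen <- logical(n_grc)
  for (i in seq_len(n_goc)) {
    in_box <- which(abs(glo[, 1] - goc[i, 1]) <= half[1] &
                    abs(glo[, 2] - goc[i, 2]) <= half[2] &
                    abs(glo[, 3] - goc[i, 3]) <= half[3])
    if (length(in_box) == 0L) { rows[[i]] <- integer(0); next }
    cand <- in_box[sample.int(length(in_box))]
    chosen <- integer(0)
    touched <- integer(0)
    for (g in cand) {
      members <- adj_row(glo_grc, g)
      if (length(members) && any(seen[members])) next
      chosen <- c(chosen, g)
      seen[members] <- TRUE
      touched <- c(touched, members)
      if (length(chosen) >= cap) break
    }
    seen[touched] <- FALSE
    rows[[i]] <- chosen
  }
  new_adj(rows, n_goc, n_glo, name = "link_goca_glo")
}

#' Connect Golgi basal dendrites to glomeruli (mossy-fiber excitation)
#'
#' Golgi basal dendrites spread around the soma on its horizontal plane;
#' each Golgi cell picks up to `goc_basal_mf_target` (40) glomeruli at
#' random inside a disk of radius `basal_radius` in the x-y plane, within
#' `basal_halfheight` of the soma height.
#'
#' @inheritParams connect_goc_axon_glo
#' @return `gl_adj`, Golgi -> glomerulus.
#' @export
connect_goc_basal_glo <- function(placement, config) {
  goc <- placement$c_goc; glo <- placement$c_glo
  n_goc <- nrow(goc); n_glo <- nrow(glo)
  r2 <- config$basal_radius^2
  rows <- vector("list", n_goc)
  for (i in seq_len(n_goc)) {
    d2 <- (glo[, 1] - goc[i, 1])^2 + (glo[, 2] - goc[i, 2])^2
    ok <- which(d2 <= r2 & abs(glo[, 3] - goc[i, 3]) <= config$basal_halfheight)
    n_take <- min(length(ok), config$goc_basal_mf_target)
    rows[[i]] <- if (n_take > 0L) ok[sample.int(length(ok), n_take)]
                 else integer(0)
  }
  new_adj(rows, n_goc, n_glo, name = "link_gocdb_glo")
}

#' Connect granule cells to Golgi cells (ascending axon and parallel fibers)
#'
#' For every Golgi cell an elliptical cylinder is built around the soma
#' (major axis `apical_major` along x, minor axis `apical_minor` along y,
#' spanning the full height): granule cells inside it can contact the
#' apical dendrites directly through their ascending axon, excluding a small
#' cylinder directly under the soma where contacts are unlikely. Parallel
#' fibers run along the depth (y) axis, so any granule cell whose (x, z)
#' track crosses the apical field can contact it: from inside the ellipse
#' these are local parallel-fiber contacts, from outside distal ones.
#' Quotas: `aa_per_goc` (400) ascending-axon, `local_pf_per_goc` (400)
#' local and `distal_pf_per_goc` (1200) distal contacts, sampled uniformly;
#' shortfalls occur only when a candidate set is exhausted.
#'
#' @inheritParams connect_goc_axon_glo
#' @return list with `aa_goc_link` (Golgi -> granule) and `pf_goc_link`
#'   (Golgi -> granule, tag 1 = local, 2 = distal).
#' @export
connect_grc_goc <- function(placement, config) {
  goc <- placement$c_goc; grc <- placement$c_grc
  n_goc <- nrow(goc); n_grc <- nrow(grc)
  a <- config$apical_major / 2; b <- config$apical_minor / 2
  rex2 <- config$aa_exclusion_radius^2
  ox <- order(grc[, 1])
  gx_sorted <- grc[ox, 1]
  aa_rows <- vector("list", n_goc)
  pf_rows <- vector("list", n_goc)
  pf_tags <- vector("list", n_goc)
  for (i in seq_len(n_goc)) {
    lo <- findInterval(goc[i, 1] - a, gx_sorted) + 1L
    hi <- findInterval(goc[i, 1] + a, gx_sorted)
    if (hi < lo) {
      aa_rows[[i]] <- integer(0); pf_rows[[i]] <- integer(0)
      pf_tags[[i]] <- integer(0); next
    }
    idx <- ox[lo:hi]
    dx <- grc[idx, 1] - goc[i, 1]
    dy <- grc[idx, 2] - goc[i, 2]
    in_ellipse <- (dx / a)^2 + (dy / b)^2 <= 1
    inner <- dx^2 + dy^2 <= rex2
    aa_cand <- idx[in_ellipse & !inner]
    aa_take <- min(length(aa_cand), config$aa_per_goc)
    aa_sel <- if (aa_take > 0L) aa_cand[sample.int(length(aa_cand), aa_take)]
              else integer(0)
    aa_rows[[i]] <- aa_sel
    ## local PF: in-ellipse granule cells not used for the AA contact
    loc_cand <- setdiff(idx[in_ellipse], aa_sel)
    loc_take <- min(length(loc_cand), config$local_pf_per_goc)
    loc_sel <- if (loc_take > 0L)
      loc_cand[sample.int(length(loc_cand), loc_take)] else integer(0)
    ## distal PF: |dx| <= a already guaranteed by the window; outside ellipse
    dist_cand <- idx[!in_ellipse]
    dist_take <- min(length(dist_cand), config$distal_pf_per_goc)
    dist_sel <- if (dist_take > 0L)
      dist_cand[sample.int(length(dist_cand), dist_take)] else integer(0)
    pf_rows[[i]] <- c(loc_sel, dist_sel)
    pf_tags[[i]] <- c(rep.int(1L, length(loc_sel)),
                      rep.int(2L, length(dist_sel)))
  }
  list(aa_goc_link = new_adj(aa_rows, n_goc, n_grc, name = "aa_goc_link"),
       pf_goc_link = new_adj(pf_rows, n_goc, n_grc, tags = pf_tags,
                             name = "pf_goc_link"))
}

#' Connect Golgi cells through gap junctions
#'
#' Every Golgi cell is electrically coupled to its up-to-2 nearest eligible
#' neighbors within `gap_reach`; links are symmetric and cells at the volume
#' border may end with one or zero partners. Pairs are formed greedily in
#' ascending distance order, each cell accepting partners while it has free
#' slots (ties broken by lowest id pair).
#'
#' @inheritParams connect_goc_axon_glo
#' @return `gl_adj`, Golgi -> Golgi, symmetric.
#' @export
connect_gap_junctions <- function(placement, config) {
  goc <- placement$c_goc
  n <- nrow(goc)
  cap <- config$gap_junctions_per_goc
  if (n < 2L) return(new_adj(rep(list(integer(0)), n), n, n,
                             name = "gap_junction"))
  d <- as.matrix(stats::dist(goc))
  pairs <- which(upper.tri(d) & d <= config$gap_reach, arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    return(new_adj(rep(list(integer(0)), n), n, n, name = "gap_junction"))
  pd <- d[pairs]
  o <- order(pd, pairs[, 1], pairs[, 2])
  pairs <- pairs[o, , drop = FALSE]
  deg <- integer(n)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (deg[i] < cap && deg[j] < cap) {
      keep[k] <- TRUE
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  adj_from_flat(c(pairs[, 1], pairs[, 2]), c(pairs[, 2], pairs[, 1]),
                n, n, name = "gap_junction")
}
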