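#' Place Golgi cells, glomeruli and granule cells in the volume
#'
#' The height of the volume is divided into layers sized by the soma
#' diameter of the class being placed; each layer is a grid of square-based
#' boxes (box side = soma diameter) and every box hosts at most one element,
#' which fixes the x and y coordinates at the box center while z is drawn
#' uniformly inside the box (degenerating to the box mid-height when the box
#' height equals the diameter). Golgi cells are placed first; glomeruli and
#' granule cells then share one finer grid (which prevents same-class and
#' glomerulus-granule overlaps) with the extra constraint that their somata
#' must not intersect any Golgi soma. Each element gets up to
#' `config$placement_retry` random box draws before being recorded as
#' skipped.
#'
#' All randomness is driven by `config$seed`; identical configurations give
#' bit-identical placements.
#'
#' @param config a [network_config()].
#' @return an object of class `gl_placement`: coordinate matrices `c_goc`,
#'   `c_glo`, `c_grc` (columns x, y, z in um), per-class `placed` and
#'   `skipped` counts, and the target counts.
#' @export
place_elements <- function(config) {
  validate_config(config)
  counts <- compute_element_counts(config)
  set.seed(config$seed)

  ## -- Golgi cells: own grid -------------------------------------------
  goc <- place_boxed(
    n = counts$n_goc, d = config$diameter_goc, config = config,
    occupied = NULL, goc_coords = NULL, clearance = 0,
    retry = config$placement_retry
  )

  ## -- glomeruli + granules: shared fine grid --------------------------
  d_small <- max(config$diameter_glo, config$diameter_grc)
  grid <- grid_spec(d_small, config)
  occupied <- new.env(parent = emptyenv())
  occupied$taken <- logical(grid$n_boxes)
  clearance_glo <- (config$diameter_goc + config$diameter_glo) / 2
  clearance_grc <- (config$diameter_goc + config$diameter_grc) / 2

  glo <- place_boxed(
    n = counts$n_glo, d = d_small, config = config,
    occupied = occupied, goc_coords = goc$coords,
    clearance = clearance_glo, retry = config$placement_retry, grid = grid
  )
  grc <- place_boxed(
    n = counts$n_grc, d = d_small, config = config,
    occupied = occupied, goc_coords = goc$coords,
    clearance = clearance_grc, retry = config$placement_retry, grid = grid
  )

  out <- list(
    c_goc = goc$coords, c_glo = glo$coords, c_grc = grc$coords,
    placed = c(goc = nrow(goc$coords), glo = nrow(glo$coords),
               grc = nrow(grc$coords)),
    skipped = c(goc = goc$skipped, glo = glo$skipped, grc = grc$skipped),
    target = c(goc = counts$n_goc, glo = counts$n_glo, grc = counts$n_grc),
    config = config
  )
  class(out) <- "gl_placement"
  out
}

#' @export
print.gl_placement <- function(x, ...) {
  cat("Granular-layer placement\n")
  for (cl in c("goc", "glo", "grc")) {
    cat(sprintf("  %s: %d / %d placed (%d skipped)\n", toupper(cl),
                x$placed[[cl]], x$target[[cl]], x$skipped[[cl]]))
  }
  invisible(x)
}

grid_spec <- function(d, config) {
  nx <- floor(config$length_um / d)
  ny <- floor(config$depth_um / d)
  n_layers <- floor(config$height_um / d)
  if (nx < 1 || ny < 1 || n_layers < 1)
    stop("invalid config: volume too small to host one box", call. = FALSE)
  list(nx = nx, ny = ny, n_layers = n_layers,
       layer_h = config$height_um / n_layers,
       d = d, n_boxes = nx * ny * n_layers)
}

## Evenly split n across layers, remainder going to the lower layers.
layer_quota <- function(n, n_layers) {
  q <- rep(n %/% n_layers, n_layers)
  r <- n %% n_layers
  if (r > 0) q[seq_len(r)] <- q[seq_len(r)] + 1L
  q
}

## Batched random placement of one class into a box grid. Elements with a
## layer assignment repeatedly draw a random box in their layer; a draw is
## rejected when the box is taken, when another pending element drew the
## same box this round (the earlier element wins), or when the candidate
## sphere would intersect a Golgi soma. `occupied` is an environment so the
## glomerulus and granule phases share one occupancy vector.
place_boxed <- function(n, d, config, occupied, goc_coords, clearance,
                        retry, grid = grid_spec(d, config)) {
  if (n == 0L)
    return(list(coords = matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("x", "y", "z"))),
                skipped = 0L))
  own_grid <- is.null(occupied)
  if (own_grid) {
    occupied <- new.env(parent = emptyenv())
    occupied$taken <- logical(grid$n_boxes)
  }
  quota <- layer_quota(n, grid$n_layers)
  layer <- rep.int(seq_len(grid$n_layers), quota)

  check_goc <- !is.null(goc_coords) && nrow(goc_coords) > 0 && clearance > 0
  if (check_goc) goc_cells <- goc_cell_table(goc_coords, clearance)

  pending <- seq_len(n)
  attempts <- integer(n)
  xs <- ys <- zs <- rep(NA_real_, n)
  r <- d / 2
  z_margin <- grid$layer_h - d

  while (length(pending) > 0L) {
    m <- length(pending)
    ix <- sample.int(grid$nx, m, replace = TRUE)
    iy <- sample.int(grid$ny, m, replace = TRUE)
    lz <- layer[pending]
    box <- (lz - 1L) * (grid$nx * grid$ny) + (iy - 1L) * grid$nx + ix
    u <- stats::runif(m)

    ok <- !occupied$taken[box]
    ok <- ok & !duplicated(box)

    x <- (ix - 0.5) * grid$d
    y <- (iy - 0.5) * grid$d
    z <- (lz - 1L) * grid$layer_h + r + u * max(z_margin, 0)

    if (check_goc && any(ok)) {
      idx <- which(ok)
      clash <- goc_clash(x[idx], y[idx], z[idx], goc_cells, clearance)
      ok[idx[clash]] <- FALSE
    }

    acc <- pending[ok]
    xs[acc] <- x[ok]; ys[acc] <- y[ok]; zs[acc] <- z[ok]
    occupied$taken[box[ok]] <- TRUE

    attempts[pending] <- attempts[pending] + 1L
    pending <- pending[!ok]
    pending <- pending[attempts[pending] < retry]
  }

  placed <- !is.na(xs)
  list(coords = cbind(x = xs[placed], y = ys[placed], z = zs[placed]),
       skipped = n - sum(placed))
}

## Register each Golgi soma in every coarse cell its clearance ball touches.
goc_cell_table <- function(goc_coords, clearance) {
  cs <- clearance              # cell size = clearance radius
  lo <- floor((goc_coords - clearance) / cs)
  hi <- floor((goc_coords + clearance) / cs)
  n <- nrow(goc_coords)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gx <- lo[i, 1]:hi[i, 1]; gy <- lo[i, 2]:hi[i, 2]; gz <- lo[i, 3]:hi[i, 3]
    g <- expand.grid(cx = gx, cy = gy, cz = gz)
    rows[[i]] <- data.table::data.table(cx = g$cx, cy = g$cy, cz = g$cz,
                                        goc = i)
  }
  reg <- data.table::rbindlist(rows)
  reg[, `:=`(gx = goc_coords[goc, 1], gy = goc_coords[goc, 2],
             gz = goc_coords[goc, 3])]
  data.table::setkey(reg, cx, cy, cz)
  attr(reg, "cell_size") <- cs
  reg
}

## TRUE for candidate points whose sphere would intersect a Golgi soma.
goc_clash <- function(x, y, z, goc_cells, clearance) {
  cs <- attr(goc_cells, "cell_size")
  cand <- data.table::data.table(
    cx = floor(x / cs), cy = floor(y / cs), cz = floor(z / cs),
    px = x, py = y, pz = z, id = seq_along(x)
  )
  hit <- goc_cells[cand, on = c("cx", "cy", "cz"), allow.cartesian = TRUE,
                   nomatch = NULL]
  if (nrow(hit) == 0L) return(logical(length(x)))
  d2 <- (hit$px - hit$gx)^2 + (hit$py - hit$gy)^2 + (hit$pz - hit$gz)^2
  bad <- unique(hit$id[d2 < clearance^2])
  out <- logical(length(x))
  out[bad] <- TRUE
  out
}
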