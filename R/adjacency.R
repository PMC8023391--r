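## Ragged adjacency container (CSR-like): `targets` holds the concatenated
## per-source id lists, `ptr` (length n_src + 1) the row offsets, `tag` an
## optional per-link integer label. Connection matrices at full scale hold
## millions of links, so flat integer vectors are used instead of R lists.

new_adj <- function(rows, n_src, n_tgt, tags = NULL, name = "adj") {
  lens <- lengths(rows)
  adj <- list(
    targets = as.integer(unlist(rows, use.names = FALSE)),
    ptr = c(0L, cumsum(lens)),
    tag = if (!is.null(tags)) as.integer(unlist(tags, use.names = FALSE)),
    n_src = as.integer(n_src), n_tgt = as.integer(n_tgt), name = name
  )
  class(adj) <- "gl_adj"
  adj
}

adj_from_flat <- function(src, tgt, n_src, n_tgt, tag = NULL, name = "adj") {
  o <- order(src, method = "radix")
  src <- src[o]; tgt <- tgt[o]
  if (!is.null(tag)) tag <- tag[o]
  counts <- tabulate(src, nbins = n_src)
  adj <- list(targets = as.integer(tgt), ptr = c(0L, cumsum(counts)),
              tag = if (!is.null(tag)) as.integer(tag),
              n_src = as.integer(n_src), n_tgt = as.integer(n_tgt),
              name = name)
  class(adj) <- "gl_adj"
  adj
}

#' Extract one row of a connection matrix
#'
#' Connection matrices are stored as ragged integer arrays; `adj_row`
#' returns the target ids linked to source `i`, `adj_lengths` the per-source
#' link counts, and `adj_pairs` the full (source, target, tag) link table.
#'
#' @param adj a connection matrix as built by the `connect_*` functions.
#' @param i source id (1-based).
#' @return `adj_row`: integer vector of target ids; `adj_lengths`: integer
#'   vector of length `n_src`; `adj_pairs`: a data.frame.
#' @export
adj_row <- function(adj, i) {
  stopifnot(inherits(adj, "gl_adj"), i >= 1L, i <= adj$n_src)
  if (adj$ptr[i] == adj$ptr[i + 1L]) return(integer(0))
  adj$targets[(adj$ptr[i] + 1L):adj$ptr[i + 1L]]
}

#' @rdname adj_row
#' @export
adj_lengths <- function(adj) {
  stopifnot(inherits(adj, "gl_adj"))
  diff(adj$ptr)
}

#' @rdname adj_row
#' @export
adj_pairs <- function(adj) {
  stopifnot(inherits(adj, "gl_adj"))
  lens <- diff(adj$ptr)
  out <- data.frame(source_id = rep.int(seq_len(adj$n_src), lens),
                    target_id = adj$targets)
  out$tag <- if (!is.null(adj$tag)) adj$tag
             else rep(NA_integer_, nrow(out))
  out
}

## Invert an adjacency (target -> sources); keeps tags if present.
adj_invert <- function(adj, name = paste0(adj$name, "_inv")) {
  lens <- diff(adj$ptr)
  src <- rep.int(seq_len(adj$n_src), lens)
  adj_from_flat(adj$targets, src, n_src = adj$n_tgt, n_tgt = adj$n_src,
                tag = adj$tag, name = name)
}

#' @export
print.gl_adj <- function(x, ...) {
  cat(sprintf("connection matrix '%s': %d sources -> %d targets, %d links\n",
              x$name, x$n_src, x$n_tgt, length(x$targets)))
  invisible(x)
}
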