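#' Directed Erdos-Renyi graphs for the LIF network
#'
#' `build_internal_graph()` draws the recurrent adjacency: every ordered pair
#' `(target n, source m)` with `n != m` is connected independently with
#' probability `p_internal`, without regard to unit type (the synapse type is
#' determined later by the presynaptic unit's label). `build_external_graph()`
#' draws the feed-forward adjacency from `m_external` Poisson sources onto the
#' network: external sources connect with probability `p_external` to
#' excitatory units only; inhibitory units receive no external input.
#'
#' Edges are sampled per source as a binomial edge count followed by a uniform
#' draw of distinct targets (the Gilbert model, in its degree-wise form), which
#' keeps memory at O(edges) rather than O(N^2).
#'
#' @param n_units number of network units (targets; for the internal graph
#'   also sources).
#' @param p_internal,p_external connection probabilities in `[0, 1]`.
#' @param unit_type per-unit labels from [unit_types()].
#' @param m_external number of external source units.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return an object of class `lif_adjacency`: a compressed sparse
#'   representation with `targets` (concatenated 1-based target indices),
#'   `ptr` (length `n_sources + 1`; source `m` owns
#'   `targets[ptr[m]:(ptr[m+1]-1)]`), `n_sources`, `n_targets` and `kind`.
#' @examples
#' g <- build_internal_graph(50, 0.1, seed = 1)
#' n_edges(g)
#' @export
build_internal_graph <- function(n_units, p_internal, seed = 1L) {
  if (!is.finite(p_internal) || p_internal < 0 || p_internal > 1) {
    stop("p_internal must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_units >= 1)
  n_units <- as.integer(n_units)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  tgt_list <- vector("list", n_units)
  if (p_internal > 0 && n_units > 1L) {
    ks <- stats::rbinom(n_units, n_units - 1L, p_internal)
    for (m in seq_len(n_units)) {
      k <- ks[m]
      if (k == 0L) next
      t0 <- sample.int(n_units - 1L, k)   # uniform distinct, excluding self
      tgt_list[[m]] <- ifelse(t0 >= m, t0 + 1L, t0)
    }
  }
  new_adjacency(tgt_list, n_sources = n_units, n_targets = n_units,
                kind = "internal")
}

#' @rdname build_internal_graph
#' @export
build_external_graph <- function(n_units, unit_type, m_external, p_external,
                                 seed = 1L) {
  if (!is.finite(p_external) || p_external < 0 || p_external > 1) {
    stop("p_external must lie in [0, 1]", call. = FALSE)
  }
  if (length(unit_type) != n_units) {
    stop("unit_type must have length n_units", call. = FALSE)
  }
  m_external <- as.integer(m_external)
  exc_idx <- which(unit_type == "excitatory")
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  tgt_list <- vector("list", max(m_external, 0L))
  if (p_external > 0 && length(exc_idx) > 0L && m_external > 0L) {
    ks <- stats::rbinom(m_external, length(exc_idx), p_external)
    for (m in seq_len(m_external)) {
      k <- ks[m]
      if (k == 0L) next
      tgt_list[[m]] <- exc_idx[sample.int(length(exc_idx), k)]
    }
  }
  new_adjacency(tgt_list, n_sources = m_external, n_targets = as.integer(n_units),
                kind = "external")
}

new_adjacency <- function(tgt_list, n_sources, n_targets, kind) {
  lens <- vapply(tgt_list, length, integer(1))
  adj <- list(
    targets = as.integer(unlist(tgt_list, use.names = FALSE)),
    ptr = c(1L, 1L + cumsum(lens)),
    n_sources = as.integer(n_sources),
    n_targets = as.integer(n_targets),
    kind = kind
  )
  class(adj) <- "lif_adjacency"
  adj
}

#' @export
print.lif_adjacency <- function(x, ...) {
  cat("<lif_adjacency:", x$kind, ">", x$n_sources, "sources ->",
      x$n_targets, "targets,", n_edges(x), "edges\n")
  invisible(x)
}

#' Edge count, in-degrees and dense form of an adjacency
#'
#' @param adj a `lif_adjacency`.
#' @return `n_edges()` the total number of directed edges; `in_degree()` an
#'   integer vector of length `n_targets`; `adjacency_matrix()` the dense 0/1
#'   matrix `A` with `A[n, m] = 1` iff source `m` targets `n` (only sensible
#'   for small graphs).
#' @export
n_edges <- function(adj) length(adj$targets)

#' @rdname n_edges
#' @export
in_degree <- function(adj) tabulate(adj$targets, nbins = adj$n_targets)

#' @rdname n_edges
#' @export
adjacency_matrix <- function(adj) {
  A <- matrix(0L, adj$n_targets, adj$n_sources)
  for (m in seq_len(adj$n_sources)) {
    A[source_targets(adj, m), m] <- 1L
  }
  A
}

source_targets <- function(adj, m) {
  adj$targets[seq2(adj$ptr[m], adj$ptr[m + 1L] - 1L)]
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

# RNG bracketing: run a block under a given seed, then restore the caller's
# RNG state so package functions do not clobber the global stream.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
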