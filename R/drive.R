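#' External Poisson drive as binned per-unit counts
#'
#' Realizes the merged external input of each network unit directly as a
#' Poisson process at the unit's aggregate rate (external in-degree times the
#' per-source rate): the superposition of independent Poisson sources is
#' itself Poisson, so the union of the connected sources never needs to be
#' enumerated. Returns the counts binned at `dt`.
#'
#' This materializes an `n_targets x n_bins` matrix and is intended for
#' small problems (oracles, toy analyses); [simulate_network()] draws the
#' identical process step-by-step internally without storing it.
#'
#' @param m_external number of external source units (consistency check
#'   against `external_graph`).
#' @param rate_ext per-source rate (Hz).
#' @param external_graph a `lif_adjacency` from [build_external_graph()].
#' @param t_total duration (ms).
#' @param dt bin width (ms).
#' @param seed integer seed.
#' @return list with `counts` (integer matrix, units x bins), `rate_ms`
#'   (per-unit aggregate rate in events/ms) and `dt`.
#' @export
generate_external_drive <- function(m_external, rate_ext, external_graph,
                                    t_total, dt, seed = 1L) {
  stopifnot(rate_ext >= 0, inherits(external_graph, "lif_adjacency"))
  if (external_graph$n_sources != m_external) {
    stop("external_graph has ", external_graph$n_sources,
         " sources but m_external = ", m_external, call. = FALSE)
  }
  n_bins <- as.integer(round(t_total / dt))
  rate_ms <- in_degree(external_graph) * rate_ext / 1000
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  counts <- matrix(stats::rpois(length(rate_ms) * n_bins,
                                rep(rate_ms * dt, times = n_bins)),
                   nrow = length(rate_ms), ncol = n_bins)
  list(counts = counts, rate_ms = rate_ms, dt = dt)
}

#' Population-mean spike input from a raster
#'
#' Recomputes the drive series the simulator records: for each synapse type
#' and time bin, the mean over target units of the spikes received through
#' edges of that type, divided by `dt` (a delta spike contributes `1/dt` in
#' its bin, so the series approximates a rate density in 1/ms). The synapse
#' type of an edge is the presynaptic unit's label. With
#' `subset = "excitatory"` the average runs over excitatory target units
#' only (the encephalography-motivated variant); deliveries are then counted
#' through edges into that subset and divided by its size.
#'
#' @param raster a `lif_raster`.
#' @param internal_graph the `lif_adjacency` the raster was generated on.
#' @param unit_type per-unit labels; defaults to `raster$unit_type`.
#' @param dt bin width (ms).
#' @param subset `"all"` or `"excitatory"`: which target units to average
#'   over.
#' @return a `lif_drive` (its `phi_ext` is zero: external input is not part
#'   of the raster).
#' @export
population_drive <- function(raster, internal_graph,
                             unit_type = raster$unit_type, dt,
                             subset = c("all", "excitatory")) {
  subset <- match.arg(subset)
  n <- raster$n_units
  if (length(unit_type) != n || internal_graph$n_sources != n ||
      internal_graph$n_targets != n) {
    stop("raster, unit_type and internal_graph disagree in unit count",
         call. = FALSE)
  }
  in_set <- if (subset == "all") rep(TRUE, n) else unit_type == "excitatory"
  n_set <- sum(in_set)
  if (n_set == 0L) stop("target subset is empty", call. = FALSE)

  # per source: number of its targets inside the averaging subset
  fanout <- integer(n)
  for (m in seq_len(n)) fanout[m] <- sum(in_set[source_targets(internal_graph, m)])

  n_bins <- as.integer(round(raster$t_total / dt))
  # spike at time t lands in bin floor(t/dt)+1 (bin b covers [(b-1)dt, b dt));
  # a spike exactly at t_total goes to the last bin
  bin <- pmin(floor(raster$time / dt) + 1L, n_bins)
  src_exc <- unit_type[raster$unit] == "excitatory"
  w <- fanout[raster$unit]
  acc <- function(sel) {
    if (!any(sel)) return(numeric(n_bins))
    as.numeric(tapply_sum(bin[sel], w[sel], n_bins))
  }
  phi_exc <- acc(src_exc) / (n_set * dt)
  phi_inh <- acc(!src_exc) / (n_set * dt)
  drive_series(phi_exc, phi_inh, numeric(n_bins), dt)
}

tapply_sum <- function(idx, w, n_bins) {
  out <- numeric(n_bins)
  s <- rowsum(as.numeric(w), group = idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
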