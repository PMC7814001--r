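#' Simulate the stochastic LIF network
#'
#' Integrates the conductance-based leaky integrate-and-fire network with an
#' Euler-Maruyama scheme: leak toward the membrane reversal potential,
#' per-type exponential synaptic conductances driven by internal spikes
#' routed through a directed Erdos-Renyi graph, an aggregate external Poisson
#' drive onto excitatory units, additive white membrane noise, and
#' threshold/reset/refractory spike generation. Records the spike raster, the
#' three population-mean drive series (the coupling handed to the mass
#' models) and the population-mean membrane potential.
#'
#' Spikes emitted at step `t` reach their targets' conductances at step
#' `t + 1`; a spike contributes a conductance jump `g_hat / tau` (the exact
#' integral of the first-order synapse against a delta input, preserving
#' total charge independent of `dt`). During the refractory period the
#' membrane is clamped at `v_reset` while conductances keep evolving and
#' external input keeps accumulating. Initial potentials are drawn uniformly
#' on `[v_reset, v_thres)`; conductances start at zero. All randomness
#' (graphs, initial state, external drive, noise) derives from `config$seed`.
#'
#' @param config a [network_config()] object.
#' @param internal_graph,external_graph optional pre-built adjacencies from
#'   [build_internal_graph()] / [build_external_graph()]; built from the
#'   config (with seeds derived from `config$seed`) when omitted.
#' @param g_ext_clamp if non-`NULL`, holds every unit's external conductance
#'   at this constant (nS) instead of drawing Poisson input; used by the
#'   closed-form single-neuron oracles.
#' @return a list of class `lif_simulation` with elements `raster`
#'   (`lif_raster`), `drive` (`lif_drive`), `trace` (`lif_trace`, all-unit
#'   mean), `trace_exc` (excitatory-unit mean), `unit_type`, `v_init_mean`,
#'   `config`, and the realized `internal_graph` / `external_graph`.
#' @examples
#' cfg <- network_config(n_units = 100, m_external = 100,
#'                       t_total = 500, t_transient = 100, seed = 7)
#' sim <- simulate_network(cfg)
#' sim$trace$v_bar
#' @export
simulate_network <- function(config, internal_graph = NULL,
                             external_graph = NULL, g_ext_clamp = NULL) {
  validate_config(config)
  n <- config$n_units
  types <- unit_types(n, config$lambda_exc)
  if (is.null(internal_graph)) {
    internal_graph <- build_internal_graph(n, config$p_internal,
                                           seed = derive_seed(config$seed, 1L))
  }
  if (internal_graph$n_sources != n || internal_graph$n_targets != n) {
    stop("internal_graph size does not match config$n_units", call. = FALSE)
  }
  if (is.null(external_graph)) {
    external_graph <- build_external_graph(n, types, config$m_external,
                                           config$p_external,
                                           seed = derive_seed(config$seed, 2L))
  }
  # merged external Poisson sources: aggregate per-unit rate (events/ms)
  ext_rate_ms <- in_degree(external_graph) * config$rate_ext / 1000

  n_steps <- as.integer(round(config$t_total / config$dt))
  n_ref <- as.integer(round(config$tau_ref / config$dt))

  old <- set_local_seed(derive_seed(config$seed, 3L))
  on.exit(restore_seed(old), add = TRUE)
  v_init <- stats::runif(n, config$v_reset, config$v_thres)

  res <- lif_integrate_cpp(
    n, as.integer(types == "excitatory"),
    internal_graph$targets, internal_graph$ptr, ext_rate_ms, v_init,
    config$dt, n_steps,
    config$v_thres, config$v_reset, config$v_leak,
    config$v_rev_exc, config$v_rev_inh, config$v_rev_ext,
    config$tau_mem, config$tau_syn_exc, config$tau_syn_inh,
    config$tau_syn_ext, n_ref,
    config$g_leak, config$g_hat_exc, config$g_hat_inh, config$g_hat_ext,
    config$noise_var,
    if (is.null(g_ext_clamp)) -1 else g_ext_clamp
  )

  drive <- drive_series(res$phi_exc, res$phi_inh, res$phi_ext, config$dt)
  attr(drive, "t_transient") <- config$t_transient
  out <- list(
    raster = spike_raster(res$spike_unit, res$spike_time, types,
                          config$t_total),
    drive = drive,
    trace = potential_trace(res$v_mean, config$dt, "LIF",
                            config$t_transient),
    trace_exc = potential_trace(res$v_mean_exc, config$dt, "LIF",
                                config$t_transient),
    unit_type = types,
    v_init_mean = mean(v_init),
    internal_graph = internal_graph,
    external_graph = external_graph,
    config = config
  )
  class(out) <- "lif_simulation"
  out
}

#' @export
print.lif_simulation <- function(x, ...) {
  rate <- length(x$raster$time) / x$config$n_units /
    (x$config$t_total / 1000)
  cat("<lif_simulation> N =", x$config$n_units, " p =", x$config$p_internal,
      " lambda =", x$config$lambda_exc, "\n")
  cat("  ", length(x$raster$time), " spikes (", round(rate, 2),
      " Hz/unit), v_bar = ", round(x$trace$v_bar, 2), " mV\n", sep = "")
  invisible(x)
}

#' Per-run summary statistics
#'
#' Firing rate per unit type (Hz), realized mean in-degree and the
#' post-transient mean potential; the quantities logged per run.
#'
#' @param sim a `lif_simulation`.
#' @return a named list.
#' @export
simulation_summary <- function(sim) {
  dur_s <- sim$config$t_total / 1000
  counts <- tabulate(sim$raster$unit, nbins = sim$config$n_units)
  exc <- sim$unit_type == "excitatory"
  list(
    rate_exc_hz = if (any(exc)) mean(counts[exc]) / dur_s else NA_real_,
    rate_inh_hz = if (any(!exc)) mean(counts[!exc]) / dur_s else NA_real_,
    mean_in_degree = mean(in_degree(sim$internal_graph)),
    v_bar = sim$trace$v_bar
  )
}

# Counter-based derivation of per-purpose/per-repetition seeds from a master
# seed; result stays inside the positive 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + 97 * as.numeric(k)) %%
               2147483647)
}
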