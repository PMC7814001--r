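#' Network configuration for the LIF simulator
#'
#' Collects every biophysical, topological, drive and integration parameter of
#' the conductance-based leaky integrate-and-fire (LIF) network. Defaults are
#' the published reference values: a network of `N = 10000` units driven by
#' `M = 10000` independent external Poisson trains at 5 Hz, integrated with an
#' Euler-Maruyama scheme at `dt = 0.1` ms for `3e4` ms of which the first
#' `3e3` ms are treated as transient.
#'
#' Membrane dynamics: leak toward `v_leak` with time constant `tau_mem`,
#' conductance-scaled synaptic currents toward the per-type reversal
#' potentials, additive white noise of intensity `noise_var`, threshold at
#' `v_thres`, reset to `v_reset` and a refractory clamp of `tau_ref` ms.
#' Synapses are exponential (first-order conductance dynamics) with per-type
#' time constants and peak conductances.
#'
#' @param n_units number of LIF units (N).
#' @param m_external number of external Poisson source units (M).
#' @param p_internal connection probability of the directed Erdos-Renyi
#'   internal graph (p); mean degree is `n_units * p_internal`.
#' @param p_external probability that an external source connects to a given
#'   excitatory unit. Not fixed by the reference study; default 0.1.
#' @param lambda_exc fraction of excitatory units,
#'   `#excitatory / (#excitatory + #inhibitory)`.
#' @param v_thres,v_reset,v_leak threshold, reset and membrane reversal
#'   potentials (mV).
#' @param v_rev_exc,v_rev_inh,v_rev_ext synaptic reversal potentials (mV) for
#'   excitatory, inhibitory and external synapses.
#' @param tau_mem membrane time constant (ms).
#' @param tau_syn_exc,tau_syn_inh,tau_syn_ext synaptic time constants (ms).
#' @param tau_ref refractory period (ms).
#' @param g_leak leak conductance (nS).
#' @param g_hat_exc,g_hat_inh,g_hat_ext peak synaptic conductances (nS).
#' @param noise_var white-noise intensity Q (mV^2 * ms; the per-step standard
#'   deviation of the membrane noise is `sqrt(noise_var * dt) / tau_mem`).
#' @param rate_ext firing rate of each external Poisson source (Hz).
#' @param dt integration step (ms).
#' @param t_total total simulated time (ms).
#' @param t_transient initial transient (ms) excluded from time averages and
#'   all downstream statistics (samples are retained in the arrays).
#' @param seed integer seed for all randomness of a run (graphs, drive, noise,
#'   initial conditions).
#' @return an object of class `lif_config` (a validated named list).
#' @examples
#' cfg <- network_config(n_units = 200, m_external = 200, t_total = 1000)
#' cfg$tau_mem
#' @export
network_config <- function(n_units = 10000L,
                           m_external = 10000L,
                           p_internal = 0.2,
                           p_external = 0.1,
                           lambda_exc = 0.75,
                           v_thres = -50,
                           v_reset = -60,
                           v_leak = -80,
                           v_rev_exc = 0,
                           v_rev_inh = -70,
                           v_rev_ext = 0,
                           tau_mem = 20,
                           tau_syn_exc = 3,
                           tau_syn_inh = 7,
                           tau_syn_ext = 3,
                           tau_ref = 5,
                           g_leak = 10,
                           g_hat_exc = 4,
                           g_hat_inh = 40,
                           g_hat_ext = 5,
                           noise_var = 5e-4,
                           rate_ext = 5,
                           dt = 0.1,
                           t_total = 3e4,
                           t_transient = 3e3,
                           seed = 1L) {
  cfg <- list(
    n_units = as.integer(n_units), m_external = as.integer(m_external),
    p_internal = p_internal, p_external = p_external, lambda_exc = lambda_exc,
    v_thres = v_thres, v_reset = v_reset, v_leak = v_leak,
    v_rev_exc = v_rev_exc, v_rev_inh = v_rev_inh, v_rev_ext = v_rev_ext,
    tau_mem = tau_mem, tau_syn_exc = tau_syn_exc, tau_syn_inh = tau_syn_inh,
    tau_syn_ext = tau_syn_ext, tau_ref = tau_ref,
    g_leak = g_leak, g_hat_exc = g_hat_exc, g_hat_inh = g_hat_inh,
    g_hat_ext = g_hat_ext,
    noise_var = noise_var, rate_ext = rate_ext,
    dt = dt, t_total = t_total, t_transient = t_transient,
    seed = as.integer(seed)
  )
  class(cfg) <- "lif_config"
  validate_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Checks probability ranges, ordering of reset/threshold, positivity of
#' time constants and step sizes, and the transient/total-time relation.
#' Called by every entry point; exported so externally assembled or edited
#' configurations can be checked too.
#'
#' @param cfg a `lif_config`.
#' @return the config, invisibly; errors on the first violated invariant.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "lif_config"))
  probs <- c(p_internal = cfg$p_internal, p_external = cfg$p_external,
             lambda_exc = cfg$lambda_exc)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_units < 1L) stop("n_units must be >= 1", call. = FALSE)
  if (cfg$m_external < 0L) stop("m_external must be >= 0", call. = FALSE)
  if (!(cfg$v_reset < cfg$v_thres)) {
    stop("v_reset must be below v_thres", call. = FALSE)
  }
  taus <- c(cfg$tau_mem, cfg$tau_syn_exc, cfg$tau_syn_inh, cfg$tau_syn_ext)
  if (any(taus <= 0)) stop("all time constants must be > 0", call. = FALSE)
  if (cfg$tau_ref < 0) stop("tau_ref must be >= 0", call. = FALSE)
  if (cfg$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (cfg$rate_ext < 0) stop("rate_ext must be >= 0", call. = FALSE)
  if (cfg$noise_var < 0) stop("noise_var must be >= 0", call. = FALSE)
  if (!(cfg$t_transient < cfg$t_total)) {
    stop("t_transient must be smaller than t_total", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.lif_config <- function(x, ...) {
  cat("<lif_config> N =", x$n_units, " M =", x$m_external,
      " p =", x$p_internal, " lambda =", x$lambda_exc, "\n")
  cat("  dt =", x$dt, "ms, T =", x$t_total, "ms (transient", x$t_transient,
      "ms), seed =", x$seed, "\n")
  invisible(x)
}

#' Excitatory/inhibitory labelling for a given excitatory fraction
#'
#' The first `round(lambda_exc * n_units)` units are excitatory, the rest
#' inhibitory. Unit identity is exchangeable (the graph is type-blind), so a
#' deterministic labelling is statistically equivalent to a random one.
#'
#' @param n_units number of units.
#' @param lambda_exc excitatory fraction in `[0, 1]`.
#' @return character vector of length `n_units` with values
#'   `"excitatory"` / `"inhibitory"`.
#' @export
unit_types <- function(n_units, lambda_exc) {
  stopifnot(n_units >= 1, lambda_exc >= 0, lambda_exc <= 1)
  n_exc <- round(lambda_exc * n_units)
  rep(c("excitatory", "inhibitory"), times = c(n_exc, n_units - n_exc))
}

#' Read or write a configuration as a JSON file
#'
#' Field names mirror [network_config()] arguments one-to-one.
#'
#' @param cfg a `lif_config`.
#' @param path file path.
#' @return `read_config()` returns a `lif_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(network_config, vals)
}
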