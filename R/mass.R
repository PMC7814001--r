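#' Configuration of the second-order mass dynamics
#'
#' Parameters of the Freeman-type population dynamics
#' `[tau_mem d/dt + 1][tau_syn d/dt + 1] V = J(t)` with
#' `J = v_leak - sum_sigma (g_hat_sigma/g)(F - v_rev_sigma) Phi_sigma`.
#' The conventional model (CFM) forces the synaptic terms with the constant
#' time-averaged potential `F = v_bar`; the modified model (MFM) uses the
#' instantaneous state `F = V(t)` (parametric forcing). `tau_syn` defaults to
#' 5 ms, the average of the network's excitatory (3 ms) and inhibitory (7 ms)
#' synaptic time constants.
#'
#' @param variant `"CFM"` or `"MFM"`.
#' @param tau_mem,tau_syn time constants (ms).
#' @param v_leak,v_rev_exc,v_rev_inh,v_rev_ext potentials (mV).
#' @param g_ratio_exc,g_ratio_inh,g_ratio_ext dimensionless conductance
#'   ratios `g_hat_sigma / g_leak`.
#' @param v_bar constant forcing potential (mV); required for the CFM,
#'   conventionally the companion LIF run's post-transient mean
#'   (`trace$v_bar`), never fitted.
#' @param dt integration step (ms).
#' @param v0,dv0 initial potential (mV) and slope (mV/ms).
#' @return a `mass_config` object.
#' @export
mass_config <- function(variant = c("CFM", "MFM"),
                        tau_mem = 20, tau_syn = 5,
                        v_leak = -80, v_rev_exc = 0, v_rev_inh = -70,
                        v_rev_ext = 0,
                        g_ratio_exc = 0.4, g_ratio_inh = 4, g_ratio_ext = 0.5,
                        v_bar = NULL, dt = 0.1, v0 = NULL, dv0 = 0) {
  variant <- match.arg(variant)
  stopifnot(tau_mem > 0, tau_syn > 0, dt > 0)
  if (variant == "CFM" && (is.null(v_bar) || !is.finite(v_bar))) {
    stop("CFM requires a finite v_bar", call. = FALSE)
  }
  cfg <- list(variant = variant, tau_mem = tau_mem, tau_syn = tau_syn,
              v_leak = v_leak, v_rev_exc = v_rev_exc, v_rev_inh = v_rev_inh,
              v_rev_ext = v_rev_ext,
              g_ratio_exc = g_ratio_exc, g_ratio_inh = g_ratio_inh,
              g_ratio_ext = g_ratio_ext,
              v_bar = if (is.null(v_bar)) NA_real_ else v_bar,
              dt = dt,
              v0 = if (is.null(v0)) {
                if (is.null(v_bar)) v_leak else v_bar
              } else v0,
              dv0 = dv0)
  class(cfg) <- "mass_config"
  cfg
}

#' Derive a mass configuration from a network configuration
#'
#' Copies potentials and conductance ratios from a [network_config()];
#' `tau_syn` is the mean of the network's two synaptic time constants.
#'
#' @param net_config a `lif_config`.
#' @param variant `"CFM"` or `"MFM"`.
#' @param v_bar constant forcing potential (CFM) and default initial state.
#' @param v0 initial potential; for the MFM conventionally the LIF run's
#'   initial population mean.
#' @return a `mass_config`.
#' @export
mass_config_from_network <- function(net_config, variant, v_bar = NULL,
                                     v0 = NULL) {
  mass_config(variant = variant,
              tau_mem = net_config$tau_mem,
              tau_syn = (net_config$tau_syn_exc + net_config$tau_syn_inh) / 2,
              v_leak = net_config$v_leak,
              v_rev_exc = net_config$v_rev_exc,
              v_rev_inh = net_config$v_rev_inh,
              v_rev_ext = net_config$v_rev_ext,
              g_ratio_exc = net_config$g_hat_exc / net_config$g_leak,
              g_ratio_inh = net_config$g_hat_inh / net_config$g_leak,
              g_ratio_ext = net_config$g_hat_ext / net_config$g_leak,
              v_bar = v_bar, dt = net_config$dt, v0 = v0)
}

#' Integrate the conventional / modified Freeman model on a recorded drive
#'
#' Forward-Euler integration of the factorised second-order dynamics in
#' cascade form (`U = tau_syn dV/dt + V`), with the drive held piecewise
#' constant per bin. `integrate_cfm()` forces the synaptic terms with the
#' constant `config$v_bar`; `integrate_mfm()` with the instantaneous state,
#' unless `freeze_at` is given, in which case the right-hand-side potential
#' is pinned to that constant and the result reproduces the CFM exactly.
#'
#' Two integration schemes are available. `"euler"` is the reference forward
#' scheme with the drive held constant per bin. For the MFM it is only
#' conditionally stable: the parametric forcing makes the instantaneous
#' restoring coefficient `a(t) = sum_sigma r_sigma Phi_sigma` spike during
#' population bursts, and at `dt = 0.1` ms the scheme can (and in
#' synchronized regimes does) diverge. `"exact"` propagates the cascade over
#' each bin with the closed-form matrix exponential of the frozen affine
#' system -- unconditionally stable for nonnegative drive and identical to
#' Euler up to O(dt) whenever Euler is stable. The sweep pipeline uses
#' `"exact"` for both models.
#'
#' @param drive a `lif_drive` whose bin width matches `config$dt`.
#' @param config a [mass_config()] of the matching variant.
#' @param freeze_at (`integrate_mfm` only) optional constant at which to
#'   freeze the right-hand-side potential.
#' @param method `"euler"` (reference first-order scheme) or `"exact"`
#'   (per-bin matrix-exponential propagation).
#' @return a `lif_trace` labelled `"CFM"` / `"MFM"`, sampled on the same
#'   grid as the drive.
#' @export
integrate_cfm <- function(drive, config, method = c("euler", "exact")) {
  method <- match.arg(method)
  check_mass_inputs(drive, config, "CFM")
  v <- mass_integrate_cpp(drive$phi_exc, drive$phi_inh, drive$phi_ext,
                          config$dt, config$tau_mem, config$tau_syn,
                          config$v_leak, config$v_rev_exc, config$v_rev_inh,
                          config$v_rev_ext,
                          config$g_ratio_exc, config$g_ratio_inh,
                          config$g_ratio_ext,
                          config$v_bar, FALSE, config$v0, config$dv0,
                          if (method == "euler") 0L else 1L)
  potential_trace(v, config$dt, "CFM", t_transient = attr(drive, "t_transient") %||% 0)
}

#' @rdname integrate_cfm
#' @export
integrate_mfm <- function(drive, config, freeze_at = NULL,
                          method = c("euler", "exact")) {
  method <- match.arg(method)
  check_mass_inputs(drive, config, "MFM")
  im <- if (method == "euler") 0L else 1L
  if (is.null(freeze_at)) {
    v <- mass_integrate_cpp(drive$phi_exc, drive$phi_inh, drive$phi_ext,
                            config$dt, config$tau_mem, config$tau_syn,
                            config$v_leak, config$v_rev_exc, config$v_rev_inh,
                            config$v_rev_ext,
                            config$g_ratio_exc, config$g_ratio_inh,
                            config$g_ratio_ext,
                            NA_real_, TRUE, config$v0, config$dv0, im)
  } else {
    v <- mass_integrate_cpp(drive$phi_exc, drive$phi_inh, drive$phi_ext,
                            config$dt, config$tau_mem, config$tau_syn,
                            config$v_leak, config$v_rev_exc, config$v_rev_inh,
                            config$v_rev_ext,
                            config$g_ratio_exc, config$g_ratio_inh,
                            config$g_ratio_ext,
                            freeze_at, FALSE, config$v0, config$dv0, im)
  }
  potential_trace(v, config$dt, "MFM", t_transient = attr(drive, "t_transient") %||% 0)
}

check_mass_inputs <- function(drive, config, variant) {
  stopifnot(inherits(drive, "lif_drive"), inherits(config, "mass_config"))
  if (config$variant != variant) {
    stop("config$variant is ", config$variant, ", expected ", variant,
         call. = FALSE)
  }
  if (abs(drive$dt - config$dt) > 1e-12) {
    stop("drive bin width does not match config$dt", call. = FALSE)
  }
  vals <- c(drive$phi_exc, drive$phi_inh, drive$phi_ext)
  if (!all(is.finite(vals))) stop("non-finite drive", call. = FALSE)
  invisible(TRUE)
}

#' Analytic frequency response of the drive-free mass dynamics
#'
#' The transfer function of the second-order low-pass filter
#' `1 / ((1 + i 2 pi f tau_mem)(1 + i 2 pi f tau_syn))` with `f` in Hz and
#' the time constants in ms. Serves as the oracle for the empirical
#' sine-sweep gain of the integrators.
#'
#' @param freq frequencies (Hz), `>= 0`; vectorised.
#' @param config a `mass_config`.
#' @return complex gains.
#' @examples
#' cfg <- mass_config("CFM", v_bar = -60)
#' Mod(analytic_response(0, cfg))   # DC gain 1
#' @export
analytic_response <- function(freq, config) {
  stopifnot(all(freq >= 0))
  wm <- 2i * pi * freq * config$tau_mem / 1000
  ws <- 2i * pi * freq * config$tau_syn / 1000
  1 / ((1 + wm) * (1 + ws))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
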