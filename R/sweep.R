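#' Define a {p, lambda} sweep grid
#'
#' The grid carries the base network configuration, the repetition count and
#' deterministic per-(point, repetition) seeds derived from a master seed by
#' a counter scheme, so points are independent and the sweep is resumable.
#' The full-scale study ran a dense grid at `N = 10^4`; the default desk
#' grid is 9 x 13 points at `N = 2000`, `T = 10^4` ms.
#'
#' @param p_values connection probabilities.
#' @param lambda_values excitatory fractions.
#' @param base_config a [network_config()] whose `p_internal`, `lambda_exc`
#'   and `seed` are overridden per point. The default reduced-scale config
#'   keeps the per-unit external input of the full-scale study by preserving
#'   the external in-degree (~10^3, hence `p_external = 0.5` at `M = 2000`)
#'   rather than the connection probability.
#' @param n_repetitions simulations per point (default 10; graph and drive
#'   are redrawn each repetition).
#' @param master_seed master seed for the whole sweep.
#' @return a `sweep_grid` object.
#' @export
sweep_grid <- function(p_values = seq(0.05, 0.4, length.out = 9),
                       lambda_values = seq(0.4, 1.0, length.out = 13),
                       base_config = network_config(n_units = 2000L,
                                                    m_external = 2000L,
                                                    p_external = 0.5,
                                                    t_total = 1e4,
                                                    t_transient = 1e3),
                       n_repetitions = 10L,
                       master_seed = 1L) {
  stopifnot(length(p_values) >= 1, length(lambda_values) >= 1,
            all(p_values >= 0 & p_values <= 1),
            all(lambda_values >= 0 & lambda_values <= 1),
            n_repetitions >= 1)
  g <- list(p_values = p_values, lambda_values = lambda_values,
            base_config = base_config,
            n_repetitions = as.integer(n_repetitions),
            master_seed = as.integer(master_seed))
  class(g) <- "sweep_grid"
  g
}

point_seeds <- function(grid, i_point) {
  vapply(seq_len(grid$n_repetitions), function(r) {
    derive_seed(grid$master_seed, i_point * 1000L + r)
  }, integer(1))
}

#' Simulate and compare one {p, lambda} point
#'
#' Runs `length(seeds)` repetitions of the full chain: simulate the LIF
#' network (redrawing graph and drive each repetition), integrate CFM and
#' MFM on the recorded drive (the CFM forced with that repetition's
#' post-transient mean potential, the MFM started at the LIF initial mean),
#' then compute spike-contrast synchrony per repetition, realization-averaged
#' spectra with median frequencies, the chi-squared spectral statistic with
#' its significance flag, and the lag-optimised correlations (summarised by
#' the repetition mean of `rho(tau_max)` and the modal `tau_max`).
#'
#' @param p,lambda grid coordinates.
#' @param base_config base [network_config()].
#' @param seeds one integer seed per repetition.
#' @param subset `"all"` or `"excitatory"`: which units enter the mean
#'   potential and the drive averaging (the latter mimics recordings that
#'   only see excitatory populations).
#' @param max_lag,alpha,rho0 comparison parameters, see
#'   [lagged_correlation()] and [fisher_significance()].
#' @return list with `summary` (one-row data.frame, the ComparisonResult)
#'   and `details` (per-repetition objects).
#' @export
run_point <- function(p, lambda, base_config, seeds,
                      subset = c("all", "excitatory"),
                      max_lag = 500, alpha = 0.01, rho0 = 0.95) {
  subset <- match.arg(subset)
  stopifnot(length(seeds) >= 1, p >= 0, p <= 1, lambda >= 0, lambda <= 1)
  cfg0 <- base_config
  cfg0$p_internal <- p
  cfg0$lambda_exc <- lambda
  validate_config(cfg0)

  reps <- lapply(seeds, function(s) {
    cfg <- cfg0
    cfg$seed <- as.integer(s)
    sim <- simulate_network(cfg)
    drv <- point_drive(sim, subset)
    ref <- if (subset == "all") sim$trace else sim$trace_exc
    ccfg <- mass_config_from_network(cfg, "CFM", v_bar = ref$v_bar)
    mcfg <- mass_config_from_network(cfg, "MFM", v_bar = ref$v_bar,
                                     v0 = sim$v_init_mean)
    cfm <- integrate_cfm(drv, ccfg, method = "exact")
    # the MFM's parametric forcing can be genuinely unstable under strongly
    # synchronized (delta-like) drive; a repetition that overflows or leaves
    # any physically interpretable range (|V| > 1e6 mV) is recorded as total
    # disagreement (rho = 0, excluded from the spectrum average)
    mfm <- tryCatch(integrate_mfm(drv, mcfg, method = "exact"),
                    error = function(e) NULL)
    if (!is.null(mfm) && max(abs(mfm$values)) > 1e6) mfm <- NULL
    list(sim = sim, ref = ref, cfm = cfm, mfm = mfm,
         sync = spike_contrast(raster_window(sim$raster,
                                             cfg$t_transient))$value,
         lc_cfm = fisher_significance(
           lagged_correlation(ref, cfm, max_lag), alpha = alpha, rho0 = rho0),
         lc_mfm = if (is.null(mfm)) NULL else fisher_significance(
           lagged_correlation(ref, mfm, max_lag), alpha = alpha, rho0 = rho0))
  })

  sp_lif <- estimate_spectrum(lapply(reps, `[[`, "ref"))
  sp_cfm <- estimate_spectrum(lapply(reps, `[[`, "cfm"))
  mfm_ok <- !vapply(reps, function(r) is.null(r$mfm), logical(1))
  sp_mfm <- if (any(mfm_ok)) {
    estimate_spectrum(lapply(reps[mfm_ok], `[[`, "mfm"))
  } else NULL
  L <- length(sp_lif$freqs)
  chi2_c <- chi2_spectra(sp_lif, sp_cfm)
  chi2_m <- if (is.null(sp_mfm)) Inf else chi2_spectra(sp_lif, sp_mfm)

  lc_c <- summarize_lagcorr(lapply(reps, `[[`, "lc_cfm"), alpha, rho0)
  lc_m <- summarize_lagcorr(lapply(reps, function(r) {
    r$lc_mfm %||% list(tau_max = 0, rho_max = 0, n_effective = 4,
                       significant = FALSE)
  }), alpha, rho0)

  summary <- data.frame(
    p = p, lambda = lambda, n_reps = length(seeds), subset = subset,
    synchrony = mean(vapply(reps, `[[`, numeric(1), "sync")),
    median_freq_lif = sp_lif$median_freq,
    median_freq_cfm = sp_cfm$median_freq,
    median_freq_mfm = if (is.null(sp_mfm)) NA_real_ else sp_mfm$median_freq,
    mfm_n_diverged = sum(!mfm_ok),
    chi2_cfm = chi2_c, chi2_mfm = chi2_m,
    chi2_cfm_ok = chi2_significance(chi2_c, L, alpha),
    chi2_mfm_ok = chi2_significance(chi2_m, L, alpha),
    chi2_self = chi2_spectra(sp_lif, sp_lif),     # per-point self-check, 0
    tau_max_cfm = lc_c$tau_max, rho_max_cfm = lc_c$rho_max,
    corr_cfm_ok = lc_c$significant,
    tau_max_mfm = lc_m$tau_max, rho_max_mfm = lc_m$rho_max,
    corr_mfm_ok = lc_m$significant,
    rate_hz = mean(vapply(reps, function(r) {
      length(r$sim$raster$time) / r$sim$config$n_units /
        (r$sim$config$t_total / 1000)
    }, numeric(1)))
  )
  list(summary = summary,
       details = list(reps = reps, sp_lif = sp_lif, sp_cfm = sp_cfm,
                      sp_mfm = sp_mfm))
}

# subset-aware drive: the simulator's recorded series are all-unit averages;
# for the excitatory-only variant the internal channels are recomputed over
# excitatory targets and the external channel rescaled to the subset size
# (external spikes only ever reach excitatory units).
point_drive <- function(sim, subset) {
  if (subset == "all") return(sim$drive)
  d <- population_drive(sim$raster, sim$internal_graph, sim$unit_type,
                        sim$config$dt, subset = "excitatory")
  n_exc <- sum(sim$unit_type == "excitatory")
  phi_ext <- sim$drive$phi_ext * sim$config$n_units / n_exc
  out <- drive_series(d$phi_exc, d$phi_inh, phi_ext, sim$config$dt)
  attr(out, "t_transient") <- sim$config$t_transient
  out
}

summarize_lagcorr <- function(lcs, alpha, rho0) {
  taus <- vapply(lcs, `[[`, numeric(1), "tau_max")
  rhos <- vapply(lcs, `[[`, numeric(1), "rho_max")
  neff <- vapply(lcs, `[[`, numeric(1), "n_effective")
  tab <- table(taus)
  modal <- as.numeric(names(tab)[tab == max(tab)])
  tau_mode <- modal[order(abs(modal), -sign(modal))][1]
  rho_mean <- mean(rhos)
  list(tau_max = tau_mode, rho_max = rho_mean,
       significant = fisher_significance(rho_mean, stats::median(neff),
                                         alpha, rho0))
}

#' Run a full sweep over the grid
#'
#' Iterates [run_point()] over all `{p, lambda}` combinations, appending one
#' summary row per completed point to `out_csv` (written after every point,
#' so an interrupted sweep can be resumed: with `resume = TRUE` points whose
#' coordinates already appear in the file are skipped and the final table is
#' identical to an uninterrupted run with the same master seed). Points are
#' independent given their seeds. A failing point is logged, marked and
#' skipped rather than aborting the sweep.
#'
#' @param grid a [sweep_grid()].
#' @param out_csv optional path of the append-safe results table.
#' @param resume skip points already present in `out_csv`.
#' @param subset forwarded to [run_point()].
#' @param verbose print one line per completed point.
#' @return data.frame of all completed points, sorted by `(p, lambda)`.
#' @export
run_sweep <- function(grid, out_csv = NULL, resume = FALSE,
                      subset = "all", verbose = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  done <- NULL
  if (resume && !is.null(out_csv) && file.exists(out_csv)) {
    done <- utils::read.csv(out_csv)
  }
  pts <- expand.grid(lambda = grid$lambda_values, p = grid$p_values)[, 2:1]
  rows <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts$p[i]; lam <- pts$lambda[i]
    if (!is.null(done) &&
        any(abs(done$p - p) < 1e-12 & abs(done$lambda - lam) < 1e-12)) {
      rows[[i]] <- done[abs(done$p - p) < 1e-12 &
                          abs(done$lambda - lam) < 1e-12, , drop = FALSE][1, ]
      next
    }
    res <- tryCatch(
      run_point(p, lam, grid$base_config, point_seeds(grid, i),
                subset = subset)$summary,
      error = function(e) {
        warning(sprintf("point (p=%g, lambda=%g) failed: %s", p, lam,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    rows[[i]] <- res
    if (!is.null(out_csv)) {
      utils::write.table(res, out_csv, sep = ",", row.names = FALSE,
                         col.names = !file.exists(out_csv), append =
                           file.exists(out_csv))
    }
    if (verbose) {
      message(sprintf("point (p=%g, lambda=%g): sync=%.3f, rho_cfm=%.3f",
                      p, lam, res$synchrony, res$rho_max_cfm))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$p, out$lambda), , drop = FALSE]
}
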