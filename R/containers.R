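#' Spike raster, drive series and potential trace containers
#'
#' Light S3 containers shared across the package. A `lif_raster` stores spike
#' events as parallel vectors (`unit`, `time` in ms) together with per-unit
#' type labels; a `lif_drive` stores the time-binned population-mean spike
#' input rates for the three synapse types (units 1/ms: a delta spike
#' contributes `1 / (N * dt)` to its bin); a `lif_trace` stores a uniformly
#' sampled potential series with its transient marker and post-transient time
#' average `v_bar`.
#'
#' @param unit integer unit indices (1-based).
#' @param time spike times in ms.
#' @param unit_type per-unit labels (`"excitatory"` / `"inhibitory"`).
#' @param t_total total duration in ms.
#' @return the corresponding container object.
#' @name containers
NULL

#' @rdname containers
#' @export
spike_raster <- function(unit, time, unit_type, t_total) {
  stopifnot(length(unit) == length(time))
  if (length(time) && (min(time) < 0 || max(time) > t_total + 1e-9)) {
    stop("spike times must lie in [0, t_total]", call. = FALSE)
  }
  ord <- order(time, unit)
  r <- list(unit = as.integer(unit[ord]), time = as.numeric(time[ord]),
            unit_type = unit_type, n_units = length(unit_type),
            t_total = t_total)
  class(r) <- "lif_raster"
  r
}

#' @export
print.lif_raster <- function(x, ...) {
  cat("<lif_raster>", length(x$time), "spikes from", x$n_units, "units over",
      x$t_total, "ms\n")
  invisible(x)
}

#' @rdname containers
#' @param phi_exc,phi_inh,phi_ext binned population-mean input rates (1/ms).
#' @param dt bin width (ms).
#' @export
drive_series <- function(phi_exc, phi_inh, phi_ext, dt) {
  n <- length(phi_exc)
  stopifnot(length(phi_inh) == n, length(phi_ext) == n, dt > 0)
  if (any(c(phi_exc, phi_inh, phi_ext) < 0)) {
    stop("drive series must be nonnegative", call. = FALSE)
  }
  d <- list(phi_exc = phi_exc, phi_inh = phi_inh, phi_ext = phi_ext,
            dt = dt, n_bins = n)
  class(d) <- "lif_drive"
  d
}

#' @rdname containers
#' @param values potential samples (mV), one per time step, sample `i` taken
#'   at time `i * dt`.
#' @param label one of `"LIF"`, `"CFM"`, `"MFM"`.
#' @param t_transient transient duration (ms) excluded from `v_bar`.
#' @export
potential_trace <- function(values, dt, label = c("LIF", "CFM", "MFM"),
                            t_transient = 0) {
  label <- match.arg(label)
  if (!all(is.finite(values))) {
    stop("potential trace contains non-finite values", call. = FALSE)
  }
  tr <- list(values = as.numeric(values), dt = dt, label = label,
             t_transient = t_transient,
             v_bar = mean(post_transient(values, dt, t_transient)))
  class(tr) <- "lif_trace"
  tr
}

#' @export
print.lif_trace <- function(x, ...) {
  cat("<lif_trace:", x$label, ">", length(x$values), "samples at dt =",
      x$dt, "ms, v_bar =", round(x$v_bar, 3), "mV\n")
  invisible(x)
}

# Samples strictly after the transient: sample i sits at time i*dt, keep
# i*dt > t_transient (robust to float noise in the comparison).
post_transient <- function(values, dt, t_transient) {
  n0 <- min(length(values), floor(t_transient / dt + 1e-9))
  values[seq2(n0 + 1L, length(values))]
}

#' Restrict a raster to a time window
#'
#' Keeps spikes with `t0 < time <= t1` and re-references times to the window
#' start, so downstream statistics (e.g. [spike_contrast()]) operate on the
#' post-transient recording.
#'
#' @param raster a `lif_raster`.
#' @param t0,t1 window bounds in ms (`t1` defaults to the raster end).
#' @return a `lif_raster` of duration `t1 - t0`.
#' @export
raster_window <- function(raster, t0, t1 = raster$t_total) {
  stopifnot(t1 > t0)
  keep <- raster$time > t0 & raster$time <= t1
  spike_raster(raster$unit[keep], raster$time[keep] - t0, raster$unit_type,
               t1 - t0)
}
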