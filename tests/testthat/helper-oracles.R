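# Independent oracles. These share no code with the package implementation:
# everything is computed by direct enumeration / closed form on small inputs.

# Brute-force spike-contrast at one bin size: walk every half-overlapping bin
# with explicit interval membership tests.
oracle_contrast_scale <- function(time, unit, n_units, t_total, b) {
  te <- pmin(time, t_total - 1e-9)   # end-spikes fold into the last bins
  starts <- seq(0, by = b / 2,
                length.out = max(1, ceiling(t_total / (b / 2))))
  theta <- integer(length(starts))
  nk <- integer(length(starts))
  for (k in seq_along(starts)) {
    inbin <- te >= starts[k] & te < starts[k] + b
    theta[k] <- sum(inbin)
    nk[k] <- length(unique(unit[inbin]))
  }
  tot <- sum(theta)
  if (tot == 0) return(0)
  contr <- if (length(theta) > 1) {
    min(1, sum(abs(diff(theta))) / (2 * length(time)))
  } else 0
  act <- (sum(nk * theta) / tot - 1) / (n_units - 1)
  contr * max(act, 0)
}

oracle_spike_contrast <- function(raster) {
  t_total <- raster$t_total
  isis <- unlist(lapply(split(raster$time, raster$unit), function(ts) {
    if (length(ts) > 1) diff(sort(ts)) else numeric(0)
  }))
  b <- t_total / 2
  sizes <- c()
  while (b >= 2 * min(isis)) {
    sizes <- c(sizes, b)
    b <- b / 2
  }
  if (length(sizes) < 3) sizes <- t_total / c(2, 4, 8)
  mean(vapply(sizes, function(b) {
    oracle_contrast_scale(raster$time, raster$unit, raster$n_units,
                          t_total, b)
  }, numeric(1)))
}

# Direct O(n * lags) lagged correlation on z-scored series.
oracle_lagcorr <- function(x, y, L) {
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  n <- length(x)
  vapply(-L:L, function(k) {
    if (k >= 0) {
      sum(zx[1:(n - k)] * zy[(1 + k):n]) / (n - k)
    } else {
      sum(zx[(1 - k):n] * zy[1:(n + k)]) / (n + k)
    }
  }, numeric(1))
}

# Closed-form relaxation of the drive-free second-order cascade from
# (V0, dV/dt = 0) toward v_leak.
oracle_biexp <- function(t, v0, v_leak, tau_m, tau_s) {
  v_leak + (v0 - v_leak) *
    (tau_m * exp(-t / tau_m) - tau_s * exp(-t / tau_s)) / (tau_m - tau_s)
}

# Closed-form LIF period under a clamped external conductance g_star with
# external reversal at 0 mV.
oracle_lif_period <- function(g_leak, g_star, v_leak, v_thres, v_reset,
                              tau_mem, tau_ref) {
  v_inf <- (g_leak * v_leak) / (g_leak + g_star)
  tau_eff <- tau_mem * g_leak / (g_leak + g_star)
  tau_eff * log((v_inf - v_reset) / (v_inf - v_thres)) + tau_ref
}

point_seeds_for_test <- function(grid, i) lifmass:::point_seeds(grid, i)

# Hand-built adjacency (list of per-source target vectors) in the package's
# compressed representation.
new_toy_graph <- function(tgt_list, n_units) {
  lens <- vapply(tgt_list, length, integer(1))
  g <- list(targets = as.integer(unlist(tgt_list, use.names = FALSE)),
            ptr = c(1L, 1L + cumsum(lens)),
            n_sources = length(tgt_list), n_targets = as.integer(n_units),
            kind = "internal")
  class(g) <- "lif_adjacency"
  g
}

# Small deterministic raster builder used across tests.
toy_raster <- function(spikes, n_units, t_total, lambda = 1) {
  spike_raster(spikes$unit, spikes$time, unit_types(n_units, lambda), t_total)
}
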