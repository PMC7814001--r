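#' Lag-optimised cross-correlation between potential traces
#'
#' Both traces are z-scored over their post-transient window (population
#' standard deviation, so a trace correlated with itself gives exactly 1 at
#' lag 0). The correlation
#' `rho(tau) = sum_t z_ref(t) z_model(t + tau) / (n - |k|)` is evaluated for
#' all integer-bin lags `k` in `[-max_lag, max_lag]` via FFT; `tau_max`
#' selects the lag maximising `|rho|` (ties broken toward the smallest
#' `|tau|`, then the positive one). A positive `tau_max` means the model
#' lags behind the reference.
#'
#' The effective sample size reported for significance testing is the number
#' of post-transient samples divided by the integrated autocorrelation time
#' of the reference (raw counts at sub-millisecond sampling grossly overstate
#' independence).
#'
#' @param ref,model `lif_trace` objects with identical `dt` and length.
#' @param max_lag maximum lag (ms), much smaller than the trace length;
#'   default 500 ms.
#' @param t_transient transient to exclude (ms); defaults to `ref`'s marker.
#' @return a `lif_lagcorr`: `rho` (correlation per lag), `lags` (ms),
#'   `tau_max` (ms), `rho_max`, `n_effective`, `model_label`, and
#'   `significant` (`NA` until [fisher_significance()] is applied).
#' @examples
#' x <- sin(2 * pi * 5 * (1:30000) / 10000) + 0.1 * rnorm(30000)
#' a <- potential_trace(x, 0.1, "LIF")
#' b <- potential_trace(c(rep(0, 150), x[1:29850]), 0.1, "CFM")
#' lagged_correlation(a, b, max_lag = 50)$tau_max   # 15 ms delay
#' @export
lagged_correlation <- function(ref, model, max_lag = 500,
                               t_transient = NULL) {
  stopifnot(inherits(ref, "lif_trace"), inherits(model, "lif_trace"))
  if (abs(ref$dt - model$dt) > 1e-12) stop("traces must share dt", call. = FALSE)
  tt <- t_transient %||% ref$t_transient
  x <- post_transient(ref$values, ref$dt, tt)
  y <- post_transient(model$values, model$dt, tt)
  n <- length(x)
  if (length(y) != n) stop("traces must share length", call. = FALSE)
  L <- as.integer(round(max_lag / ref$dt))
  if (L >= n) stop("max_lag must be much smaller than the trace", call. = FALSE)
  zx <- zscore(x)
  zy <- zscore(y)
  cc <- cross_corr_fft(zx, zy, L)           # sum_t zx[t] * zy[t + k]
  rho <- cc / (n - abs(-L:L))
  rho <- pmin(1, pmax(-1, rho))
  lags <- (-L:L) * ref$dt
  # argmax |rho|; ties -> smallest |tau|, then positive tau
  best <- order(-abs(rho), abs(lags), -sign(lags))[1]
  res <- list(rho = rho, lags = lags,
              tau_max = lags[best], rho_max = rho[best],
              n_effective = n / integrated_act(zx),
              model_label = model$label, significant = NA)
  class(res) <- "lif_lagcorr"
  res
}

#' @export
print.lif_lagcorr <- function(x, ...) {
  cat("<lif_lagcorr:", x$model_label, "> rho_max =", round(x$rho_max, 4),
      "at tau_max =", x$tau_max, "ms (n_eff =", round(x$n_effective, 1), ")\n")
  invisible(x)
}

zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero-variance trace: correlation undefined", call. = FALSE)
  (x - mean(x)) / s
}

# sum_t x[t] * y[t + k] for k = -L..L, zero-padded FFT cross-correlation
cross_corr_fft <- function(x, y, L) {
  n <- length(x)
  m <- stats::nextn(n + L, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  # index 1 is lag 0, 1+k is lag k (k>0); lag -k wraps to m+1-k
  c(cc[(m - L + 1):m], cc[1:(L + 1)])
}

# Integrated autocorrelation time: 1 + 2 * sum of the autocorrelation up to
# its first non-positive value (capped at n/10); >= 1.
integrated_act <- function(z) {
  n <- length(z)
  kmax <- max(1L, n %/% 10L)
  ac <- cross_corr_fft(z, z, kmax)[(kmax + 2):(2 * kmax + 1)] / (n - seq_len(kmax))
  cut <- which(ac <= 0)[1]
  if (!is.na(cut)) ac <- ac[seq_len(cut - 1L)]
  max(1, 1 + 2 * sum(ac))
}

#' Fisher-transform agreement test for a lag-optimised correlation
#'
#' Classifies whether a model trace is "not significantly different" from
#' the reference: the Fisher `1 - alpha` confidence interval for the
#' correlation, `atanh(rho) +/- z_{1-alpha/2} / sqrt(n_effective - 3)`, must
#' lie entirely above the agreement threshold `atanh(rho0)`. A correlation
#' of magnitude 1 is treated as trivially perfect agreement (when positive).
#'
#' @param rho_max lag-optimised correlation, or a `lif_lagcorr` (in which
#'   case its stored `rho_max` / `n_effective` are used and the object is
#'   returned with `significant` filled in).
#' @param n_effective effective sample size (> 3), ignored when a
#'   `lif_lagcorr` is passed.
#' @param alpha significance level (default 0.01).
#' @param rho0 agreement threshold (default 0.95).
#' @return logical, or the updated `lif_lagcorr`.
#' @export
fisher_significance <- function(rho_max, n_effective = NULL, alpha = 0.01,
                                rho0 = 0.95) {
  if (inherits(rho_max, "lif_lagcorr")) {
    obj <- rho_max
    obj$significant <- fisher_significance(obj$rho_max, obj$n_effective,
                                           alpha, rho0)
    return(obj)
  }
  if (abs(rho_max) >= 1) return(rho_max >= 1)
  if (is.null(n_effective) || n_effective <= 3) {
    stop("n_effective must exceed 3", call. = FALSE)
  }
  z <- atanh(rho_max)
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n_effective - 3)
  (z - half) > atanh(rho0)
}
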