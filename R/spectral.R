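#' Averaged power spectrum of potential traces
#'
#' Per realization: the post-transient samples are mean-removed, multiplied
#' by a Hamming window and Fourier-transformed; the one-sided periodogram
#' `|X_l|^2 / n` is averaged across realizations (conventionally 10
#' independently seeded runs). The frequency band is restricted to
#' `[f_min, f_max]` (default 0.5-500 Hz) to drop DC / ultra-slow drift and
#' window leakage; no segment averaging is used (one whole-trace periodogram
#' per realization).
#'
#' @param traces a `lif_trace` or list of them; all must share `dt`, length
#'   and transient.
#' @param t_transient transient (ms) to exclude; defaults to the traces' own
#'   marker.
#' @param f_min,f_max retained frequency band (Hz).
#' @return a `lif_spectrum`: `power`, `freqs` (Hz, strictly increasing),
#'   `n_realizations`, `median_freq`.
#' @examples
#' tr <- potential_trace(sin(2 * pi * 10 * (1:20000) / 10000), 0.1, "LIF")
#' estimate_spectrum(tr)$median_freq
#' @export
estimate_spectrum <- function(traces, t_transient = NULL,
                              f_min = 0.5, f_max = 500) {
  if (inherits(traces, "lif_trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("need at least one trace", call. = FALSE)
  dt <- traces[[1]]$dt
  tt <- t_transient %||% traces[[1]]$t_transient
  xs <- lapply(traces, function(tr) {
    if (abs(tr$dt - dt) > 1e-12) stop("traces must share dt", call. = FALSE)
    post_transient(tr$values, tr$dt, tt)
  })
  n <- length(xs[[1]])
  if (any(vapply(xs, length, integer(1)) != n)) {
    stop("traces must share length", call. = FALSE)
  }
  w <- hamming_window(n)
  fs <- 1000 / dt                                  # Hz
  freqs_all <- (seq_len(n %/% 2)) * fs / n         # one-sided, DC dropped
  pw <- Reduce(`+`, lapply(xs, function(x) {
    X <- stats::fft((x - mean(x)) * w)
    (Mod(X[2:(n %/% 2 + 1)])^2) / n
  })) / length(xs)
  keep <- freqs_all >= f_min & freqs_all <= f_max
  if (!any(keep)) stop("empty frequency band", call. = FALSE)
  sp <- list(power = pw[keep], freqs = freqs_all[keep],
             n_realizations = length(xs), median_freq = NA_real_)
  class(sp) <- "lif_spectrum"
  sp$median_freq <- median_frequency(sp)
  sp
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' @export
print.lif_spectrum <- function(x, ...) {
  cat("<lif_spectrum>", length(x$freqs), "bins in [",
      round(min(x$freqs), 2), ",", round(max(x$freqs), 2),
      "] Hz, median_freq =", round(x$median_freq, 3), "Hz (",
      x$n_realizations, "realizations )\n")
  invisible(x)
}

#' Median frequency of a spectrum
#'
#' The smallest frequency bin at which the cumulative power reaches half of
#' the total power.
#'
#' @param spectrum a `lif_spectrum`.
#' @return frequency in Hz.
#' @export
median_frequency <- function(spectrum) {
  tot <- sum(spectrum$power)
  if (tot <= 0) stop("median frequency undefined for zero spectrum",
                     call. = FALSE)
  spectrum$freqs[which(cumsum(spectrum$power) >= tot / 2)[1]]
}

#' Chi-squared distance between two spectra
#'
#' Both spectra are rescaled to a common histogram scale (unit sum times a
#' shared effective-count constant, by default the number of bins `L`), then
#' `chi^2 = sum_l (P_l - Q_l)^2 / (P_l + Q_l)`, skipping bins where
#' `P_l + Q_l = 0`. The statistic scales linearly with `count_scale`; the
#' constant cancels in relative comparisons across parameter points.
#'
#' @param p,q `lif_spectrum` objects on identical frequency grids.
#' @param count_scale shared histogram scale; default `length(p$power)`.
#' @return the scalar statistic.
#' @export
chi2_spectra <- function(p, q, count_scale = NULL) {
  stopifnot(inherits(p, "lif_spectrum"), inherits(q, "lif_spectrum"))
  if (length(p$freqs) != length(q$freqs) ||
      max(abs(p$freqs - q$freqs)) > 1e-9) {
    stop("spectra are on different frequency grids", call. = FALSE)
  }
  L <- length(p$power)
  cs <- count_scale %||% L
  ph <- p$power / sum(p$power) * cs
  qh <- q$power / sum(q$power) * cs
  s <- ph + qh
  nz <- s > 0
  sum((ph[nz] - qh[nz])^2 / s[nz])
}

#' Chi-squared indistinguishability at level alpha
#'
#' `TRUE` iff the statistic does not exceed the `1 - alpha` quantile of the
#' chi-squared distribution with `n_bins - 1` degrees of freedom (one degree
#' lost to the unit-sum normalization), i.e. the two spectra are *not*
#' significantly different at level `alpha`.
#'
#' @param stat statistic from [chi2_spectra()].
#' @param n_bins number of frequency bins `L` (>= 2).
#' @param alpha significance level (default 0.01).
#' @return logical.
#' @export
chi2_significance <- function(stat, n_bins, alpha = 0.01) {
  stopifnot(n_bins >= 2)
  stat <= stats::qchisq(1 - alpha, df = n_bins - 1)
}
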