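# Multitaper spectral estimation: DPSS tapers, PSD, spectrogram, coherence.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computes the first `k` Slepian tapers of length `n` at time-bandwidth
#' product `nw`, from the symmetric tridiagonal commuting matrix of the
#' spheroidal concentration problem; tapers are unit-norm, mutually
#' orthogonal and ordered by decreasing spectral concentration. The
#' concentration (eigenvalue of the sinc-kernel problem, the fraction of each
#' taper's energy inside the design band of half-width `nw/n` cycles per
#' sample) is computed from the sinc-kernel quadratic form and returned
#' alongside. Results are cached per `(n, nw, k)`.
#'
#' The package defaults mirror 2 s windows at 780 Hz with +/-1 Hz bandwidth:
#' `n = 1560`, `nw = 2`, `k = 3 = 2 * nw - 1` tapers.
#'
#' @param n taper length, samples (`n > 2 * nw`).
#' @param nw time-bandwidth product.
#' @param k number of tapers (`1 <= k <= 2 * nw - 1`).
#' @return A `taper_set`: list with `tapers` (n x k matrix),
#'   `concentrations`, `n`, `nw`, `k`, `w` (= `nw/n`).
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  if (k < 1 || k > 2 * nw - 1) stop("k must satisfy 1 <= k <= 2*nw - 1", call. = FALSE)
  if (n <= 2 * nw) stop("n must exceed 2*nw", call. = FALSE)
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_v
  A[cbind(1:(n - 1), 2:n)] <- off_v
  A[cbind(2:n, 1:(n - 1))] <- off_v
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  # sign convention: fix each taper so its largest-magnitude element is > 0
  for (j in seq_len(k)) {
    pk <- which.max(abs(v[, j]))
    if (v[pk, j] < 0) v[, j] <- -v[, j]
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
  }
  # concentrations via the sinc kernel S_ij = sin(2 pi w (i-j)) / (pi (i-j))
  d <- 1:(n - 1)
  first <- c(2 * w, sin(2 * pi * w * d) / (pi * d))
  S <- stats::toeplitz(first)
  lam <- vapply(seq_len(k), function(j) drop(crossprod(v[, j], S %*% v[, j])), numeric(1))
  out <- structure(list(tapers = v, concentrations = lam, n = n, nw = nw,
                        k = k, w = w), class = "taper_set")
  .taper_cache[[key]] <- out
  out
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf("<taper_set> n = %d, NW = %g, K = %d; concentrations: %s\n",
              x$n, x$nw, x$k, paste(sprintf("%.6f", x$concentrations), collapse = ", ")))
  invisible(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Tapered eigencoefficients of one segment: (nfft x k) complex matrix.
eigencoefs <- function(segment, tapers, nfft) {
  seg <- segment - mean(segment)
  X <- matrix(0+0i, nfft, ncol(tapers))
  for (j in seq_len(ncol(tapers))) {
    xt <- seg * tapers[, j]
    X[, j] <- stats::fft(c(xt, rep(0, nfft - length(xt))))
  }
  X
}

one_sided_index <- function(nfft) seq_len(floor(nfft / 2) + 1L)

# Fold a two-sided spectral density (length nfft) to one-sided.
fold_one_sided <- function(sxx, nfft) {
  idx <- one_sided_index(nfft)
  out <- sxx[idx]
  interior <- idx > 1 & (idx - 1) < nfft / 2
  out[interior] <- 2 * out[interior]
  out
}

#' Multitaper power spectral density of one segment
#'
#' Average over `k` eigenspectra of the squared magnitude of the Fourier
#' transform of the tapered (demeaned) segment, scaled so that the integral
#' of the one-sided PSD over frequency approximates the segment variance
#' (Parseval consistency).
#'
#' @param segment numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product (default 2, i.e. +/-1 Hz at 2 s windows).
#' @param k number of tapers (default 3).
#' @param nfft FFT length; default the next power of two (zero-padding gives
#'   a smooth display grid). Pass `nfft = length(segment)` for the raw grid.
#' @param tapers optional precomputed [dpss_tapers()].
#' @return A `spectral_estimate`: list with `freq_hz`, `power` (units^2/Hz,
#'   one-sided) and `params`.
#' @export
mt_psd <- function(segment, fs, nw = 2, k = 3, nfft = NULL, tapers = NULL) {
  n <- length(segment)
  if (is.null(tapers)) tapers <- dpss_tapers(n, nw, k)
  if (tapers$n != n) stop("segment shorter than taper length", call. = FALSE)
  nfft <- nfft %||% next_pow2(n)
  X <- eigencoefs(segment, tapers$tapers, nfft)
  sxx <- rowMeans(Mod(X)^2) / fs
  idx <- one_sided_index(nfft)
  structure(list(freq_hz = (idx - 1) * fs / nfft,
                 power = fold_one_sided(sxx, nfft),
                 params = list(fs = fs, nw = tapers$nw, k = tapers$k,
                               n = n, nfft = nfft)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  pk <- x$freq_hz[which.max(x$power)]
  cat(sprintf("<spectral_estimate> %d bins to %.1f Hz (NW=%g, K=%d); peak at %.2f Hz\n",
              length(x$freq_hz), max(x$freq_hz), x$params$nw, x$params$k, pk))
  invisible(x)
}

# Window start indices (1-based samples) for a moving-window analysis.
window_starts <- function(n_samples, fs, window_s, step_s) {
  n_win <- round(window_s * fs)
  step <- round(step_s * fs)
  if (n_samples < n_win) return(integer(0))
  seq(1L, n_samples - n_win + 1L, by = step)
}

#' Multitaper spectrogram
#'
#' [mt_psd()] applied over moving windows of `window_s` seconds overlapping
#' by `overlap_s` (step = window - overlap; the defaults give 2 s windows
#' stepping by 1.5 s). The output is truncated at `fmax` for display and
#' export.
#'
#' @param signal a [labeled_signal()] or numeric vector.
#' @param fs sampling rate (taken from the signal when omitted).
#' @param window_s,overlap_s moving-window length and overlap, seconds.
#' @param nw,k,nfft as in [mt_psd()].
#' @param fmax highest frequency retained, Hz (default 20).
#' @return A `spectrogram`: list with `time_s` (window centres), `freq_hz`,
#'   `power` (frequency x time matrix) and `params`.
#' @export
mt_spectrogram <- function(signal, fs = NULL, window_s = 2, overlap_s = 0.5,
                           nw = 2, k = 3, nfft = NULL, fmax = 20) {
  if (inherits(signal, "labeled_signal")) {
    fs <- fs %||% signal$fs_hz
    signal <- signal$samples
  }
  stopifnot(!is.null(fs), overlap_s < window_s)
  n_win <- round(window_s * fs)
  if (length(signal) < n_win) stop("signal shorter than one window", call. = FALSE)
  starts <- window_starts(length(signal), fs, window_s, window_s - overlap_s)
  tapers <- dpss_tapers(n_win, nw, k)
  nfft <- nfft %||% next_pow2(n_win)
  first <- mt_psd(signal[starts[1] + 0:(n_win - 1)], fs, nw, k, nfft, tapers)
  keep <- first$freq_hz <= fmax
  power <- matrix(NA_real_, sum(keep), length(starts))
  power[, 1] <- first$power[keep]
  for (s in seq_along(starts)[-1]) {
    est <- mt_psd(signal[starts[s] + 0:(n_win - 1)], fs, nw, k, nfft, tapers)
    power[, s] <- est$power[keep]
  }
  structure(list(time_s = (starts - 1) / fs + window_s / 2,
                 freq_hz = first$freq_hz[keep], power = power,
                 params = first$params), class = "spectrogram")
}

#' Multitaper magnitude-squared coherence
#'
#' Cross- and auto-spectra are averaged over tapers and over moving windows
#' (same layout as [mt_spectrogram()]); the magnitude-squared coherence is
#' `|<Sxy>|^2 / (<Sxx> <Syy>)`, bounded in `[0, 1]` and equal to 1 at every
#' frequency when the two signals are affinely related.
#'
#' @param x,y equal-length numeric vectors (or [labeled_signal()]s) at the
#'   same sampling rate.
#' @param fs sampling rate.
#' @param window_s,overlap_s moving-window layout, seconds.
#' @param nw,k,nfft as in [mt_psd()].
#' @param fmax optional frequency cut for the output.
#' @return A `coherence_estimate`: list with `freq_hz`, `coherence`,
#'   `n_windows`, `params`.
#' @export
mt_coherence <- function(x, y, fs = NULL, window_s = 2, overlap_s = 0.5,
                         nw = 2, k = 3, nfft = NULL, fmax = NULL) {
  if (inherits(x, "labeled_signal")) { fs <- fs %||% x$fs_hz; x <- x$samples }
  if (inherits(y, "labeled_signal")) y <- y$samples
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  stopifnot(!is.null(fs))
  n_win <- round(window_s * fs)
  if (length(x) < n_win) stop("signals shorter than one window", call. = FALSE)
  starts <- window_starts(length(x), fs, window_s, window_s - overlap_s)
  tapers <- dpss_tapers(n_win, nw, k)
  nfft <- nfft %||% next_pow2(n_win)
  sxx <- syy <- numeric(nfft)
  sxy <- complex(nfft)
  for (s in starts) {
    seg <- s + 0:(n_win - 1)
    X <- eigencoefs(x[seg], tapers$tapers, nfft)
    Y <- eigencoefs(y[seg], tapers$tapers, nfft)
    sxx <- sxx + rowSums(Mod(X)^2)
    syy <- syy + rowSums(Mod(Y)^2)
    sxy <- sxy + rowSums(X * Conj(Y))
  }
  coh <- Mod(sxy)^2 / (sxx * syy)
  coh[!is.finite(coh)] <- 0
  idx <- one_sided_index(nfft)
  freq <- (idx - 1) * fs / nfft
  coh <- coh[idx]
  if (!is.null(fmax)) {
    keep <- freq <= fmax
    freq <- freq[keep]
    coh <- coh[keep]
  }
  structure(list(freq_hz = freq, coherence = coh, n_windows = length(starts),
                 params = list(fs = fs, nw = nw, k = k, window_s = window_s,
                               overlap_s = overlap_s, nfft = nfft)),
            class = "coherence_estimate")
}

#' @export
print.coherence_estimate <- function(x, ...) {
  pk <- x$freq_hz[which.max(x$coherence)]
  cat(sprintf("<coherence_estimate> %d bins, %d windows; max C = %.3f at %.2f Hz\n",
              length(x$freq_hz), x$n_windows, max(x$coherence), pk))
  invisible(x)
}
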