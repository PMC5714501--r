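# Pre-micturition epoch spectra / coherence and the repeated-measures ANOVA.

default_epochs <- function() list(pre = c(-30, 0), baseline = c(-60, -30))

epoch_segment <- function(samples, fs, event_time, epoch) {
  a <- event_time + epoch[1]
  b <- event_time + epoch[2]
  if (a < 0 || b * fs > length(samples)) return(NULL)
  i0 <- round(a * fs) + 1L
  i1 <- round(b * fs)
  samples[i0:i1]
}

#' Per-cycle epoch power spectra and their means
#'
#' For each micturition cycle and each named epoch (by default `pre`, the
#' 30 s ending at peak pressure, and `baseline`, the preceding 30 s), the
#' multitaper PSD is averaged over all complete moving windows inside the
#' epoch; spectra are then averaged across cycles. Cycles whose epoch would
#' be truncated by a session edge are skipped with a warning.
#'
#' @param signal a [labeled_signal()] or numeric vector.
#' @param events a `uro_events` data frame or numeric vector of peak times.
#' @param fs sampling rate (taken from the signal when omitted).
#' @param epochs named list of `c(start, end)` offsets relative to the peak,
#'   seconds.
#' @param window_s,overlap_s,nw,k,nfft spectral parameters as in
#'   [mt_spectrogram()].
#' @param fmax highest frequency retained, Hz.
#' @return An `epoch_spectra`: list with `freq_hz`, `per_cycle` (array
#'   frequency x epoch x cycle), `mean` (matrix frequency x epoch), `epochs`,
#'   `cycles_used`.
#' @export
epoch_mean_spectra <- function(signal, events, fs = NULL,
                               epochs = default_epochs(), window_s = 2,
                               overlap_s = 0.5, nw = 2, k = 3, nfft = NULL,
                               fmax = 20) {
  if (inherits(signal, "labeled_signal")) {
    fs <- fs %||% signal$fs_hz
    signal <- signal$samples
  }
  stopifnot(!is.null(fs), length(epochs) >= 1, !is.null(names(epochs)))
  peaks <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  n_win <- round(window_s * fs)
  tapers <- dpss_tapers(n_win, nw, k)
  nfft <- nfft %||% next_pow2(n_win)
  freq <- (one_sided_index(nfft) - 1) * fs / nfft
  keep <- freq <= fmax
  freq <- freq[keep]

  epoch_psd <- function(seg) {
    starts <- window_starts(length(seg), fs, window_s, window_s - overlap_s)
    if (!length(starts)) return(NULL)
    acc <- numeric(sum(keep))
    for (s in starts) {
      est <- mt_psd(seg[s + 0:(n_win - 1)], fs, nw, k, nfft, tapers)
      acc <- acc + est$power[keep]
    }
    acc / length(starts)
  }

  per <- list()
  used <- integer(0)
  for (ci in seq_along(peaks)) {
    mats <- matrix(NA_real_, length(freq), length(epochs),
                   dimnames = list(NULL, names(epochs)))
    ok <- TRUE
    for (en in names(epochs)) {
      seg <- epoch_segment(signal, fs, peaks[ci], epochs[[en]])
      p <- if (is.null(seg)) NULL else epoch_psd(seg)
      if (is.null(p)) { ok <- FALSE; break }
      mats[, en] <- p
    }
    if (!ok) {
      warning(sprintf("cycle %d skipped: epoch truncated by session edge", ci))
      next
    }
    per[[length(per) + 1L]] <- mats
    used <- c(used, ci)
  }
  if (!length(per)) stop("no cycle had complete epochs", call. = FALSE)
  arr <- array(unlist(per), dim = c(length(freq), length(epochs), length(per)),
               dimnames = list(NULL, names(epochs), NULL))
  structure(list(freq_hz = freq, per_cycle = arr,
                 mean = apply(arr, c(1, 2), mean),
                 epochs = epochs, cycles_used = used),
            class = "epoch_spectra")
}

#' Per-cycle epoch coherence between two signals
#'
#' Companion to [epoch_mean_spectra()]: for each cycle and epoch the
#' magnitude-squared coherence is estimated from the moving windows inside
#' the epoch ([mt_coherence()] on the epoch segment).
#'
#' @param x,y the two signals ([labeled_signal()] or numeric), equal length
#'   and rate.
#' @inheritParams epoch_mean_spectra
#' @return An `epoch_spectra`-shaped list (`freq_hz`, `per_cycle`, `mean`,
#'   `epochs`, `cycles_used`) holding coherence values in `[0, 1]`.
#' @export
epoch_coherence <- function(x, y, events, fs = NULL, epochs = default_epochs(),
                            window_s = 2, overlap_s = 0.5, nw = 2, k = 3,
                            nfft = NULL, fmax = 20) {
  if (inherits(x, "labeled_signal")) { fs <- fs %||% x$fs_hz; x <- x$samples }
  if (inherits(y, "labeled_signal")) y <- y$samples
  if (length(x) != length(y)) stop("signals must have equal length", call. = FALSE)
  stopifnot(!is.null(fs))
  peaks <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  per <- list()
  used <- integer(0)
  freq <- NULL
  for (ci in seq_along(peaks)) {
    mats <- NULL
    ok <- TRUE
    for (en in names(epochs)) {
      sx <- epoch_segment(x, fs, peaks[ci], epochs[[en]])
      sy <- epoch_segment(y, fs, peaks[ci], epochs[[en]])
      if (is.null(sx) || is.null(sy) || length(sx) < round(window_s * fs)) {
        ok <- FALSE; break
      }
      est <- mt_coherence(sx, sy, fs, window_s, overlap_s, nw, k, nfft, fmax)
      if (is.null(freq)) freq <- est$freq_hz
      if (is.null(mats)) mats <- matrix(NA_real_, length(freq), length(epochs),
                                        dimnames = list(NULL, names(epochs)))
      mats[, en] <- est$coherence
    }
    if (!ok) {
      warning(sprintf("cycle %d skipped: epoch truncated by session edge", ci))
      next
    }
    per[[length(per) + 1L]] <- mats
    used <- c(used, ci)
  }
  if (!length(per)) stop("no cycle had complete epochs", call. = FALSE)
  arr <- array(unlist(per), dim = c(length(freq), length(epochs), length(per)),
               dimnames = list(NULL, names(epochs), NULL))
  structure(list(freq_hz = freq, per_cycle = arr,
                 mean = apply(arr, c(1, 2), mean),
                 epochs = epochs, cycles_used = used),
            class = "epoch_spectra")
}

#' Two-way repeated-measures ANOVA across epochs and frequencies
#'
#' Classical univariate repeated-measures decomposition with cycles as
#' subjects and epoch (2 levels) and frequency (the repeated measure over
#' bins) as within-subject factors. Each effect is tested against its
#' interaction with cycles; the epoch main effect, the result of interest,
#' has 1 and (cycles - 1) degrees of freedom. No sphericity correction is
#' applied (none is standard for this design's headline contrast; the
#' epoch factor has only two levels, for which sphericity holds trivially).
#'
#' @param per_cycle array frequency x epoch x cycle, e.g. the `per_cycle`
#'   component of [epoch_mean_spectra()] or [epoch_coherence()] (an
#'   `epoch_spectra` object may be passed directly).
#' @return An `epoch_anova`: list with `F_epoch`, `df1`, `df2`, `p_epoch`
#'   and `table`, the full effect table.
#' @export
rm_anova_epochs <- function(per_cycle) {
  if (inherits(per_cycle, "epoch_spectra")) per_cycle <- per_cycle$per_cycle
  d <- dim(per_cycle)
  stopifnot(length(d) == 3)
  nf <- d[1]; ne <- d[2]; nc <- d[3]
  if (nc < 2) stop("repeated-measures ANOVA needs at least 2 cycles", call. = FALSE)
  if (ne < 2) stop("need at least 2 epochs", call. = FALSE)
  Y <- per_cycle
  m <- mean(Y)
  m_e <- apply(Y, 2, mean)
  m_f <- apply(Y, 1, mean)
  m_c <- apply(Y, 3, mean)
  m_ec <- apply(Y, c(2, 3), mean)
  m_fc <- apply(Y, c(1, 3), mean)
  m_fe <- apply(Y, c(1, 2), mean)

  ss_epoch <- nf * nc * sum((m_e - m)^2)
  ss_err_e <- nf * sum((m_ec - outer(m_e, rep(1, nc)) -
                          outer(rep(1, ne), m_c) + m)^2)
  ss_freq <- ne * nc * sum((m_f - m)^2)
  ss_err_f <- ne * sum((m_fc - outer(m_f, rep(1, nc)) -
                          outer(rep(1, nf), m_c) + m)^2)
  ss_fe <- nc * sum((m_fe - outer(m_f, rep(1, ne)) -
                       outer(rep(1, nf), m_e) + m)^2)
  resid <- Y
  for (ci in seq_len(nc))
    resid[, , ci] <- Y[, , ci] - m_fe -
      outer(m_fc[, ci], rep(1, ne)) - outer(rep(1, nf), m_ec[, ci]) +
      outer(m_f, rep(1, ne)) + outer(rep(1, nf), m_e) + m_c[ci] - m
  ss_err_fe <- sum(resid^2)

  eff <- function(name, ss, df1, ss_err, df2) {
    mse <- ss_err / df2
    Fv <- if (mse > 0) (ss / df1) / mse else if (ss == 0) 0 else Inf
    data.frame(effect = name, df1 = df1, df2 = df2, ss = ss, ss_error = ss_err,
               F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  }
  tab <- rbind(
    eff("epoch", ss_epoch, ne - 1, ss_err_e, (ne - 1) * (nc - 1)),
    eff("frequency", ss_freq, nf - 1, ss_err_f, (nf - 1) * (nc - 1)),
    eff("epoch:frequency", ss_fe, (ne - 1) * (nf - 1), ss_err_fe,
        (ne - 1) * (nf - 1) * (nc - 1)))
  rownames(tab) <- NULL
  structure(list(F_epoch = tab$F[1], df1 = tab$df1[1], df2 = tab$df2[1],
                 p_epoch = tab$p[1], table = tab), class = "epoch_anova")
}

#' @export
print.epoch_anova <- function(x, ...) {
  cat(sprintf("<epoch_anova> epoch effect: F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F_epoch, x$p_epoch))
  invisible(x)
}
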