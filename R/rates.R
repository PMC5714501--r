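# Binned firing rates, z-scores, peri-event matrices, pre/post comparison.

#' Binned firing rate of a spike train
#'
#' Half-open bins `[start, start + width)` tile the interval from its start;
#' a trailing partial bin is dropped. Rate is count divided by bin width, so
#' the total binned count equals the number of spikes in the tiled portion of
#' the interval.
#'
#' @param train a [spike_train()] or a numeric vector of spike times.
#' @param bin_width_s bin width, seconds (5 s for across-cycle averages, 1 s
#'   for latency estimation).
#' @param interval numeric length-2, the interval to tile.
#' @return A `rate_series`: list with `bin_starts_s`, `bin_width_s`,
#'   `counts`, `rates_hz`.
#' @export
bin_rate <- function(train, bin_width_s, interval) {
  times <- if (inherits(train, "spike_train")) train$times_s else as.numeric(train)
  stopifnot(bin_width_s > 0, length(interval) == 2L)
  span <- interval[2] - interval[1]
  n_bins <- floor(span / bin_width_s + 1e-9)
  if (n_bins <= 0) {
    return(structure(list(bin_starts_s = numeric(0), bin_width_s = bin_width_s,
                          counts = integer(0), rates_hz = numeric(0)),
                     class = "rate_series"))
  }
  starts <- interval[1] + bin_width_s * (seq_len(n_bins) - 1)
  idx <- floor((times - interval[1]) / bin_width_s)
  idx <- idx[times >= interval[1] & idx < n_bins]
  counts <- tabulate(idx + 1L, nbins = n_bins)
  structure(list(bin_starts_s = starts, bin_width_s = bin_width_s,
                 counts = counts, rates_hz = counts / bin_width_s),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d bins of %g s, mean rate %.2f Hz\n",
              length(x$counts), x$bin_width_s,
              if (length(x$counts)) mean(x$rates_hz) else NA_real_))
  invisible(x)
}

# Indices of bins lying wholly inside any of the given [start, end) windows.
bins_in_windows <- function(rs, windows) {
  if (is.matrix(windows) || is.data.frame(windows)) {
    windows <- lapply(seq_len(nrow(windows)), function(i) as.numeric(windows[i, 1:2]))
  } else if (is.numeric(windows)) {
    windows <- list(windows)
  }
  ends <- rs$bin_starts_s + rs$bin_width_s
  inside <- rep(FALSE, length(rs$bin_starts_s))
  for (w in windows) {
    if (anyNA(w)) next
    inside <- inside | (rs$bin_starts_s >= w[1] - 1e-9 & ends <= w[2] + 1e-9)
  }
  which(inside)
}

#' Z-score a binned firing rate against background windows
#'
#' The background mean and standard deviation are computed from the bins that
#' lie wholly inside the background windows (by default each cycle's
#' intermicturition window); the z-transform `(rate - mean) / sd` is then
#' applied to every bin. Over the background bins themselves the z-scores
#' have mean 0 and (sample) standard deviation 1 by construction.
#'
#' If the background has exactly zero variance the series is degenerate: when
#' every rate in the series equals the background mean, z is defined as 0
#' everywhere (self-normalisation of a constant series) with a warning;
#' otherwise an error of class `uro_degenerate_background` is signalled.
#'
#' @param rate_series a [bin_rate()] result.
#' @param background_windows one window `c(start, end)`, a list of such
#'   windows, or a two-column matrix/data frame of them.
#' @return A `zrate_series`: the rate series plus `background_mean_hz`,
#'   `background_sd_hz` and `z`.
#' @export
zscore_rate <- function(rate_series, background_windows) {
  stopifnot(inherits(rate_series, "rate_series"))
  bg <- bins_in_windows(rate_series, background_windows)
  if (length(bg) < 2)
    stop("background windows contain fewer than 2 bins", call. = FALSE)
  m <- mean(rate_series$rates_hz[bg])
  s <- stats::sd(rate_series$rates_hz[bg])
  if (s == 0) {
    if (all(rate_series$rates_hz == m)) {
      warning("constant series with zero background variance; z set to 0")
      z <- rep(0, length(rate_series$rates_hz))
      s <- 0
    } else {
      stop(structure(class = c("uro_degenerate_background", "error", "condition"),
                     list(message = "background firing rate has zero variance",
                          call = sys.call())))
    }
  } else {
    z <- (rate_series$rates_hz - m) / s
  }
  out <- rate_series
  out$background_mean_hz <- m
  out$background_sd_hz <- s
  out$background_bins <- bg
  out$z <- z
  class(out) <- c("zrate_series", "rate_series")
  out
}

#' Peri-event firing-rate matrix
#'
#' Rates of every unit in `window_s`-second windows around each event peak,
#' binned at `bin_s` (defaults reproduce a -50 to +50 s window in 10 s bins,
#' the layout used for population heatmaps, with time 0 at peak pressure).
#'
#' @param trains list of [spike_train()] objects.
#' @param events a `uro_events` data frame or numeric vector of peak times.
#' @param window_s half-width of the peri-event window, seconds.
#' @param bin_s bin width, seconds.
#' @return Matrix units x bins of rates averaged across events, with
#'   attributes `bin_edges_s` (relative to the peak) and `per_event`, the
#'   units x bins x events array it was averaged from. Overlapping peri-event
#'   windows (events closer than `2 * window_s`) are flagged with a warning
#'   but still computed.
#' @export
peri_event_matrix <- function(trains, events, window_s = 50, bin_s = 10) {
  peaks <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  stopifnot(length(peaks) > 0, length(trains) > 0)
  if (length(peaks) > 1 && any(diff(peaks) < 2 * window_s))
    warning("peri-event windows overlap (events closer than 2 * window_s)")
  n_bins <- floor(2 * window_s / bin_s + 1e-9)
  ids <- vapply(seq_along(trains), function(i) {
    id <- trains[[i]]$unit_id
    if (is.null(id)) sprintf("unit%02d", i) else as.character(id)
  }, character(1))
  per_event <- array(0, dim = c(length(trains), n_bins, length(peaks)),
                     dimnames = list(ids, NULL, NULL))
  for (ei in seq_along(peaks)) {
    for (ui in seq_along(trains)) {
      rs <- bin_rate(trains[[ui]], bin_s, peaks[ei] + c(-window_s, window_s))
      per_event[ui, , ei] <- rs$rates_hz
    }
  }
  m <- apply(per_event, c(1, 2), mean)
  attr(m, "bin_edges_s") <- seq(-window_s, window_s, by = bin_s)
  attr(m, "per_event") <- per_event
  m
}

#' Paired pre/post micturition rate comparison
#'
#' For each unit, the pre-micturition rate is the mean rate in
#' `[peak - 50, peak - 40)` and the post-micturition rate the mean rate in
#' `[peak, peak + 10)`, averaged over cycles; the two are compared with a
#' paired Student's t-test on the per-unit differences (n - 1 degrees of
#' freedom).
#'
#' @param trains list of [spike_train()] objects (at least 2).
#' @param events a `uro_events` data frame or numeric vector of peak times.
#' @param pre_window,post_window windows relative to the peak, seconds.
#' @return List with `per_unit` (data frame `unit_id`, `pre_hz`, `post_hz`),
#'   `t`, `df`, `p`. If every per-unit difference is zero the t statistic is
#'   degenerate; `t = 0`, `p = 1` are returned with a warning.
#' @export
pre_post_comparison <- function(trains, events, pre_window = c(-50, -40),
                                post_window = c(0, 10)) {
  peaks <- if (is.data.frame(events)) events$peak_time_s else as.numeric(events)
  stopifnot(length(trains) >= 2, length(peaks) >= 1)
  mean_rate <- function(times, win) {
    r <- vapply(peaks, function(pk) {
      sum(in_window(times, pk + win[1], pk + win[2])) / diff(win)
    }, numeric(1))
    mean(r)
  }
  pre <- vapply(trains, function(tr) mean_rate(tr$times_s, pre_window), numeric(1))
  post <- vapply(trains, function(tr) mean_rate(tr$times_s, post_window), numeric(1))
  ids <- vapply(trains, function(tr) as.character(tr$unit_id), character(1))
  d <- post - pre
  if (all(d == 0)) {
    warning("all per-unit pre/post differences are zero; t statistic degenerate")
    tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
  }
  list(per_unit = data.frame(unit_id = ids, pre_hz = pre, post_hz = post),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
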