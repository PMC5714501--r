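# Activation-latency estimation for LC units and the latency histogram.

#' Estimate the activation-onset latency before one event
#'
#' Scans the z-scored 1 s-binned rate within `[peak - search_back_s, peak]`
#' for runs of at least `k_consec` consecutive bins with `z >= z_thresh`. A
#' run qualifies when it persists to within `persist_tol_s` of the peak (its
#' last bin ends no more than `persist_tol_s` before the peak); the onset is
#' the start of the earliest qualifying run and the latency is
#' `peak - onset`. The thresholds are declared, configurable conventions --
#' "significant activation" has no standard operational definition.
#'
#' @param zrate a `zrate_series` from [zscore_rate()] (1 s bins recommended).
#' @param event_time peak-pressure time, seconds.
#' @param z_thresh z-score threshold (default 2).
#' @param k_consec minimum run length in bins (default 3).
#' @param search_back_s length of the backward search window (default 70 s,
#'   covering the 0--65 s range of observed latencies).
#' @param persist_tol_s persistence tolerance, seconds (default 5).
#' @return One-row data frame (`onset_s`, `latency_s`) or `NULL` when no
#'   qualifying run exists.
#' @export
activation_latency <- function(zrate, event_time, z_thresh = 2, k_consec = 3,
                               search_back_s = 70, persist_tol_s = 5) {
  stopifnot(inherits(zrate, "zrate_series"))
  w <- zrate$bin_width_s
  starts <- zrate$bin_starts_s
  sel <- which(starts >= event_time - search_back_s - 1e-9 &
                 starts + w <= event_time + 1e-9)
  if (!length(sel)) return(NULL)
  hot <- zrate$z[sel] >= z_thresh
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < k_consec) next
    run_end <- starts[sel[ends[k]]] + w
    if (run_end >= event_time - persist_tol_s - 1e-9) {
      onset <- starts[sel[begins[k]]]
      return(data.frame(onset_s = onset, latency_s = event_time - onset))
    }
  }
  NULL
}

#' Activation latencies of a set of units across cycles
#'
#' Convenience wrapper: for each unit, rates are binned at `bin_s` over the
#' whole session, z-scored against the pooled intermicturition windows of
#' `cycles`, and [activation_latency()] is applied per cycle.
#'
#' @param trains list of [spike_train()] objects.
#' @param cycles a `uro_cycles` data frame (already excluding any cycles that
#'   should not contribute, e.g. the first).
#' @param session_bounds numeric length-2 recording bounds.
#' @param bin_s bin width, seconds (default 1).
#' @param ... passed to [activation_latency()].
#' @return Data frame `unit_id`, `cycle`, `onset_s`, `latency_s`, one row per
#'   unit-cycle with a detected onset.
#' @export
lc_latency_table <- function(trains, cycles, session_bounds, bin_s = 1, ...) {
  stopifnot(nrow(cycles) >= 1)
  bg <- cycles[!is.na(cycles$inter_start), c("inter_start", "inter_end")]
  if (!nrow(bg)) stop("no intermicturition background windows available", call. = FALSE)
  out <- list()
  for (tr in trains) {
    rs <- bin_rate(tr, bin_s, session_bounds)
    zr <- tryCatch(zscore_rate(rs, bg),
                   uro_degenerate_background = function(e) NULL)
    if (is.null(zr)) next
    for (ci in seq_len(nrow(cycles))) {
      est <- activation_latency(zr, cycles$peak_time_s[ci], ...)
      if (is.null(est)) next
      out[[length(out) + 1L]] <- data.frame(unit_id = as.character(tr$unit_id),
                                            cycle = cycles$cycle[ci],
                                            onset_s = est$onset_s,
                                            latency_s = est$latency_s)
    }
  }
  if (!length(out)) {
    return(data.frame(unit_id = character(0), cycle = integer(0),
                      onset_s = numeric(0), latency_s = numeric(0)))
  }
  do.call(rbind, out)
}

#' Histogram of activation latencies
#'
#' @param latencies_s numeric vector of latencies (or the data frame returned
#'   by [lc_latency_table()]).
#' @param bin_s histogram bin width, seconds.
#' @return List with `breaks_s`, `counts`, `n`; counts sum to the number of
#'   latencies.
#' @export
latency_histogram <- function(latencies_s, bin_s = 5) {
  if (is.data.frame(latencies_s)) latencies_s <- latencies_s$latency_s
  stopifnot(bin_s > 0, all(latencies_s >= 0))
  if (!length(latencies_s)) {
    return(list(breaks_s = numeric(0), counts = integer(0), n = 0L))
  }
  n_bins <- max(1L, ceiling(max(latencies_s) / bin_s + 1e-9))
  idx <- pmin(floor(latencies_s / bin_s), n_bins - 1L)  # right edge closes last bin
  list(breaks_s = bin_s * (0:n_bins),
       counts = tabulate(idx + 1L, nbins = n_bins),
       n = length(latencies_s))
}
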