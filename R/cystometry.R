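# Cystometry: micturition-event detection and phase-window segmentation.

#' Detect micturition events from a bladder-pressure trace
#'
#' A micturition event is a supra-threshold pressure excursion that is
#' followed, within `max_void_s`, by a return of pressure to baseline (the
#' void). Each maximal run of samples above `min_peak_mmHg` contributes one
#' candidate whose peak time is the argmax of that rise; candidates whose
#' pressure never returns to `baseline_mmHg` within `max_void_s` after the
#' peak are discarded. Detection is deterministic: re-running on the same
#' trace yields identical events.
#'
#' @param trace a [pressure_trace()].
#' @param min_peak_mmHg peak threshold; default half the trace's global
#'   maximum (the study defines micturition qualitatively, so the threshold
#'   is an operational, configurable convention).
#' @param baseline_mmHg pressure at or below which the bladder counts as
#'   empty.
#' @param max_void_s maximum allowed time from peak to baseline return.
#' @return A `uro_events` data frame: `peak_time_s`, `peak_pressure_mmHg`,
#'   `void_end_time_s`. Zero rows when no sample exceeds the threshold.
#' @export
detect_micturition_events <- function(trace, min_peak_mmHg = NULL,
                                      baseline_mmHg = 2, max_void_s = 30) {
  stopifnot(inherits(trace, "pressure_trace"), length(trace$pressure) > 0)
  p <- trace$pressure
  t <- trace_times(trace)
  if (is.null(min_peak_mmHg)) min_peak_mmHg <- max(p) / 2
  empty <- data.frame(peak_time_s = numeric(0), peak_pressure_mmHg = numeric(0),
                      void_end_time_s = numeric(0))
  above <- p > min_peak_mmHg
  if (!any(above)) return(structure(empty, class = c("uro_events", "data.frame")))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    ipk <- seg[which.max(p[seg])]
    after <- which(t > t[ipk] & t <= t[ipk] + max_void_s & p <= baseline_mmHg)
    if (!length(after)) next
    out <- rbind(out, data.frame(peak_time_s = t[ipk],
                                 peak_pressure_mmHg = p[ipk],
                                 void_end_time_s = t[after[1]]))
  }
  out <- out[order(out$peak_time_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("uro_events", "data.frame"))
}

#' Segment micturition cycles into phase windows
#'
#' For each detected event, derives the half-open phase windows used by all
#' downstream statistics: a pre-micturition window of `pre_s` seconds ending
#' at the peak, a post-micturition window of `post_s` seconds starting at the
#' peak, and an intermicturition window running from `inter_margin_s` after
#' the previous peak to `inter_margin_s` before the current one. The first
#' event has no intermicturition window; windows are clipped to the session
#' bounds, and an intermicturition window whose bounds cross is recorded as
#' empty (`NA`).
#'
#' @param events a `uro_events` data frame (sorted by peak time).
#' @param session_bounds numeric length-2, start and end of the recording.
#' @param pre_s,post_s pre/post window lengths, seconds (default 20).
#' @param inter_margin_s margin defining the intermicturition window (default
#'   120 s).
#' @return A `uro_cycles` data frame with one row per event: window bounds
#'   `pre_start`, `pre_end`, `post_start`, `post_end`, `inter_start`,
#'   `inter_end` plus the event columns.
#' @export
segment_cycles <- function(events, session_bounds, pre_s = 20, post_s = 20,
                           inter_margin_s = 120) {
  stopifnot(is.data.frame(events), length(session_bounds) == 2L)
  pk <- events$peak_time_s
  stopifnot(!is.unsorted(pk))
  prev <- c(NA_real_, pk[-length(pk)])
  inter_start <- prev + inter_margin_s
  inter_end <- pk - inter_margin_s
  bad <- is.na(prev) | inter_start >= inter_end
  inter_start[bad] <- NA_real_
  inter_end[bad] <- NA_real_
  cyc <- data.frame(
    cycle = seq_along(pk),
    peak_time_s = pk,
    peak_pressure_mmHg = events$peak_pressure_mmHg,
    void_end_time_s = events$void_end_time_s,
    pre_start = pmax(session_bounds[1], pk - pre_s),
    pre_end = pk,
    post_start = pk,
    post_end = pmin(session_bounds[2], pk + post_s),
    inter_start = pmax(session_bounds[1], inter_start),
    inter_end = pmin(session_bounds[2], inter_end)
  )
  structure(cyc, class = c("uro_cycles", "data.frame"))
}

#' Assign micturition-cycle phase labels to time points
#'
#' Membership is tested against half-open windows `[start, end)`. Times in no
#' window are labelled `"unclassified"`; should windows ever be configured to
#' overlap, `pre` takes precedence, then `post`, then `inter`.
#'
#' @param t numeric vector of times, seconds.
#' @param cycles a `uro_cycles` data frame from [segment_cycles()].
#' @return Character vector: `"pre"`, `"post"`, `"inter"` or
#'   `"unclassified"`.
#' @export
assign_phase <- function(t, cycles) {
  out <- rep("unclassified", length(t))
  hit <- function(t, a, b) {
    m <- rep(FALSE, length(t))
    for (k in seq_along(a)) {
      if (is.na(a[k]) || is.na(b[k])) next
      m <- m | in_window(t, a[k], b[k])
    }
    m
  }
  out[hit(t, cycles$inter_start, cycles$inter_end)] <- "inter"
  out[hit(t, cycles$post_start, cycles$post_end)] <- "post"
  out[hit(t, cycles$pre_start, cycles$pre_end)] <- "pre"
  out
}

#' Drop the first micturition cycle
#'
#' Cystometry cycles typically regularise only after the first void, so
#' summary statistics exclude the first cycle by default.
#'
#' @param cycles a `uro_cycles` data frame.
#' @return The same data frame without its first row (unchanged if fewer than
#'   two cycles).
#' @export
drop_first_cycle <- function(cycles) {
  if (nrow(cycles) < 2) return(cycles)
  structure(cycles[-1, , drop = FALSE], class = class(cycles))
}
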