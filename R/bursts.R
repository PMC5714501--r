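# ISI-criterion burst detection and per-phase (Table-1-style) summaries.

#' Burst-detection parameters
#'
#' The interspike-interval criteria: a burst begins at an ISI of at most
#' `onset_max_isi_ms` (80 ms), continues while ISIs stay strictly below
#' `within_max_isi_ms` (160 ms), and is retained only when it contains at
#' least `min_spikes` spikes ("more than 4", i.e. >= 5).
#'
#' @param onset_max_isi_ms maximum ISI opening a burst (default 80).
#' @param within_max_isi_ms ISI at which a burst closes (default 160; an ISI
#'   exactly equal to this terminates the burst).
#' @param min_spikes minimum spike count per burst (default 5).
#' @return A `burst_params` list.
#' @export
burst_params <- function(onset_max_isi_ms = 80, within_max_isi_ms = 160,
                         min_spikes = 5L) {
  stopifnot(onset_max_isi_ms <= within_max_isi_ms, min_spikes >= 2)
  structure(list(onset_max_isi_ms = onset_max_isi_ms,
                 within_max_isi_ms = within_max_isi_ms,
                 min_spikes = as.integer(min_spikes)),
            class = "burst_params")
}

#' Detect bursts in a spike train
#'
#' Greedy left-to-right scan: a burst opens at spike *i* when the ISI to the
#' next spike is at most 80 ms; it extends while subsequent ISIs are strictly
#' below 160 ms and closes at the first ISI at or above 160 ms; it is kept
#' only when it contains more than 4 spikes. Scanning resumes after the
#' closing spike, so bursts never overlap or share spikes. The 80 ms rule
#' applies to the first ISI only; continuation uses the 160 ms rule.
#'
#' @param train a [spike_train()] or sorted numeric vector of spike times.
#' @param params a [burst_params()].
#' @param unit_id label attached to the output rows (taken from the train if
#'   available).
#' @return Data frame with one row per burst: `unit_id`, `onset_s`,
#'   `n_spikes`, `duration_ms` (last minus first spike), `mean_isi_ms`,
#'   `intra_freq_hz` (`(n_spikes - 1) / duration`).
#' @export
detect_bursts <- function(train, params = burst_params(), unit_id = NULL) {
  if (inherits(train, "spike_train")) {
    unit_id <- unit_id %||% as.character(train$unit_id)
    times <- train$times_s
  } else {
    times <- as.numeric(train)
  }
  unit_id <- unit_id %||% NA_character_
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  empty <- data.frame(unit_id = character(0), onset_s = numeric(0),
                      n_spikes = integer(0), duration_ms = numeric(0),
                      mean_isi_ms = numeric(0), intra_freq_hz = numeric(0))
  n <- length(times)
  if (n < 2) return(empty)
  isi <- diff(times) * 1000  # ms
  # 1e-6 ms guard: ISIs within numerical noise of a boundary are treated as
  # exactly on it (<= 80 opens, == 160 closes)
  onset_ok <- isi <= params$onset_max_isi_ms + 1e-6
  within_ok <- isi < params$within_max_isi_ms - 1e-6
  rows <- list()
  i <- 1L
  while (i <= n - 1L) {
    if (!onset_ok[i]) { i <- i + 1L; next }
    j <- i + 1L  # isi index; burst currently spans spikes i..j
    while (j <= n - 1L && within_ok[j]) j <- j + 1L
    first <- i
    last <- j  # spikes first..last form the candidate burst
    cnt <- last - first + 1L
    if (cnt >= params$min_spikes) {
      dur_ms <- (times[last] - times[first]) * 1000
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = unit_id, onset_s = times[first], n_spikes = cnt,
        duration_ms = dur_ms, mean_isi_ms = dur_ms / (cnt - 1L),
        intra_freq_hz = (cnt - 1L) / (dur_ms / 1000))
    }
    i <- last + 1L  # resume after the closing spike
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label bursts with micturition-cycle phases
#'
#' Phase membership is decided by the burst onset time via [assign_phase()];
#' bursts whose onset falls in no window are labelled `"unclassified"` (and
#' are excluded from per-phase summaries). A burst spanning a window edge is
#' assigned by its onset.
#'
#' @param bursts data frame from [detect_bursts()].
#' @param cycles a `uro_cycles` data frame.
#' @return `bursts` with an added `phase` column.
#' @export
label_burst_phases <- function(bursts, cycles) {
  bursts$phase <- if (nrow(bursts)) assign_phase(bursts$onset_s, cycles) else character(0)
  bursts
}

#' Per-phase burst summary (Table-1 style)
#'
#' For each phase, the burst count per cell per cycle is the number of bursts
#' whose onset falls in that phase divided by `n_units` times the number of
#' cycles possessing that phase window; spike-count, ISI, duration and
#' intra-burst-frequency statistics are per-burst means with their standard
#' errors across bursts.
#'
#' @param bursts labelled bursts from [label_burst_phases()].
#' @param cycles the `uro_cycles` data frame the labels came from.
#' @param n_units number of units contributing to `bursts`.
#' @return Data frame with one row per phase (`pre`, `inter`, `post`):
#'   `n_bursts`, `bursts_per_cell_per_cycle`, mean and SEM of `n_spikes`,
#'   `mean_isi_ms`, `duration_ms`, `intra_freq_hz`. Phases without bursts
#'   report a zero count and `NA` statistics.
#' @export
summarize_bursts <- function(bursts, cycles, n_units) {
  stopifnot(n_units >= 1)
  phases <- c("pre", "inter", "post")
  n_cycles_with <- c(pre = nrow(cycles), inter = sum(!is.na(cycles$inter_start)),
                     post = nrow(cycles))
  rows <- lapply(phases, function(ph) {
    b <- bursts[!is.na(bursts$phase) & bursts$phase == ph, , drop = FALSE]
    denom <- n_units * n_cycles_with[[ph]]
    stat <- function(x, f) if (nrow(b)) f(x) else NA_real_
    data.frame(
      phase = ph,
      n_bursts = nrow(b),
      bursts_per_cell_per_cycle = if (denom > 0) nrow(b) / denom else NA_real_,
      n_spikes_mean = stat(b$n_spikes, mean),
      n_spikes_sem = stat(b$n_spikes, sem),
      isi_ms_mean = stat(b$mean_isi_ms, mean),
      isi_ms_sem = stat(b$mean_isi_ms, sem),
      duration_ms_mean = stat(b$duration_ms, mean),
      duration_ms_sem = stat(b$duration_ms, sem),
      intra_freq_hz_mean = stat(b$intra_freq_hz, mean),
      intra_freq_hz_sem = stat(b$intra_freq_hz, sem))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
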