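# Synthetic-session generators: pressure, PMC/LC spike trains, LFP pair.

#' Generate a synthetic bladder-pressure trace
#'
#' Piecewise cystometrogram: near-zero baseline, a monotone linear rise over
#' `pre_rise_duration_s` to `peak_pressure_mmHg` at each planted event time,
#' and a linear fall back to baseline over `void_fall_duration_s`. Optional
#' small triangular transients (amplitude `post_transient_mmHg`, 2 s wide) can
#' be tied to post-void burst times. Gaussian noise of sd `0.1 * noise_sd`
#' mm Hg is added, so `noise_sd = 0` gives the exact piecewise trace.
#'
#' @param config a [session_config()].
#' @param event_times strictly increasing peak times, seconds.
#' @param duration_s total trace duration; defaults to the session layout.
#' @param transient_times times of post-void transients (may be empty).
#' @param seed optional seed; set it when calling outside [gen_session()].
#' @return A `pressure_trace`: list with `start_time_s`, `fs_hz`, `pressure`.
#' @export
gen_pressure <- function(config, event_times, duration_s = session_duration(config),
                         transient_times = numeric(0), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (length(event_times)) {
    stopifnot(all(diff(event_times) > 0),
              all(event_times >= 0), all(event_times <= duration_s))
    gaps <- diff(c(0, event_times))
    if (any(gaps < config$pre_rise_duration_s) ||
        (length(event_times) > 1 &&
         any(diff(event_times) < config$pre_rise_duration_s + config$void_fall_duration_s)))
      stop("event spacing shorter than rise + fall durations", call. = FALSE)
  }
  fs <- config$pressure_fs_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  p <- numeric(n)
  for (e in event_times) {
    rise <- in_window(t, e - config$pre_rise_duration_s, e) | t == e
    p[rise] <- config$peak_pressure_mmHg *
      (t[rise] - (e - config$pre_rise_duration_s)) / config$pre_rise_duration_s
    fall <- t > e & t <= e + config$void_fall_duration_s
    p[fall] <- config$peak_pressure_mmHg *
      (1 - (t[fall] - e) / config$void_fall_duration_s)
  }
  for (tt in transient_times) {
    w <- abs(t - tt) <= 1
    p[w] <- p[w] + config$post_transient_mmHg * (1 - abs(t[w] - tt))
  }
  if (config$noise_sd > 0) p <- p + stats::rnorm(n, 0, 0.1 * config$noise_sd)
  pressure_trace(p, fs)
}

#' Construct a pressure trace object
#'
#' @param pressure numeric vector of pressures, mm Hg.
#' @param fs_hz sampling rate.
#' @param start_time_s time of the first sample.
#' @return A `pressure_trace`.
#' @export
pressure_trace <- function(pressure, fs_hz, start_time_s = 0) {
  stopifnot(fs_hz > 0, all(is.finite(pressure)))
  structure(list(start_time_s = start_time_s, fs_hz = fs_hz,
                 pressure = as.numeric(pressure)),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples @ %g Hz (%.1f s), max %.1f mm Hg\n",
              length(x$pressure), x$fs_hz, length(x$pressure) / x$fs_hz,
              max(x$pressure)))
  invisible(x)
}

trace_times <- function(trace) {
  trace$start_time_s + (seq_along(trace$pressure) - 1) / trace$fs_hz
}

#' Construct a spike train object
#'
#' @param times_s strictly increasing, non-negative spike times.
#' @param unit_id unit identifier.
#' @param region region label, one of `"PMC"`, `"LC"`.
#' @return A `spike_train`.
#' @export
spike_train <- function(times_s, unit_id, region) {
  times_s <- as.numeric(times_s)
  stopifnot(!is.unsorted(times_s, strictly = TRUE), all(times_s >= 0),
            region %in% c("PMC", "LC"))
  structure(list(unit_id = unit_id, region = region, times_s = times_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s unit %s: %d spikes", x$region,
              as.character(x$unit_id), length(x$times_s)))
  if (length(x$times_s)) cat(sprintf(" over %.1f s", max(x$times_s)))
  cat("\n")
  invisible(x)
}

# Homogeneous Poisson spike times on [t0, t1).
rpoisson_train <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# One planted burst: n near-regular spikes spanning `dur` seconds from onset.
# ISI jitter is uniform +/-10% of the mean ISI and ISIs are rescaled to span
# the drawn duration exactly, so intra-burst frequency stays well defined and
# the largest possible ISI is bounded well below the 160 ms continuation rule.
burst_spikes <- function(onset, freq, dur, min_spikes) {
  n <- max(min_spikes, round(freq * dur) + 1L)
  isi <- rep(dur / (n - 1), n - 1) * stats::runif(n - 1, 0.9, 1.1)
  isi <- isi * dur / sum(isi)
  onset + cumsum(c(0, isi))
}

# Phase windows used by the generator for planting bursts; these mirror the
# analysis definitions in segment_cycles().
gen_phase_window <- function(phase, e, prev_e, inter_margin = 120, pre_s = 20, post_s = 20) {
  switch(phase,
    pre   = c(e - pre_s, e),
    post  = c(e, e + post_s),
    inter = if (is.na(prev_e) || (e - inter_margin) <= (prev_e + inter_margin)) NULL
            else c(prev_e + inter_margin, e - inter_margin),
    stop("unknown phase"))
}

#' Generate one synthetic PMC spike train
#'
#' Inhomogeneous point process: tonic Poisson discharge at `pmc_tonic_hz`,
#' elevated to `pmc_void_hz` from each pressure peak until the bladder is
#' empty, plus structured high-frequency bursts planted per phase. Burst
#' counts per phase and cycle are Poisson; per burst, intra-burst frequency
#' and duration are drawn from truncated normals and spikes are emitted with
#' near-regular jittered ISIs. Burst onsets are uniform within the phase
#' window, with a 300 ms separation margin between planted bursts so each
#' remains individually detectable.
#'
#' @inheritParams gen_pressure
#' @param unit_id identifier for the generated unit.
#' @return List with `train` (a [spike_train()]) and `planted`, a data frame
#'   of ground-truth bursts (`onset_s`, `n_spikes`, `duration_ms`,
#'   `intra_freq_hz`, `phase`).
#' @export
gen_pmc_train <- function(config, event_times, unit_id = "pmc1",
                          duration_s = session_duration(config), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  spikes <- rpoisson_train(config$pmc_tonic_hz, 0, duration_s)
  extra <- config$pmc_void_hz - config$pmc_tonic_hz
  for (e in event_times)
    spikes <- c(spikes, rpoisson_train(extra, e, min(e + config$void_fall_duration_s, duration_s)))

  planted <- list()
  for (ci in seq_along(event_times)) {
    e <- event_times[ci]
    prev_e <- if (ci > 1) event_times[ci - 1] else NA_real_
    for (phase in c("pre", "inter", "post")) {
      pp <- config$burst_phase_params[[phase]]
      win <- gen_phase_window(phase, e, prev_e)
      if (is.null(win) || pp$bursts_per_cycle_mean <= 0) next
      nb <- stats::rpois(1L, pp$bursts_per_cycle_mean)
      if (nb == 0) next
      placed <- matrix(numeric(0), ncol = 2)  # occupied [onset, end] intervals
      for (b in seq_len(nb)) {
        freq <- max(5, stats::rnorm(1, pp$intra_burst_freq_hz_mean, pp$intra_burst_freq_hz_sd))
        dur <- max(0.05, stats::rnorm(1, pp$duration_ms_mean, pp$duration_ms_sd) / 1000)
        onset <- NA_real_
        for (try in 1:100) {
          cand <- stats::runif(1, win[1], win[2])
          if (!nrow(placed) ||
              all(cand > placed[, 2] + 0.3 | cand + dur < placed[, 1] - 0.3)) {
            onset <- cand
            break
          }
        }
        if (is.na(onset) || onset + dur > duration_s) next
        placed <- rbind(placed, c(onset, onset + dur))
        st <- burst_spikes(onset, freq, dur, pp$min_spikes)
        spikes <- c(spikes, st)
        planted[[length(planted) + 1L]] <- data.frame(
          unit_id = unit_id, cycle = ci, onset_s = onset,
          n_spikes = length(st), duration_ms = 1000 * (max(st) - min(st)),
          intra_freq_hz = (length(st) - 1) / (max(st) - min(st)),
          phase = phase, stringsAsFactors = FALSE)
      }
    }
  }
  spikes <- sort(spikes)
  spikes <- spikes[c(TRUE, diff(spikes) > 1e-9)]  # drop exact collisions
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(unit_id = character(0), cycle = integer(0), onset_s = numeric(0),
               n_spikes = integer(0), duration_ms = numeric(0),
               intra_freq_hz = numeric(0), phase = character(0))
  list(train = spike_train(spikes, unit_id, "PMC"), planted = planted)
}

#' Generate one synthetic LC spike train
#'
#' Poisson discharge at a per-unit baseline rate drawn from
#' `lc_baseline_hz_range`, stepping to `lc_activation_hz` over
#' `[event - L, event]` in each cycle with latency `L` drawn uniformly from
#' `lc_latency_s_range`, and returning to baseline at the event (peak
#' pressure) time.
#'
#' @inheritParams gen_pmc_train
#' @return List with `train` (a [spike_train()]), `onsets` data frame
#'   (`unit_id`, `cycle`, `onset_s`, `latency_s`), and `baseline_hz`.
#' @export
gen_lc_train <- function(config, event_times, unit_id = "lc1",
                         duration_s = session_duration(config), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  baseline <- stats::runif(1, config$lc_baseline_hz_range[1], config$lc_baseline_hz_range[2])
  if (duration_s <= 0) {
    return(list(train = spike_train(numeric(0), unit_id, "LC"),
                onsets = data.frame(unit_id = character(0), cycle = integer(0),
                                    onset_s = numeric(0), latency_s = numeric(0)),
                baseline_hz = baseline))
  }
  lat <- stats::runif(length(event_times), config$lc_latency_s_range[1],
                      config$lc_latency_s_range[2])
  onset <- pmax(0, event_times - lat)
  spikes <- rpoisson_train(baseline, 0, duration_s)
  extra <- config$lc_activation_hz - baseline
  for (ci in seq_along(event_times))
    spikes <- c(spikes, rpoisson_train(extra, onset[ci], min(event_times[ci], duration_s)))
  spikes <- sort(spikes)
  spikes <- spikes[c(TRUE, diff(spikes) > 1e-9)]
  onsets <- data.frame(unit_id = rep(unit_id, length(event_times)),
                       cycle = seq_along(event_times),
                       onset_s = onset, latency_s = event_times - onset)
  list(train = spike_train(spikes, unit_id, "LC"), onsets = onsets,
       baseline_hz = baseline)
}

#' Construct a labelled field-potential signal
#'
#' @param samples numeric sample vector.
#' @param fs_hz sampling rate.
#' @param region region label, one of `"LC"`, `"mPFC"`.
#' @param band recorded frequency band, Hz.
#' @return A `labeled_signal`.
#' @export
labeled_signal <- function(samples, fs_hz, region, band = c(1, 150)) {
  stopifnot(fs_hz > 0, all(is.finite(samples)), region %in% c("LC", "mPFC"))
  structure(list(region = region, fs_hz = fs_hz, samples = as.numeric(samples),
                 band = band), class = "labeled_signal")
}

#' @export
print.labeled_signal <- function(x, ...) {
  cat(sprintf("<labeled_signal> %s: %d samples @ %g Hz (%.1f s), band %g-%g Hz\n",
              x$region, length(x$samples), x$fs_hz,
              length(x$samples) / x$fs_hz, x$band[1], x$band[2]))
  invisible(x)
}

# Band-limited spectrally shaped Gaussian noise, scaled to unit sd.
# exponent 0 -> white within the band; -0.5 -> 1/f power (pink).
shaped_noise <- function(n, fs, band = c(1, 150), exponent = -0.5) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  gain <- ifelse(f >= band[1] & f <= min(band[2], fs / 2), pmax(f, band[1])^exponent, 0)
  y <- Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Generate the synthetic LC/mPFC field-potential pair
#'
#' The LC signal is band-limited (1--150 Hz) pink noise plus a slow 1--4 Hz
#' oscillatory component at baseline; within each theta epoch
#' `[event - theta_epoch_s, event]` the slow component is replaced by a
#' sinusoid at `theta_freq_hz` with a random per-epoch phase. The mPFC signal
#' is independent pink noise whose amplitude is multiplied by
#' `mpfc_desync_gain` during theta epochs, plus `coupled_theta_gain` times the
#' identical theta sinusoid -- the shared component that yields LC--mPFC
#' coherence confined to the theta band.
#'
#' @inheritParams gen_pressure
#' @return List with elements `lc` and `mpfc` ([labeled_signal()]s) and
#'   `theta_epochs`, a two-column matrix of epoch start/end times.
#' @export
gen_lfp_pair <- function(config, event_times, duration_s = session_duration(config),
                         seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (config$theta_freq_hz >= config$lfp_fs_hz / 2)
    stop("theta_freq_hz at or above Nyquist", call. = FALSE)
  fs <- config$lfp_fs_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sdv <- config$noise_sd

  lc_noise <- sdv * shaped_noise(n, fs)
  slow <- sdv * shaped_noise(n, fs, band = c(1, 4), exponent = 0)
  mp_noise <- sdv * shaped_noise(n, fs)

  epochs <- cbind(start = pmax(0, event_times - config$theta_epoch_s),
                  end = pmin(event_times, duration_s))
  in_epoch <- rep(FALSE, n)
  theta <- numeric(n)
  for (k in seq_len(nrow(epochs))) {
    idx <- which(in_window(t, epochs[k, 1], epochs[k, 2]))
    if (!length(idx)) next
    in_epoch[idx] <- TRUE
    phase <- stats::runif(1, 0, 2 * pi)
    theta[idx] <- config$theta_amp * sdv *
      sin(2 * pi * config$theta_freq_hz * t[idx] + phase)
  }
  lc <- lc_noise + ifelse(in_epoch, 0, 1) * slow + theta
  mp <- mp_noise * ifelse(in_epoch, config$mpfc_desync_gain, 1) +
    config$coupled_theta_gain * theta
  list(lc = labeled_signal(lc, fs, "LC"),
       mpfc = labeled_signal(mp, fs, "mPFC"),
       theta_epochs = epochs)
}

#' Generate a complete synthetic session
#'
#' Composes [gen_pressure()], [gen_pmc_train()], [gen_lc_train()] and
#' [gen_lfp_pair()] under one seeded random stream, split into fixed per-
#' component sub-streams so that, for example, adding LC units leaves the
#' pressure trace and every PMC train unchanged. Planted event times are laid
#' out at `cycle_period_s` spacing. The result is bit-identical for a fixed
#' `config$seed`.
#'
#' @param config a [session_config()].
#' @return A `uro_session`: list with `pressure`, `trains`, `lfps`, `truth`
#'   (ground-truth events, planted bursts, LC onsets, theta epochs) and
#'   `config`.
#' @export
gen_session <- function(config) {
  validate_config(config)
  ss <- subseeds(config$seed)
  events <- event_layout(config)
  dur <- session_duration(config)

  trains <- vector("list", config$n_pmc_units + config$n_lc_units)
  planted <- list()
  onsets <- list()
  for (i in seq_len(config$n_pmc_units)) {
    g <- gen_pmc_train(config, events, unit_id = sprintf("pmc%02d", i),
                       duration_s = dur, seed = ss[subseed_slot("pmc", i)])
    trains[[i]] <- g$train
    planted[[i]] <- g$planted
  }
  for (j in seq_len(config$n_lc_units)) {
    g <- gen_lc_train(config, events, unit_id = sprintf("lc%02d", j),
                      duration_s = dur, seed = ss[subseed_slot("lc", j)])
    trains[[config$n_pmc_units + j]] <- g$train
    onsets[[j]] <- g$onsets
  }
  planted <- if (length(planted)) do.call(rbind, planted) else NULL
  onsets <- if (length(onsets)) do.call(rbind, onsets) else NULL

  transient <- numeric(0)
  if (!is.null(planted) && nrow(planted) && config$post_transient_mmHg > 0) {
    first_unit <- planted$unit_id == planted$unit_id[1]
    transient <- planted$onset_s[first_unit & planted$phase == "post"]
  }
  pressure <- gen_pressure(config, events, duration_s = dur,
                           transient_times = transient,
                           seed = ss[subseed_slot("pressure")])
  lfp <- gen_lfp_pair(config, events, duration_s = dur,
                      seed = ss[subseed_slot("lfp")])

  structure(list(
    pressure = pressure,
    trains = trains,
    lfps = list(LC = lfp$lc, mPFC = lfp$mpfc),
    truth = list(event_times_s = events, planted_bursts = planted,
                 lc_onsets = onsets, theta_epochs = lfp$theta_epochs),
    config = config
  ), class = "uro_session")
}

#' @export
print.uro_session <- function(x, ...) {
  reg <- vapply(x$trains, function(tr) tr$region, character(1))
  cat(sprintf("<uro_session> %.0f s, %d planted voids; %d PMC + %d LC units; LFPs: %s\n",
              length(x$pressure$pressure) / x$pressure$fs_hz,
              length(x$truth$event_times_s),
              sum(reg == "PMC"), sum(reg == "LC"),
              paste(names(x$lfps), collapse = ", ")))
  invisible(x)
}

#' Extract the spike trains of one region
#'
#' @param session a `uro_session`.
#' @param region `"PMC"` or `"LC"`.
#' @return List of [spike_train()] objects.
#' @export
region_trains <- function(session, region) {
  Filter(function(tr) tr$region == region, session$trains)
}
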