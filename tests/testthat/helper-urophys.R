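# Shared fixtures and independent oracles, built in code at test time.

# A scaled-down session configuration: same cycle structure as the preset but
# few units and lower sampling rates, so unit tests stay fast.
tiny_cfg <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_cycles = 3, n_pmc_units = 2, n_lc_units = 2,
         lfp_fs_hz = 390, pressure_fs_hz = 5, seed = seed),
    list(...))
  do.call(session_config, args)
}

# Independent burst oracle: maximal runs of ISIs < within_max; one burst per
# run, starting at the first ISI <= onset_max inside it. Deliberately a
# different formulation (rle over the whole ISI vector) from the greedy
# scanner it checks.
oracle_bursts <- function(times, params = burst_params()) {
  n <- length(times)
  if (n < 2) return(data.frame(onset_s = numeric(0), n_spikes = integer(0)))
  isi <- diff(times) * 1000
  r <- rle(isi < params$within_max_isi_ms - 1e-6)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    rel <- which(isi[starts[k]:ends[k]] <= params$onset_max_isi_ms + 1e-6)
    if (!length(rel)) next
    s <- starts[k] + rel[1] - 1L
    cnt <- ends[k] + 1L - s + 1L
    if (cnt >= params$min_spikes)
      out[[length(out) + 1L]] <- data.frame(onset_s = times[s], n_spikes = cnt)
  }
  if (!length(out)) return(data.frame(onset_s = numeric(0), n_spikes = integer(0)))
  do.call(rbind, out)
}

# Random small spike train whose ISIs straddle the 80/160 ms criteria,
# including exact boundary values to exercise the tie conventions.
random_train <- function(n_spikes) {
  isis <- sample(c(0.02, 0.05, 0.08, 0.1, 0.16, 0.2, 0.5,
                   round(stats::runif(3, 0.01, 0.4), 3)),
                 n_spikes - 1, replace = TRUE)
  cumsum(c(0.5, isis))
}

# Deterministic regular-rate spike segment (for step/latency fixtures).
regular_spikes <- function(rate_hz, t0, t1) {
  if (rate_hz <= 0 || t1 <= t0) return(numeric(0))
  seq(t0, t1 - 1e-9, by = 1 / rate_hz)
}
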