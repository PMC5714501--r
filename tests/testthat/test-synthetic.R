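# Synthetic-session generator: preset values, construction invariants,
# determinism, point-process sanity.

test_that("packaged preset encodes the study's summary parameters", {
  cfg <- paper_preset()
  expect_equal(cfg$burst_phase_params$post$duration_ms_mean, 606)
  expect_equal(cfg$burst_phase_params$post$bursts_per_cycle_mean, 2.7)
  expect_equal(cfg$burst_phase_params$inter$bursts_per_cycle_mean, 12.3)
  expect_equal(cfg$burst_phase_params$inter$duration_ms_mean, 432)
  expect_equal(cfg$burst_phase_params$pre$bursts_per_cycle_mean, 0.3)
  expect_equal(mean(cfg$lc_latency_s_range), 20)
  expect_equal(cfg$theta_epoch_s, 30)
  expect_equal(cfg$n_cycles, 10L)
  expect_equal(cfg$n_pmc_units, 36L)
  expect_equal(cfg$n_lc_units, 51L)
  expect_equal(cfg$lfp_fs_hz, 780)
  expect_identical(paper_preset(seed = 3), paper_preset(seed = 3))
})

test_that("config invariants are enforced", {
  expect_error(session_config(pmc_tonic_hz = -1), "rates")
  expect_error(session_config(lfp_fs_hz = 200), "Nyquist|twice")
  expect_error(session_config(lc_latency_s_range = c(10, 400)), "latency")
  bp <- default_burst_phase_params()
  bp$post$min_spikes <- 3
  expect_error(session_config(burst_phase_params = bp), "min_spikes")
  expect_error(session_config(mpfc_desync_gain = 1.5), "desync")
})

test_that("noiseless pressure trace peaks exactly at planted events", {
  cfg <- tiny_cfg(noise_sd = 0)
  ev <- cfg$cycle_period_s * seq_len(cfg$n_cycles)
  tr <- gen_pressure(cfg, ev)
  expect_equal(max(tr$pressure), cfg$peak_pressure_mmHg)
  t <- tr$start_time_s + (seq_along(tr$pressure) - 1) / tr$fs_hz
  for (e in ev) {
    # argmax within the cycle lands on the planted event time (within one sample)
    cyc <- which(t >= e - cfg$cycle_period_s / 2 & t < e + cfg$cycle_period_s / 2)
    expect_lte(abs(t[cyc[which.max(tr$pressure[cyc])]] - e), 1 / tr$fs_hz)
    expect_equal(tr$pressure[which(t == e)], cfg$peak_pressure_mmHg)
  }
  # intermicturition pressure back at baseline
  mid <- which.min(abs(t - mean(ev[1:2])))
  expect_equal(tr$pressure[mid], 0)
})

test_that("pressure generation rejects events closer than rise + fall", {
  cfg <- tiny_cfg()
  expect_error(gen_pressure(cfg, c(100, 150)), "spacing")
})

test_that("planted PMC bursts meet the detection criteria and spikes are valid", {
  cfg <- paper_preset(seed = 5)
  ev <- cfg$cycle_period_s * seq_len(4)
  g <- gen_pmc_train(cfg, ev, duration_s = 4 * cfg$cycle_period_s + 60, seed = 99)
  expect_false(is.unsorted(g$train$times_s, strictly = TRUE))
  expect_true(all(g$train$times_s >= 0))
  expect_true(all(g$planted$n_spikes >= 5))
  # every planted burst is individually detectable: all ISIs < 80 ms
  for (i in seq_len(nrow(g$planted))) {
    b <- g$planted[i, ]
    isi_ms <- b$duration_ms / (b$n_spikes - 1)
    expect_lt(isi_ms * 1.1 + 1e-9, 80)  # even with max jitter
  }
  expect_true(all(g$planted$phase %in% c("pre", "inter", "post")))
})

test_that("zero burst rates give an empty planted list", {
  bp <- default_burst_phase_params()
  for (ph in names(bp)) bp[[ph]]$bursts_per_cycle_mean <- 0
  cfg <- tiny_cfg(burst_phase_params = bp)
  g <- gen_pmc_train(cfg, c(300, 600), duration_s = 700, seed = 1)
  expect_equal(nrow(g$planted), 0)
})

test_that("LC train with activation equal to baseline is homogeneous Poisson", {
  cfg <- tiny_cfg(lc_baseline_hz_range = c(2, 2), lc_activation_hz = 2)
  dur <- session_duration(cfg)
  g <- gen_lc_train(cfg, cfg$cycle_period_s * 1:3, duration_s = dur, seed = 21)
  rate <- length(g$train$times_s) / dur
  se <- sqrt(2 / dur)
  expect_lt(abs(rate - 2), 3 * se)
})

test_that("planted LC onsets precede their event with latencies in range", {
  cfg <- paper_preset(seed = 2)
  ev <- cfg$cycle_period_s * seq_len(50)
  g <- gen_lc_train(cfg, ev, duration_s = 50 * cfg$cycle_period_s + 60, seed = 4)
  expect_true(all(g$onsets$onset_s < ev))
  expect_true(all(g$onsets$latency_s >= cfg$lc_latency_s_range[1]))
  expect_true(all(g$onsets$latency_s <= cfg$lc_latency_s_range[2]))
  # mean planted latency approaches the 20 s midpoint
  expect_lt(abs(mean(g$onsets$latency_s) - 20), 3 * sqrt(400 / 12) / sqrt(50))
})

test_that("zero-duration session yields an empty LC train", {
  cfg <- tiny_cfg()
  g <- gen_lc_train(cfg, numeric(0), duration_s = 0, seed = 1)
  expect_length(g$train$times_s, 0)
})

test_that("LFP pair carries the planted theta structure", {
  cfg <- tiny_cfg(seed = 31)
  ev <- cfg$cycle_period_s * 1:3
  lf <- gen_lfp_pair(cfg, ev, seed = 31)
  expect_true(all(is.finite(lf$lc$samples)))
  expect_true(all(is.finite(lf$mpfc$samples)))
  expect_equal(nrow(lf$theta_epochs), 3)
  expect_true(all(lf$theta_epochs[, 2] - lf$theta_epochs[, 1] == cfg$theta_epoch_s))
  # epoch PSD peaks at the theta frequency (within the analysis bandwidth)
  seg <- lf$lc$samples[round((ev[2] - 30) * cfg$lfp_fs_hz):round(ev[2] * cfg$lfp_fs_hz)]
  est <- mt_psd(seg[1:(2 * cfg$lfp_fs_hz)], cfg$lfp_fs_hz)
  expect_lt(abs(est$freq_hz[which.max(est$power)] - cfg$theta_freq_hz), 1 + 1e-9)
})

test_that("theta frequency at or above Nyquist is rejected", {
  cfg <- tiny_cfg()
  cfg$theta_freq_hz <- 400  # >= 390/2, and above the recorded band
  expect_error(gen_lfp_pair(cfg, c(300)), "twice the highest|Nyquist")
})

test_that("sessions are deterministic and unperturbed by added units", {
  cfg <- tiny_cfg(seed = 77)
  s1 <- gen_session(cfg)
  s2 <- gen_session(cfg)
  expect_identical(s1$pressure$pressure, s2$pressure$pressure)
  expect_identical(lapply(s1$trains, `[[`, "times_s"),
                   lapply(s2$trains, `[[`, "times_s"))
  expect_identical(s1$lfps$LC$samples, s2$lfps$LC$samples)
  expect_equal(length(s1$truth$event_times_s), cfg$n_cycles)
  # adding LC units leaves existing component streams untouched
  cfg3 <- tiny_cfg(seed = 77, n_lc_units = 3)
  s3 <- gen_session(cfg3)
  expect_identical(s1$trains[[1]]$times_s, s3$trains[[1]]$times_s)
  expect_identical(s1$lfps$mPFC$samples, s3$lfps$mPFC$samples)
  expect_identical(region_trains(s1, "LC")[[1]]$times_s,
                   region_trains(s3, "LC")[[1]]$times_s)
})
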