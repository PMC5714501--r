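# ISI-criterion burst detection and per-phase summaries.

test_that("textbook burst cases follow the 80/160 ms, >4 spike criteria", {
  # 5 spikes at exactly 50 ms spacing -> one burst
  b <- detect_bursts(seq(0, by = 0.05, length.out = 5))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 5)
  expect_equal(b$duration_ms, 200)
  expect_equal(b$mean_isi_ms, 50)
  expect_equal(b$intra_freq_hz, 20)
  # 4 spikes: "> 4" fails
  expect_equal(nrow(detect_bursts(seq(0, by = 0.05, length.out = 4))), 0)
  # onset at exactly 80 ms qualifies; continuation at exactly 160 ms closes
  t5 <- cumsum(c(0, 0.08, 0.1, 0.1, 0.1))
  expect_equal(nrow(detect_bursts(t5)), 1)
  # ISI of exactly 160 ms closes the burst at 2 spikes; the 4-spike remainder
  # also fails the count criterion
  t_closed <- cumsum(c(0, 0.08, 0.16, 0.05, 0.05, 0.05))
  expect_equal(nrow(detect_bursts(t_closed)), 0)
})

test_that("a 150 ms continuation run closes at the 200 ms gap", {
  # ISIs 70, 150, 150, 150 then a 200 ms gap: burst = first 5 spikes
  times <- cumsum(c(1, 0.07, 0.15, 0.15, 0.15, 0.2, 0.07, 0.15, 0.15, 0.15))
  b <- detect_bursts(times)
  expect_equal(b$n_spikes[1], 5)
  expect_equal(b$onset_s[1], 1)
  expect_equal(b$duration_ms[1], 520)
  # scanning resumes after the closing spike: second identical burst found
  expect_equal(nrow(b), 2)
  expect_equal(b$n_spikes[2], 5)
})

test_that("unsorted spike input is rejected", {
  expect_error(detect_bursts(c(1, 0.5, 2)), "increasing")
})

test_that("greedy detector is equivalent to the run-based oracle on 1000 random trains", {
  set.seed(8)
  for (i in 1:1000) {
    times <- random_train(sample(2:50, 1))
    got <- detect_bursts(times)
    want <- oracle_bursts(times)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$onset_s, want$onset_s)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("bursts are disjoint, reconstruct the train, and respect min_spikes monotonicity", {
  set.seed(9)
  for (i in 1:50) {
    times <- random_train(sample(10:50, 1))
    b <- detect_bursts(times)
    if (nrow(b) > 1) {
      ends <- b$onset_s + b$duration_ms / 1000
      expect_true(all(b$onset_s[-1] > ends[-nrow(b)]))
    }
    # spikes inside burst intervals + spikes outside = all spikes
    inside <- rep(FALSE, length(times))
    for (j in seq_len(nrow(b)))
      inside <- inside | (times >= b$onset_s[j] - 1e-12 &
                          times <= b$onset_s[j] + b$duration_ms[j] / 1000 + 1e-12)
    expect_equal(sum(inside), sum(b$n_spikes))
    # raising min_spikes never increases the burst count
    counts <- vapply(5:8, function(ms)
      nrow(detect_bursts(times, burst_params(min_spikes = ms))), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("recall is 100% on noiseless planted-burst trains", {
  cfg <- paper_preset(seed = 10)
  cfg$pmc_tonic_hz <- 0
  cfg$pmc_void_hz <- 0
  ev <- cfg$cycle_period_s * 1:5
  g <- gen_pmc_train(cfg, ev, duration_s = 5 * cfg$cycle_period_s + 60, seed = 17)
  det <- detect_bursts(g$train)
  expect_equal(nrow(det), nrow(g$planted))
  ord <- order(g$planted$onset_s)
  expect_equal(det$onset_s, g$planted$onset_s[ord], tolerance = 1e-9)
  expect_equal(det$n_spikes, g$planted$n_spikes[ord])
})

test_that("phase labelling and Table-1-style summary are consistent", {
  ev <- data.frame(peak_time_s = c(300, 600), peak_pressure_mmHg = 30,
                   void_end_time_s = c(310, 610))
  cyc <- segment_cycles(ev, c(0, 700))
  bursts <- data.frame(unit_id = "u1", onset_s = c(305, 450, 740, 290),
                       n_spikes = c(10, 8, 6, 12),
                       duration_ms = c(400, 464, 300, 500),
                       mean_isi_ms = 40, intra_freq_hz = 25)
  lab <- label_burst_phases(bursts, cyc)
  expect_equal(lab$phase, c("post", "inter", "unclassified", "pre"))
  sm <- summarize_bursts(lab, cyc, n_units = 2)
  expect_equal(sm$n_bursts[sm$phase == "post"], 1)
  # inter denominator counts only cycles possessing an inter window
  expect_equal(sm$bursts_per_cell_per_cycle[sm$phase == "inter"], 1 / (2 * 1))
  expect_equal(sm$bursts_per_cell_per_cycle[sm$phase == "pre"], 1 / (2 * 2))
  # mean of 400 and 464 ms is 432 ms
  sm2 <- summarize_bursts(
    label_burst_phases(data.frame(unit_id = "u1", onset_s = c(430, 450),
                                  n_spikes = c(10, 12),
                                  duration_ms = c(400, 464),
                                  mean_isi_ms = 40, intra_freq_hz = 25), cyc),
    cyc, n_units = 1)
  expect_equal(sm2$duration_ms_mean[sm2$phase == "inter"], 432)
  # empty phase: zero count, absent statistics
  expect_true(is.na(sm2$duration_ms_mean[sm2$phase == "post"]))
  expect_equal(sm2$n_bursts[sm2$phase == "post"], 0)
})
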