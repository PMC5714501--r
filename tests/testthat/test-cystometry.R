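# Event detection, cycle segmentation and phase assignment.

test_that("noiseless synthetic trace yields every planted event within one sample", {
  cfg <- tiny_cfg(noise_sd = 0)
  ev <- cfg$cycle_period_s * seq_len(cfg$n_cycles)
  tr <- gen_pressure(cfg, ev)
  det <- detect_micturition_events(tr)
  expect_equal(nrow(det), length(ev))
  expect_true(all(abs(det$peak_time_s - ev) <= 1 / tr$fs_hz))
  expect_true(all(det$void_end_time_s >= det$peak_time_s))
  # idempotence
  expect_identical(det, detect_micturition_events(tr))
})

test_that("flat trace yields no events and unresolved peaks are excluded", {
  flat <- pressure_trace(rep(0, 100), 10)
  expect_equal(nrow(detect_micturition_events(flat, min_peak_mmHg = 5)), 0)
  # a peak never followed by a return to baseline is not an event
  p <- c(rep(0, 50), seq(0, 30, length.out = 50), rep(30, 200))
  stuck <- pressure_trace(p, 10)
  expect_equal(nrow(detect_micturition_events(stuck, max_void_s = 10)), 0)
})

test_that("cycle windows follow the 20 s / 120 s definitions", {
  ev <- data.frame(peak_time_s = c(300, 600), peak_pressure_mmHg = c(30, 30),
                   void_end_time_s = c(310, 610))
  cyc <- segment_cycles(ev, c(0, 700))
  expect_equal(cyc$pre_start, c(280, 580))
  expect_equal(cyc$post_end, c(320, 620))
  # first event has no intermicturition window
  expect_true(is.na(cyc$inter_start[1]))
  # events 300 s apart: inter window [t1+120, t2-120], 60 s long
  expect_equal(cyc$inter_start[2], 420)
  expect_equal(cyc$inter_end[2], 480)

  ev2 <- data.frame(peak_time_s = c(300, 500), peak_pressure_mmHg = c(30, 30),
                    void_end_time_s = c(310, 510))
  cyc2 <- segment_cycles(ev2, c(0, 600))
  expect_true(is.na(cyc2$inter_start[2]))  # 120 + 120 > 200
})

test_that("windows are clipped to session bounds and stay disjoint", {
  ev <- data.frame(peak_time_s = c(10, 310), peak_pressure_mmHg = c(30, 30),
                   void_end_time_s = c(15, 315))
  cyc <- segment_cycles(ev, c(0, 320))
  expect_equal(cyc$pre_start[1], 0)   # clipped
  expect_equal(cyc$post_end[2], 320)  # clipped
  for (i in seq_len(nrow(cyc))) {
    if (is.na(cyc$inter_start[i])) next
    expect_lte(cyc$inter_end[i], cyc$pre_start[i])
    expect_gte(cyc$inter_start[i], cyc$post_end[i - 1])
  }
})

test_that("phase labels use half-open windows with the documented boundaries", {
  ev <- data.frame(peak_time_s = 300, peak_pressure_mmHg = 30,
                   void_end_time_s = 310)
  cyc <- segment_cycles(ev, c(0, 700))
  expect_equal(assign_phase(295, cyc), "pre")
  expect_equal(assign_phase(300, cyc), "post")     # [peak, peak+20)
  expect_equal(assign_phase(320, cyc), "unclassified")  # half-open end
  expect_equal(assign_phase(280, cyc), "pre")
  expect_equal(assign_phase(279.999, cyc), "unclassified")
})

test_that("phase assignment agrees with a brute-force interval scan", {
  set.seed(42)
  ev <- data.frame(peak_time_s = sort(stats::runif(4, 200, 2000)),
                   peak_pressure_mmHg = 30, void_end_time_s = NA)
  ev$void_end_time_s <- ev$peak_time_s + 10
  cyc <- segment_cycles(ev, c(0, 2100))
  ts <- stats::runif(10000, 0, 2100)
  got <- assign_phase(ts, cyc)
  brute <- vapply(ts, function(t) {
    for (i in seq_len(nrow(cyc))) {
      if (t >= cyc$pre_start[i] && t < cyc$pre_end[i]) return("pre")
      if (t >= cyc$post_start[i] && t < cyc$post_end[i]) return("post")
      if (!is.na(cyc$inter_start[i]) &&
          t >= cyc$inter_start[i] && t < cyc$inter_end[i]) return("inter")
    }
    "unclassified"
  }, character(1))
  expect_identical(got, brute)
})
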