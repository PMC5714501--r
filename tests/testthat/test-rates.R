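# Binned rates, z-scoring, peri-event matrices, pre/post comparison.

test_that("bin_rate implements half-open 5 s bins with count conservation", {
  # 10 spikes uniformly inside one 5 s bin -> 2 Hz
  rs <- bin_rate(seq(0.25, 4.75, length.out = 10), 5, c(0, 5))
  expect_equal(rs$rates_hz, 2)
  # empty train -> all-zero rates
  rs0 <- bin_rate(numeric(0), 5, c(0, 20))
  expect_equal(rs0$rates_hz, rep(0, 4))
  # trailing partial bin dropped
  expect_length(bin_rate(numeric(0), 5, c(0, 23))$rates_hz, 4)
  # conservation on random trains
  set.seed(1)
  for (rep in 1:20) {
    sp <- sort(stats::runif(stats::rpois(1, 80), 0, 100))
    rs <- bin_rate(sp, 5, c(0, 100))
    expect_equal(sum(rs$counts), sum(sp >= 0 & sp < 100))
  }
  # boundary spikes go to the bin on their right (half-open)
  expect_equal(bin_rate(c(5), 5, c(0, 10))$counts, c(0, 1))
})

test_that("z-scoring centres and scales the background bins exactly", {
  set.seed(2)
  rs <- bin_rate(sort(stats::runif(300, 0, 300)), 5, c(0, 300))
  zr <- zscore_rate(rs, c(0, 150))
  bg <- zr$background_bins
  expect_lt(abs(mean(zr$z[bg])), 1e-9)
  expect_lt(abs(stats::sd(zr$z[bg]) - 1), 1e-9)
  # a bin exactly 2 sd above background mean has z = 2
  rs2 <- rs
  rs2$rates_hz[40] <- zr$background_mean_hz + 2 * zr$background_sd_hz
  zr2 <- zscore_rate(rs2, c(0, 150))
  expect_equal(zr2$z[40], 2, tolerance = 1e-6)
})

test_that("z-scoring is invariant to affine rescaling of the rates", {
  set.seed(3)
  rs <- bin_rate(sort(stats::runif(200, 0, 200)), 5, c(0, 200))
  zr <- zscore_rate(rs, c(0, 100))
  rs_scaled <- rs
  rs_scaled$rates_hz <- 3.7 * rs$rates_hz + 2.2
  zr_scaled <- zscore_rate(rs_scaled, c(0, 100))
  expect_equal(zr$z, zr_scaled$z, tolerance = 1e-9)
})

test_that("degenerate backgrounds are handled per the documented contract", {
  rs <- bin_rate(numeric(0), 5, c(0, 100))
  # constant series: z defined as 0 with a warning
  expect_warning(zr <- zscore_rate(rs, c(0, 100)), "constant")
  expect_true(all(zr$z == 0))
  # zero-variance background with non-constant series: error
  rs2 <- bin_rate(c(50.1, 50.2, 51, 52, 53.5), 5, c(0, 100))
  expect_error(zscore_rate(rs2, c(0, 50)), class = "uro_degenerate_background")
})

test_that("peri-event matrix places spikes and composes from bin_rate", {
  tr <- spike_train(c(101), "u1", "PMC")
  m <- peri_event_matrix(list(tr), 100)
  expect_equal(dim(m), c(1, 10))
  edges <- attr(m, "bin_edges_s")
  nz <- which(m[1, ] != 0)
  expect_equal(edges[nz], 0)  # only the [0, 10) bin is nonzero
  expect_equal(unname(m[1, nz]), 0.1)

  set.seed(4)
  trains <- lapply(1:3, function(i)
    spike_train(sort(stats::runif(200, 0, 600)), paste0("u", i), "PMC"))
  peaks <- c(200, 280)  # closer than 2 * window_s -> overlap flagged
  expect_warning(m2 <- peri_event_matrix(trains, peaks), "overlap")
  for (ui in 1:3) {
    manual <- rowMeans(vapply(peaks, function(pk)
      bin_rate(trains[[ui]], 10, pk + c(-50, 50))$rates_hz, numeric(10)))
    expect_equal(unname(m2[ui, ]), manual)
  }
})

test_that("paired pre/post t statistic matches the closed form", {
  # three fabricated units with known rates in the comparison windows
  mk <- function(pre_n, post_n, pk = 100) {
    spike_train(sort(c(seq(pk - 50, pk - 40, length.out = pre_n + 2)[2:(pre_n + 1)],
                       seq(pk, pk + 10, length.out = post_n + 2)[2:(post_n + 1)])),
                paste0("u", pre_n, post_n), "PMC")
  }
  trains <- list(mk(10, 30), mk(20, 25), mk(5, 40))
  cmp <- pre_post_comparison(trains, 100)
  d <- cmp$per_unit$post_hz - cmp$per_unit$pre_hz
  t_manual <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(cmp$t, t_manual, tolerance = 1e-12)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p, 2 * stats::pt(-abs(t_manual), 2), tolerance = 1e-12)
  # identical pre/post -> degenerate, t = 0 with warning
  same <- list(mk(10, 10), mk(20, 20))
  expect_warning(cmp0 <- pre_post_comparison(same, 100), "degenerate")
  expect_equal(cmp0$t, 0)
})
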