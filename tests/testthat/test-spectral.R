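# DPSS tapers, multitaper PSD, spectrogram, coherence.

test_that("DPSS tapers are orthonormal with high, ordered concentrations", {
  ts <- dpss_tapers(128, 2, 3)
  G <- crossprod(ts$tapers)
  expect_lt(max(abs(G - diag(3))), 1e-8)
  expect_true(all(diff(ts$concentrations) < 0))
  expect_gt(ts$concentrations[1], 0.99)
  # concentration verified independently: energy of the taper's spectrum
  # inside [-W, W], by fine zero-padded FFT quadrature
  nfft <- 2^15
  for (j in 1:3) {
    U2 <- Mod(stats::fft(c(ts$tapers[, j], rep(0, nfft - 128))))^2
    f <- (0:(nfft - 1)) / nfft
    f <- pmin(f, 1 - f)
    lam_num <- sum(U2[f <= ts$w]) / sum(U2)
    expect_equal(ts$concentrations[j], lam_num, tolerance = 1e-3)
  }
  # infeasible parameter sets are rejected
  expect_error(dpss_tapers(128, 2, 4), "k must")
  expect_error(dpss_tapers(3, 2, 3), "n must")
})

test_that("multitaper PSD finds line spectra and passes the Parseval check", {
  fs <- 100
  t <- (0:(2 * fs - 1)) / fs
  est <- mt_psd(sin(2 * pi * 6 * t), fs)
  expect_lt(abs(est$freq_hz[which.max(est$power)] - 6), 1 + 1e-9)
  expect_true(all(est$power >= 0))
  # zero signal -> zero power
  expect_true(all(mt_psd(rep(0, 200), fs)$power == 0))
  # white noise: integrated PSD approximates the variance within 10%
  set.seed(10)
  ratio <- replicate(100, {
    x <- stats::rnorm(256, sd = 2)
    est <- mt_psd(x, fs)
    df <- est$freq_hz[2] - est$freq_hz[1]
    sum(est$power) * df / stats::var(x)
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("spectrogram layout and stationarity behave as documented", {
  fs <- 100
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * t) + 0.1 * stats::rnorm(length(t))
  sg <- mt_spectrogram(x, fs, window_s = 2, overlap_s = 0.5, fmax = 20)
  # column count = floor((T - window)/step) + 1
  expect_equal(ncol(sg$power), floor((20 - 2) / 1.5) + 1)
  expect_true(all(sg$freq_hz <= 20))
  peaks <- sg$freq_hz[apply(sg$power, 2, which.max)]
  expect_true(all(abs(peaks - 6) <= 1 + 1e-9))
  expect_error(mt_spectrogram(x[1:50], fs), "shorter")
})

test_that("synthetic LC spectrogram shows theta only inside planted epochs", {
  cfg <- tiny_cfg(seed = 19)
  ev <- cfg$cycle_period_s * 1:3
  lf <- gen_lfp_pair(cfg, ev, seed = 19)
  sg <- mt_spectrogram(lf$lc, fmax = 20)
  in_epoch <- rep(FALSE, length(sg$time_s))
  for (k in seq_len(nrow(lf$theta_epochs)))
    in_epoch <- in_epoch | (sg$time_s >= lf$theta_epochs[k, 1] + 1 &
                            sg$time_s <= lf$theta_epochs[k, 2] - 1)
  peaks <- sg$freq_hz[apply(sg$power, 2, which.max)]
  theta_hit <- abs(peaks - cfg$theta_freq_hz) <= 1 + 1e-9
  expect_gt(mean(theta_hit[in_epoch]), 0.9)
  expect_lt(mean(theta_hit[!in_epoch]), 0.2)
})

test_that("coherence is bounded, scale-invariant and unity for identical signals", {
  set.seed(11)
  fs <- 100
  x <- stats::rnorm(20 * fs)
  co <- mt_coherence(x, x, fs)
  expect_true(all(abs(co$coherence - 1) < 1e-9))
  co2 <- mt_coherence(x, -2 * x, fs)
  expect_true(all(abs(co2$coherence - 1) < 1e-9))
  y <- stats::rnorm(20 * fs)
  co3 <- mt_coherence(x, y, fs)
  expect_true(all(co3$coherence >= 0 & co3$coherence <= 1))
  expect_error(mt_coherence(x, y[1:100], fs), "equal length")
})

test_that("coherence of independent noise matches the 1/(K W) estimator bias", {
  set.seed(12)
  fs <- 100
  mean_c <- replicate(10, {
    x <- stats::rnorm(20 * fs)
    y <- stats::rnorm(20 * fs)
    co <- mt_coherence(x, y, fs)
    mean(co$coherence[co$freq_hz > 2 & co$freq_hz < 48])
  })
  M <- 3 * (floor((20 - 2) / 1.5) + 1)  # tapers x windows averaged
  expect_gt(mean(mean_c), 0.5 / M)
  expect_lt(mean(mean_c), 2 / M)
})
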