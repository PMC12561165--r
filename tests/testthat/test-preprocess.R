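# Wavelet machinery, thresholds, baseline removal, Pan-Tompkins detection
# and beat segmentation.

test_that("wavelet decomposition reconstructs the input exactly", {
  withr::with_seed(1, x <- sin(seq(0, 30, length.out = 997)) + rnorm(997, 0, 0.2))
  dec <- wavelet_decompose(x, 5)
  expect_length(dec$details, 5)
  expect_lt(max(abs(wavelet_reconstruct(dec) - x)), 1e-8)
  expect_error(wavelet_decompose(rnorm(16), 5), "shorter")
})

test_that("sigma estimator matches its hand oracles and is scale-equivariant", {
  expect_equal(estimate_sigma(rep(0.6745, 8)), 1.0)
  expect_equal(estimate_sigma(c(1, -2, 3)), 2 / 0.6745, tolerance = 1e-12)
  expect_error(estimate_sigma(numeric(0)), "empty")
  # MAD consistency on Gaussian noise
  withr::with_seed(2, z <- rnorm(1e5))
  expect_gt(estimate_sigma(z), 0.97)
  expect_lt(estimate_sigma(z), 1.03)
  # scale equivariance
  withr::with_seed(3, d <- rnorm(200))
  for (k in c(0.5, 2, 10)) {
    expect_equal(estimate_sigma(k * d), k * estimate_sigma(d), tolerance = 1e-12)
  }
})

test_that("level threshold follows sigma * sqrt(2 ln N) / ln(b + 1)", {
  d <- rnorm(64)
  expect_equal(level_threshold(1, d, 1), sqrt(2 * log(64)) / log(2))
  expect_equal(level_threshold(0, d, 3), 0)
  expect_error(level_threshold(1, d, 0), "b must be")
  # decreasing in the level index for fixed sigma and N
  te <- vapply(1:5, function(b) level_threshold(1, d, b), 0)
  expect_true(all(diff(te) < 0))
})

test_that("soft thresholding kills small coefficients and shrinks the rest", {
  expect_equal(soft_threshold(c(5, -5), 2), c(3, -3))
  expect_equal(soft_threshold(1.9, 2), 0)
  withr::with_seed(4, d <- rnorm(100, sd = 2))
  out <- soft_threshold(d, 0.7)
  expect_true(all(abs(out) <= abs(d) + 1e-12))       # never grows magnitude
  expect_true(all(out * d >= 0))                     # never flips sign
  expect_identical(soft_threshold(d, 0), d)          # identity limit
})

test_that("wavelet denoising reduces noise and passes through at zero threshold", {
  g <- fx_hc_record()
  expect_equal(wavelet_denoise(numeric(100)), numeric(100))
  expect_lt(max(abs(wavelet_denoise(g$clean, thresholds = rep(0, 5)) - g$clean)),
            1e-8)
  # SNR improvement over seeded trials
  wins <- vapply(1:20, function(s) {
    withr::with_seed(s, noisy <- g$clean + rnorm(length(g$clean), 0, 0.05))
    den <- wavelet_denoise(noisy)
    sqrt(mean((den - g$clean)^2)) < sqrt(mean((noisy - g$clean)^2))
  }, TRUE)
  expect_true(all(wins))
})

test_that("denoising is contraction-like on repeated application", {
  g <- fx_hc_record()
  withr::with_seed(8, noisy <- g$clean + rnorm(length(g$clean), 0, 0.05))
  once <- wavelet_denoise(noisy)
  twice <- wavelet_denoise(once)
  expect_lt(mean((twice - once)^2), mean((once - noisy)^2))
})

test_that("median-filter baseline removal flattens drift", {
  expect_equal(remove_baseline(rep(3.7, 2000), 1000), rep(0, 2000),
               tolerance = 1e-12)
  expect_equal(remove_baseline(numeric(2000), 1000), numeric(2000))
  expect_error(remove_baseline(rnorm(100), 1000), "longer than")
  g <- fx_hc_record()
  t <- (seq_along(g$clean) - 1) / 1000
  drift <- 0.5 * sin(2 * pi * 0.3 * t)
  corrected <- remove_baseline(g$clean + drift, 1000)
  band_power <- function(x, lo = 0.1, hi = 0.5, fs = 1000) {
    n <- length(x); f <- (0:(n - 1)) * fs / n
    P <- Mod(stats::fft(x))^2 / n
    sum(P[f >= lo & f <= hi])
  }
  # residual drift-band power under 1% of the injected drift power (>= 20 dB)
  expect_lt(band_power(corrected) / band_power(drift), 0.01)
})

test_that("Pan-Tompkins finds every peak within 25 ms and is scale-invariant", {
  g <- fx_hc_record()
  x <- g$record$signal[, 1]
  r <- detect_r_peaks(x, 1000)
  expect_length(r, length(g$r_peaks))
  expect_true(all(abs(r - g$r_peaks) <= 25))
  expect_identical(detect_r_peaks(2 * x, 1000), r)
  expect_identical(detect_r_peaks(numeric(3000), 1000), integer(0))
  expect_error(detect_r_peaks(x, 50), "100 Hz")
  expect_error(detect_r_peaks(x[1:500], 1000), "2 s")
})

test_that("segmentation windows are 250 + 1 + 400 samples anchored at the R peak", {
  sig <- seq_len(2000) * 1.0
  b <- segment_beats(sig, 301)            # 0-based r = 300
  expect_equal(nrow(b$samples), 651)
  expect_equal(b$meta$r_index, 251)
  expect_equal(b$samples[, 1], sig[51:701])
  expect_message(out <- segment_beats(sig, c(101, 301)), "discarded")
  expect_equal(n_beats(out), 1)           # r = 100 lacks 250 pre-samples
  expect_equal(n_beats(suppressMessages(segment_beats(sig, integer(0)))), 0)
  many <- suppressMessages(segment_beats(sig, c(301, 701, 1101), pre_n = 100,
                                         post_n = 150))
  expect_true(all(apply(many$samples, 2, length) == 251))
})
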