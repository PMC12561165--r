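# Stockwell transform against an independent direct-sum oracle, plus the
# STFT/CWT alternatives and model-input preparation.

test_that("FFT S-transform equals the direct-sum oracle on short signals", {
  withr::with_seed(1, x <- rnorm(128))
  img <- s_transform(x, 128, f_max_hz = 40, keep_complex = TRUE)
  oracle <- st_direct_sum(x, 128, 40)
  expect_lt(max(abs(img$complex_values - oracle)), 1e-6)
})

test_that("a pure 10 Hz cosine concentrates at the 10 Hz row with amplitude 1/2", {
  t <- (0:999) / 1000
  img <- s_transform(cos(2 * pi * 10 * t), 1000, 50)
  prof <- rowMeans(img$values)
  expect_equal(img$freq_axis_hz[which.max(prof)], 10)
  expect_equal(max(prof), 0.5, tolerance = 0.02)
})

test_that("a constant signal lives entirely in the zero-frequency row", {
  img <- s_transform(rep(3, 500), 1000, 50)
  expect_equal(img$values[1, ], rep(3, 500))
  expect_lt(max(img$values[-1, ]) / 3, 0.5)
})

test_that("the complex transform is linear", {
  withr::with_seed(2, {x <- rnorm(128); y <- rnorm(128)})
  Sx <- s_transform(x, 128, 30, keep_complex = TRUE)$complex_values
  Sy <- s_transform(y, 128, 30, keep_complex = TRUE)$complex_values
  Sxy <- s_transform(2 * x - 3 * y, 128, 30, keep_complex = TRUE)$complex_values
  expect_lt(max(abs(Sxy - (2 * Sx - 3 * Sy))), 1e-9)
})

test_that("time-shifting the input shifts the magnitude image", {
  withr::with_seed(3, burst <- rnorm(40))
  x <- numeric(1000); x[301:340] <- burst
  y <- numeric(1000); y[501:540] <- burst
  ix <- s_transform(x, 1000, 30)$values
  iy <- s_transform(y, 1000, 30)$values
  # compare away from the edges: the y image is the x image shifted by 200
  expect_equal(iy[, 401:740], ix[, 201:540], tolerance = 1e-6)
})

test_that("the ridge time-width scales as 1/frequency", {
  imp <- numeric(1000); imp[500] <- 1
  img <- s_transform(imp, 1000, 30)
  width_at <- function(f) {
    row <- img$values[f + 1, ]
    t <- (seq_along(row) - 1) / 1000
    mu <- sum(row * t) / sum(row)
    sqrt(sum(row * (t - mu)^2) / sum(row))
  }
  w <- vapply(c(5, 10, 20), width_at, 0)
  expect_equal(w[1] / w[2], 2, tolerance = 0.15)
  expect_equal(w[2] / w[3], 2, tolerance = 0.15)
})

test_that("STFT and CWT alternatives share the container and basic contracts", {
  t <- (0:999) / 1000
  y <- cos(2 * pi * 10 * t)
  st <- stft_image(y, 1000, window_s = 0.2)
  expect_equal(st$freq_axis_hz[which.max(rowMeans(st$values))], 10)
  cw <- cwt_image(y, 1000)
  expect_equal(cw$freq_axis_hz[which.max(rowMeans(cw$values))], 10)
  z <- numeric(600)
  expect_equal(max(stft_image(z, 1000)$values), 0)
  expect_equal(max(cwt_image(z, 1000)$values), 0)
  # frequency-dependent vs fixed resolution: row-energy concentration differs
  beat <- fx_hc_beats()$samples[, 1]
  a <- s_transform(beat, 1000, 40)$values
  b <- stft_image(beat, 1000, f_max_hz = 40)$values
  conc <- function(m) {
    p <- rowSums(m^2); p <- p / sum(p); -sum(p[p > 0] * log(p[p > 0]))
  }
  expect_gt(abs(conc(a) - conc(b)), 0.05)
})

test_that("invalid frequency ranges are rejected", {
  expect_error(s_transform(rnorm(100), 100, f_max_hz = 60), "Nyquist")
  expect_error(stft_image(rnorm(100), 100, f_max_hz = 60), "Nyquist")
  expect_error(s_transform(1, 100), "2 samples")
})

test_that("model inputs are 3-channel, unit-range and interpolation-consistent", {
  img <- s_transform(fx_hc_beats()$samples[, 1], 1000, 50)
  x <- to_model_input(img, 224)
  expect_equal(dim(x), c(3, 224, 224))
  expect_gte(min(x), 0); expect_lte(max(x), 1)
  expect_identical(x[1, , ], x[3, , ])
  # degenerate constant image maps to all zeros
  flat <- img; flat$values[] <- 2
  expect_equal(max(to_model_input(flat, 32)), 0)
  # corner-aligned bilinear upscaling is exact for a linear ramp
  ramp <- img
  ramp$values <- outer(seq_len(nrow(img$values)), seq_len(ncol(img$values)),
                       function(i, j) 2 * i + 3 * j)
  up <- rtcn:::bilinear_resize(ramp$values, 4 * nrow(ramp$values) - 3,
                               4 * ncol(ramp$values) - 3)
  back <- up[seq(1, nrow(up), by = 4), seq(1, ncol(up), by = 4)]
  expect_lt(max(abs(back - ramp$values)), 1e-6)
})
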