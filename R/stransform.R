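# Time-frequency imaging of segmented beats: discrete Stockwell transform
# (FFT formulation), plus STFT and Morlet-CWT alternatives for ablation, and
# conversion to fixed-size model inputs.

tf_image <- function(values, freq_axis_hz, time_axis_s, method,
                     complex_values = NULL) {
  assert_that(all(values >= 0), "magnitude image must be non-negative")
  assert_that(nrow(values) == length(freq_axis_hz) &&
              ncol(values) == length(time_axis_s),
              "axis lengths must match the image shape")
  structure(list(values = values, freq_axis_hz = freq_axis_hz,
                 time_axis_s = time_axis_s, method = method,
                 complex_values = complex_values),
            class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image %s> %d freqs (%g..%g Hz) x %d time points\n",
              x$method, nrow(x$values), min(x$freq_axis_hz),
              max(x$freq_axis_hz), ncol(x$values)))
  invisible(x)
}

#' Discrete Stockwell (S-)transform
#'
#' FFT formulation of the discrete S-transform: for each non-zero frequency
#' row the signal spectrum is shifted by that frequency, multiplied by a
#' Gaussian (whose time-domain window has standard deviation 1/f, narrowing
#' as frequency grows) and inverse-transformed. The zero-frequency row is the
#' signal mean. The signal is zero-padded so the frequency axis has exactly
#' \code{freq_res_hz} spacing (1 Hz by default); the returned image keeps the
#' original time support.
#'
#' @param beat numeric vector (length at least 2).
#' @param sampling_rate_hz sampling rate.
#' @param f_max_hz highest frequency row (default 50 Hz, covering the
#'   clinically relevant ECG band); must not exceed Nyquist.
#' @param freq_res_hz frequency-axis spacing.
#' @param keep_complex keep the complex coefficients (for phase use) in the
#'   result's \code{complex_values}.
#' @return A \code{tf_image} with \code{values = |S(tau, f)|}.
#' @export
s_transform <- function(beat, sampling_rate_hz, f_max_hz = 50,
                        freq_res_hz = 1, keep_complex = FALSE) {
  L <- length(beat)
  assert_that(L >= 2, "beat must contain at least 2 samples")
  fs <- sampling_rate_hz
  assert_that(f_max_hz > 0 && f_max_hz <= fs / 2,
              "f_max_hz must lie in (0, Nyquist]")
  base_n <- round(fs / freq_res_hz)
  N <- base_n * ceiling(L / base_n)
  x <- c(beat, numeric(N - L))
  X <- stats::fft(x) / N
  freqs <- seq(0, f_max_hz, by = freq_res_hz)
  S <- matrix(0 + 0i, nrow = length(freqs), ncol = N)
  m <- 0:(N - 1)
  m_signed <- ifelse(m <= N / 2, m, m - N)
  S[1, ] <- mean(beat) + 0i
  for (r in seq_along(freqs)[-1]) {
    n_bin <- round(freqs[r] * N / fs)
    G <- exp(-2 * pi^2 * m_signed^2 / n_bin^2)
    Xs <- X[(m + n_bin) %% N + 1]
    S[r, ] <- stats::fft(Xs * G, inverse = TRUE)
  }
  S <- S[, seq_len(L), drop = FALSE]
  tf_image(abs(S), freqs, (seq_len(L) - 1) / fs, "stransform",
           complex_values = if (keep_complex) S else NULL)
}

#' Short-time Fourier transform image
#'
#' Hann-windowed magnitude spectrogram in the same container as
#' [s_transform()], for the fixed-resolution ablation alternative.
#'
#' @inheritParams s_transform
#' @param window_s analysis window length in seconds.
#' @param hop_s hop between frame centers (default a quarter window).
#' @return A \code{tf_image}.
#' @export
stft_image <- function(beat, sampling_rate_hz, window_s = 0.128,
                       hop_s = window_s / 4, f_max_hz = 50) {
  L <- length(beat)
  assert_that(L >= 2, "beat must contain at least 2 samples")
  fs <- sampling_rate_hz
  assert_that(f_max_hz > 0 && f_max_hz <= fs / 2,
              "f_max_hz must lie in (0, Nyquist]")
  nfft <- max(8L, round(window_s * fs))
  hop <- max(1L, round(hop_s * fs))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  centers <- seq(1, L, by = hop)
  half <- nfft %/% 2
  n_bins <- floor(f_max_hz * nfft / fs) + 1
  vals <- matrix(0, nrow = n_bins, ncol = length(centers))
  padded <- c(numeric(half), beat, numeric(nfft))
  for (j in seq_along(centers)) {
    seg <- padded[centers[j]:(centers[j] + nfft - 1)]
    sp <- stats::fft(seg * win) / sum(win)
    vals[, j] <- abs(sp[seq_len(n_bins)])
  }
  tf_image(vals, (seq_len(n_bins) - 1) * fs / nfft, (centers - 1) / fs, "stft")
}

#' Morlet continuous-wavelet-transform image
#'
#' Analytic Morlet scalogram (centre frequency parameter \code{omega0 = 6}),
#' computed per frequency row in the Fourier domain, in the same container as
#' [s_transform()].
#'
#' @inheritParams s_transform
#' @param omega0 Morlet centre frequency (dimensionless).
#' @return A \code{tf_image}.
#' @export
cwt_image <- function(beat, sampling_rate_hz, f_max_hz = 50, omega0 = 6) {
  L <- length(beat)
  assert_that(L >= 2, "beat must contain at least 2 samples")
  fs <- sampling_rate_hz
  assert_that(f_max_hz > 0 && f_max_hz <= fs / 2,
              "f_max_hz must lie in (0, Nyquist]")
  X <- stats::fft(beat)
  k <- 0:(L - 1)
  om <- 2 * pi * ifelse(k <= L / 2, k, k - L) * fs / L   # rad/s per bin
  freqs <- seq(1, f_max_hz, by = 1)
  vals <- matrix(0, nrow = length(freqs) + 1, ncol = L)
  vals[1, ] <- abs(mean(beat))
  for (r in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[r])                    # scale in seconds
    H <- ifelse(om > 0, exp(-0.5 * (s * om - omega0)^2), 0)
    vals[r + 1, ] <- Mod(stats::fft(X * H, inverse = TRUE) / L)
  }
  tf_image(vals, c(0, freqs), (seq_len(L) - 1) / fs, "cwt")
}

#' Convert a time-frequency image to a model input tensor
#'
#' Bilinear resize to \code{side x side}, per-image min--max normalization to
#' [0, 1] (a constant image maps to all zeros), and replication of the single
#' channel to 3 channels. Deterministic.
#'
#' @param image a \code{tf_image}.
#' @param side output spatial size (default 224, giving the backbone's 7x7
#'   final feature map).
#' @param log1p apply \code{log1p} to the magnitudes before normalization.
#' @return Numeric array of dim \code{c(3, side, side)}.
#' @export
to_model_input <- function(image, side = 224, log1p = FALSE) {
  assert_that(inherits(image, "tf_image"), "image must be a tf_image")
  v <- image$values
  assert_that(length(v) > 0, "empty image")
  if (log1p) v <- log1p(v)
  r <- bilinear_resize(v, side, side)
  rng <- range(r)
  r <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else r * 0
  out <- array(0, dim = c(3, side, side))
  for (ch in 1:3) out[ch, , ] <- r
  out
}
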