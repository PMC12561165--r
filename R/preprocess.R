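# Denoising and beat segmentation: median-filter baseline removal,
# level-dependent soft-threshold wavelet shrinkage on a periodized orthogonal
# db6 decomposition, Pan-Tompkins QRS detection, fixed-window segmentation.

# Daubechies-6 scaling coefficients (standard published constants, ascending).
DB6_H <- c(0.111540743350109466, 0.494623890398453033, 0.751133908021095884,
           0.315250351709197754, -0.226264693965440198, -0.129766867567261935,
           0.097501605587322496, 0.027522865530305456, -0.031582039318486784,
           0.000553842201161602, 0.004777257510945510, -0.001077301085308480)

wavelet_filters <- function(wavelet = "db6") {
  if (!identical(wavelet, "db6")) stop_rtcn("only the db6 wavelet is built in")
  h <- DB6_H
  m <- length(h)
  g <- rev(h) * (-1)^(seq_len(m) - 1)
  list(h = h, g = g)
}

# One periodized analysis step: a[k] = sum_m h[m] x[(2(k-1)+m-1) mod n + 1].
dwt_step <- function(x, filt) {
  n <- length(x)
  m <- length(filt$h)
  k <- seq_len(n / 2)
  idx <- (outer(2 * (k - 1), 0:(m - 1), "+")) %% n + 1
  xm <- matrix(x[idx], nrow = length(k))
  list(a = drop(xm %*% filt$h), d = drop(xm %*% filt$g))
}

idwt_step <- function(a, d, filt) {
  n <- 2 * length(a)
  m <- length(filt$h)
  k <- seq_along(a)
  idx <- (outer(2 * (k - 1), 0:(m - 1), "+")) %% n + 1
  vals <- outer(a, filt$h) + outer(d, filt$g)
  unname(drop(rowsum(as.vector(vals), as.vector(idx))))
}

#' Multi-level wavelet decomposition
#'
#' Periodized orthogonal db6 decomposition. The input is reflected at its end
#' to the next multiple of \code{2^n_levels}; reconstruction truncates back,
#' so [wavelet_reconstruct()] of an unmodified decomposition reproduces the
#' input to numerical precision.
#'
#' @param signal numeric vector, length at least \code{2^n_levels}.
#' @param n_levels decomposition depth (default 5).
#' @param wavelet wavelet basis name (db6).
#' @return Object of class \code{wavelet_decomp} with per-level detail
#'   coefficients \code{details[[b]]} (b = 1 finest) and \code{approx}.
#' @export
wavelet_decompose <- function(signal, n_levels = 5, wavelet = "db6") {
  assert_that(length(signal) >= 2^n_levels,
              "signal shorter than 2^n_levels samples")
  filt <- wavelet_filters(wavelet)
  orig_len <- length(signal)
  block <- 2^n_levels
  pad_len <- ceiling(orig_len / block) * block
  if (pad_len > orig_len) {
    ext <- rev(signal)[seq_len(pad_len - orig_len)]
    signal <- c(signal, ext)
  }
  details <- vector("list", n_levels)
  a <- signal
  for (b in seq_len(n_levels)) {
    st <- dwt_step(a, filt)
    details[[b]] <- st$d
    a <- st$a
  }
  structure(list(details = details, approx = a, n_levels = n_levels,
                 wavelet = wavelet, orig_len = orig_len, pad_len = pad_len),
            class = "wavelet_decomp")
}

#' @rdname wavelet_decompose
#' @param decomp a \code{wavelet_decomp}.
#' @export
wavelet_reconstruct <- function(decomp) {
  filt <- wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (b in rev(seq_len(decomp$n_levels))) {
    a <- idwt_step(a, decomp$details[[b]], filt)
  }
  a[seq_len(decomp$orig_len)]
}

#' Robust per-level noise estimate
#'
#' \code{sigma_b = median(|d_b|) / 0.6745}: the median absolute deviation
#' calibrated to the Gaussian scale (0.6745 is the standard normal upper
#' quartile).
#'
#' @param detail_coeffs numeric vector of detail coefficients at one level.
#' @return Non-negative noise estimate.
#' @export
estimate_sigma <- function(detail_coeffs) {
  assert_that(length(detail_coeffs) > 0, "empty coefficient vector")
  stats::median(abs(detail_coeffs)) / 0.6745
}

#' Level-dependent threshold
#'
#' \code{TE_b = sigma_b * sqrt(2 * ln(N_b)) / ln(b + 1)} where \code{N_b} is
#' the number of detail coefficients at level \code{b}: the universal
#' threshold scaled down at coarser levels (natural logarithms).
#'
#' @param sigma_b noise estimate for the level.
#' @param detail_coeffs detail coefficients at level \code{b} (only their
#'   count enters).
#' @param b level index, \code{b >= 1}.
#' @return Non-negative threshold.
#' @export
level_threshold <- function(sigma_b, detail_coeffs, b) {
  assert_that(length(detail_coeffs) > 0, "empty coefficient vector")
  assert_that(b >= 1, "level index b must be >= 1 (ln(b+1) would vanish)")
  sigma_b * sqrt(2 * log(length(detail_coeffs))) / log(b + 1)
}

#' Soft thresholding
#'
#' Coefficients with magnitude at most the threshold are zeroed; the rest are
#' shrunk toward zero by the threshold, preserving sign. Applied to a plain
#' numeric vector with a scalar threshold, or to a whole
#' [wavelet_decompose()] result with one threshold per detail level.
#'
#' @param x numeric vector or \code{wavelet_decomp}.
#' @param threshold scalar, or numeric vector of per-level thresholds
#'   \code{TE_b} (length \code{n_levels}).
#' @return Same type as \code{x}.
#' @export
soft_threshold <- function(x, threshold) {
  if (inherits(x, "wavelet_decomp")) {
    assert_that(length(threshold) == x$n_levels,
                "need one threshold per detail level")
    for (b in seq_len(x$n_levels)) {
      x$details[[b]] <- soft_threshold(x$details[[b]], threshold[b])
    }
    return(x)
  }
  assert_that(length(threshold) == 1 && threshold >= 0,
              "threshold must be a non-negative scalar")
  sign(x) * pmax(abs(x) - threshold, 0)
}

#' Wavelet denoising
#'
#' Five-level db6 decomposition, per-level soft thresholding with
#' [estimate_sigma()] / [level_threshold()], reconstruction. Output length
#' equals input length.
#'
#' @param signal numeric vector.
#' @param n_levels decomposition depth.
#' @param wavelet basis name.
#' @param thresholds optional numeric vector overriding the computed
#'   per-level thresholds (all zero gives pass-through reconstruction).
#' @return Denoised signal.
#' @export
wavelet_denoise <- function(signal, n_levels = 5, wavelet = "db6",
                            thresholds = NULL) {
  dec <- wavelet_decompose(signal, n_levels, wavelet)
  if (is.null(thresholds)) {
    thresholds <- vapply(seq_len(n_levels), function(b) {
      d <- dec$details[[b]]
      level_threshold(estimate_sigma(d), d, b)
    }, 0)
  }
  dec <- soft_threshold(dec, thresholds)
  wavelet_reconstruct(dec)
}

#' Median-filter baseline removal
#'
#' Two-stage running-median baseline estimate (a short window to flatten QRS
#' complexes, then a longer one to flatten T waves) subtracted from the
#' signal; the classic drift-removal scheme for sub-0.5 Hz baseline wander.
#'
#' @param signal numeric vector.
#' @param sampling_rate_hz sampling rate.
#' @param windows_s the two median windows in seconds (defaults 0.2 and 0.6).
#' @return Baseline-corrected signal of the same length.
#' @export
remove_baseline <- function(signal, sampling_rate_hz, windows_s = c(0.2, 0.6)) {
  odd_k <- function(w) {
    k <- round(w * sampling_rate_hz)
    if (k %% 2 == 0) k <- k + 1
    as.integer(max(k, 3))
  }
  k1 <- odd_k(windows_s[1]); k2 <- odd_k(windows_s[2])
  assert_that(max(k1, k2) <= length(signal),
              "median window longer than the signal")
  base <- stats::runmed(signal, k1, endrule = "median")
  base <- stats::runmed(base, k2, endrule = "median")
  signal - as.numeric(base)
}

#' Pan-Tompkins R-peak detection
#'
#' The classic QRS detection chain: 5--15 Hz band-pass (zero-phase
#' Butterworth), five-point derivative, squaring, 150 ms moving-window
#' integration, adaptive signal/noise dual thresholds with a 200 ms
#' refractory period; each detection is refined to the local maximum of the
#' band-passed signal.
#'
#' @param signal numeric vector, at least 2 s long.
#' @param sampling_rate_hz sampling rate, at least 100 Hz.
#' @return Ascending integer vector of R-peak sample indices (1-based);
#'   empty for a flat signal.
#' @export
detect_r_peaks <- function(signal, sampling_rate_hz) {
  fs <- sampling_rate_hz
  assert_that(fs >= 100, "sampling rate must be at least 100 Hz")
  assert_that(length(signal) >= 2 * fs, "signal must be at least 2 s long")
  if (max(abs(signal)) == 0) return(integer(0))

  but <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(but, signal)
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w <- max(3L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] & mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.6 * max(init)
  npki <- 0.5 * mean(init)
  refractory <- round(0.200 * fs)
  peaks <- integer(0)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] > thr) {
      if (length(peaks) > 0 && (i - peaks[length(peaks)]) < refractory) {
        if (mwi[i] > mwi[peaks[length(peaks)]]) peaks[length(peaks)] <- i
        next
      }
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) return(integer(0))

  # refine onto the band-passed waveform's local maximum
  half <- round(0.050 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(bp), i + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, 0L)
  sort(unique(refined))
}

#' Segment fixed-length beats around R peaks
#'
#' Each kept beat is the inclusive window from \code{pre_n} samples before to
#' \code{post_n} samples after the R peak (651 samples at the 250/400
#' defaults, R peak at position \code{pre_n + 1}). Peaks too close to either
#' record boundary are dropped; the dropped count is reported via
#' \code{message()}.
#'
#' @param signal numeric vector.
#' @param r_peaks integer vector of 1-based R-peak indices.
#' @param pre_n,post_n window extent before/after the R peak.
#' @param label,patient_id,source metadata stamped on every beat.
#' @return A [beat_set()] (possibly with zero beats).
#' @export
segment_beats <- function(signal, r_peaks, pre_n = 250, post_n = 400,
                          label = "unknown", patient_id = "unknown",
                          source = "real") {
  assert_that(pre_n >= 0 && post_n >= 0, "pre_n and post_n must be >= 0")
  L <- pre_n + post_n + 1
  keep <- r_peaks[r_peaks - pre_n >= 1 & r_peaks + post_n <= length(signal)]
  dropped <- length(r_peaks) - length(keep)
  if (dropped > 0) message(dropped, " boundary beat(s) discarded")
  if (length(keep) == 0) {
    return(beat_set(matrix(numeric(0), nrow = L, ncol = 0),
                    character(0), character(0), integer(0), character(0)))
  }
  mat <- vapply(keep, function(r) signal[(r - pre_n):(r + post_n)],
                numeric(L))
  beat_set(matrix(mat, nrow = L), label, patient_id, pre_n + 1L, source)
}

#' Preprocess a record into denoised beats
#'
#' Convenience chain for one record: baseline removal, wavelet denoising,
#' R-peak detection, beat segmentation, carrying the record's label and
#' patient ID onto the beats.
#'
#' @param record an [ecg_record()] (single lead; see [read_wfdb_record()]).
#' @param lead lead to use when the record has several.
#' @param n_levels,wavelet wavelet-denoising parameters.
#' @param pre_n,post_n segmentation window.
#' @return A [beat_set()].
#' @export
preprocess_record <- function(record, lead = record$leads[1], n_levels = 5,
                              wavelet = "db6", pre_n = 250, post_n = 400) {
  x <- record_lead(record, lead)
  x <- remove_baseline(x, record$sampling_rate_hz)
  x <- wavelet_denoise(x, n_levels = n_levels, wavelet = wavelet)
  r <- detect_r_peaks(x, record$sampling_rate_hz)
  segment_beats(x, r, pre_n, post_n, label = record$label,
                patient_id = record$patient_id)
}
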