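# Deterministic synthetic-ECG generation with known ground truth.
#
# Beats are a sum of Gaussian wave components (P, Q, R, S, T) plus a smooth
# ST-segment plateau whose offset encodes the MI-location classes, in the
# spirit of the classic dynamical ECG simulators. Class morphology is
# deliberately simple (ST deviation, Q depth, T polarity/height): enough to
# make the classification problem well-posed and every stage testable, with
# no claim of clinical realism. Additive noise mirrors the three field-typical
# contaminants: baseline drift (slow sinusoid), powerline interference and
# broadband Gaussian noise.

default_waves <- function() {
  list(P = list(amp = 0.15, center = -0.200, width = 0.025),
       Q = list(amp = -0.10, center = -0.040, width = 0.010),
       R = list(amp = 1.00, center = 0.000, width = 0.012),
       S = list(amp = -0.20, center = 0.040, width = 0.012),
       T = list(amp = 0.35, center = 0.300, width = 0.055))
}

#' Class-specific beat morphology
#'
#' Returns the wave parameters and ST-segment offset that encode each of the
#' 12 classes: anterior-family classes carry ST elevation, inferior-family
#' classes deep pathological Q waves (with mild ST change), lateral/posterior
#' classes T-wave changes.
#'
#' @param class_label one of [rtcn_classes()].
#' @return List with elements \code{waves} and \code{st_offset_mv}.
#' @export
class_morphology <- function(class_label) {
  check_class_code(class_label)
  w <- default_waves()
  st <- 0
  adj <- switch(class_label,
    HC    = list(),
    AMI   = { st <- 0.20; list() },
    ALMI  = { st <- 0.25; list(T = 0.25) },
    ASMI  = { st <- 0.30; list() },
    ASLMI = { st <- 0.35; list(T = 0.25) },
    IMI   = { st <- -0.10; list(Q = -0.35) },
    ILMI  = { st <- -0.15; list(Q = -0.40) },
    IPMI  = { st <- -0.05; list(Q = -0.30, T = -0.15) },
    IPLMI = { st <- -0.10; list(Q = -0.45, T = -0.20) },
    LMI   = { st <- 0.05; list(T = -0.30) },
    PMI   = { st <- -0.05; list(R = 1.25, T = 0.45) },
    PLMI  = { st <- 0.10; list(R = 1.20, T = -0.25) })
  for (nm in names(adj)) w[[nm]]$amp <- adj[[nm]]
  list(waves = w, st_offset_mv = st)
}

#' Synthetic-record specification
#'
#' @param class_label class code; sets default morphology via
#'   [class_morphology()] (individual waves can be overridden).
#' @param sampling_rate_hz sampling rate (default 1000 Hz, the PTB rate).
#' @param duration_s record duration in seconds.
#' @param heart_rate_bpm mean heart rate.
#' @param hr_jitter_frac fractional uniform jitter on each RR interval.
#' @param waves optional list overriding wave parameters (amp mV, center s
#'   relative to the R peak, width s).
#' @param st_offset_mv ST-segment offset; default from the class morphology.
#'   Realized as a flat plateau 0.08--0.20 s after the R peak with smooth
#'   cosine ramps, so a mid-window mean measures the offset exactly.
#' @param noise list with \code{baseline_amp_mv}, \code{baseline_freq_hz}
#'   (default 0.3 Hz drift), \code{powerline_amp_mv}, \code{powerline_freq_hz}
#'   (default 50 Hz), \code{white_sigma_mv}.
#' @param seed integer; fixes the output exactly.
#' @return Object of class \code{synth_spec}.
#' @export
synth_spec <- function(class_label = "HC", sampling_rate_hz = 1000,
                       duration_s = 10, heart_rate_bpm = 60,
                       hr_jitter_frac = 0, waves = NULL, st_offset_mv = NULL,
                       noise = list(), seed = 1L) {
  assert_that(sampling_rate_hz > 0, "sampling_rate_hz must be positive")
  assert_that(duration_s > 0, "duration_s must be positive")
  assert_that(heart_rate_bpm > 0, "heart_rate_bpm must be positive")
  assert_that(duration_s * heart_rate_bpm / 60 >= 1,
              "spec must yield at least one beat")
  morph <- class_morphology(class_label)
  w <- morph$waves
  if (!is.null(waves)) for (nm in names(waves)) w[[nm]] <- utils::modifyList(w[[nm]], waves[[nm]])
  for (wv in w) assert_that(wv$width > 0, "wave widths must be positive")
  nz <- utils::modifyList(list(baseline_amp_mv = 0, baseline_freq_hz = 0.3,
                               powerline_amp_mv = 0, powerline_freq_hz = 50,
                               white_sigma_mv = 0), noise)
  structure(list(class_label = class_label, sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_frac = hr_jitter_frac, waves = w,
                 st_offset_mv = if (is.null(st_offset_mv)) morph$st_offset_mv else st_offset_mv,
                 noise = nz, seed = as.integer(seed)),
            class = "synth_spec")
}

# ST plateau: full offset on [0.08, 0.20] s after R, raised-cosine ramps of
# 0.04 s on both sides.
st_plateau <- function(dt, offset) {
  if (offset == 0) return(numeric(length(dt)))
  up0 <- 0.04; up1 <- 0.08; dn0 <- 0.20; dn1 <- 0.24
  y <- numeric(length(dt))
  i <- dt >= up1 & dt <= dn0
  y[i] <- 1
  i <- dt > up0 & dt < up1
  y[i] <- 0.5 * (1 - cos(pi * (dt[i] - up0) / (up1 - up0)))
  i <- dt > dn0 & dt < dn1
  y[i] <- 0.5 * (1 + cos(pi * (dt[i] - dn0) / (dn1 - dn0)))
  offset * y
}

beat_shape <- function(dt, waves, st_offset_mv) {
  y <- numeric(length(dt))
  for (wv in waves) y <- y + wv$amp * exp(-(dt - wv$center)^2 / (2 * wv$width^2))
  y + st_plateau(dt, st_offset_mv)
}

#' Generate one synthetic ECG record with ground truth
#'
#' Builds a quasi-periodic clean ECG as a sum of per-beat wave templates, adds
#' the three noise terms, and returns the record together with the true R-peak
#' sample indices (1-based) and the noise-free signal. Deterministic given the
#' spec seed.
#'
#' @param spec a [synth_spec()].
#' @param record_id,patient_id identifiers for the returned record.
#' @return List with \code{record} ([ecg_record()], single lead "ii"),
#'   \code{r_peaks} (integer vector) and \code{clean} (numeric vector).
#' @export
generate_record <- function(spec, record_id = "syn", patient_id = "SYN-0001") {
  assert_that(inherits(spec, "synth_spec"), "spec must be a synth_spec")
  fs <- spec$sampling_rate_hz
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  rr0 <- 60 / spec$heart_rate_bpm
  with_seed(spec$seed, {
    r_times <- c(); tk <- rr0 / 2
    while (tk < spec$duration_s) {
      r_times <- c(r_times, tk)
      jit <- if (spec$hr_jitter_frac > 0) stats::runif(1, -1, 1) * spec$hr_jitter_frac else 0
      tk <- tk + rr0 * (1 + jit)
    }
    # snap R peaks to the sample grid so ground truth is exact
    r_idx <- pmin(pmax(round(r_times * fs) + 1L, 1L), n)
    r_times <- (r_idx - 1) / fs
    clean <- numeric(n)
    for (rt in r_times) clean <- clean + beat_shape(t - rt, spec$waves, spec$st_offset_mv)
    nz <- spec$noise
    noise <- numeric(n)
    if (nz$baseline_amp_mv > 0) {
      noise <- noise + nz$baseline_amp_mv *
        sin(2 * pi * nz$baseline_freq_hz * t + stats::runif(1, 0, 2 * pi))
    }
    if (nz$powerline_amp_mv > 0) {
      noise <- noise + nz$powerline_amp_mv *
        sin(2 * pi * nz$powerline_freq_hz * t + stats::runif(1, 0, 2 * pi))
    }
    if (nz$white_sigma_mv > 0) noise <- noise + stats::rnorm(n, 0, nz$white_sigma_mv)
    rec <- ecg_record(matrix(clean + noise, ncol = 1), fs, leads = "ii",
                      record_id = record_id, patient_id = patient_id,
                      label = spec$class_label)
    list(record = rec, r_peaks = as.integer(r_idx), clean = clean)
  })
}

#' Generate a labeled multi-patient synthetic dataset
#'
#' One record per synthetic patient, with distinct patient IDs, class-specific
#' morphology and mild per-patient variation (heart rate and R amplitude) so
#' the inter-patient protocol is exercised meaningfully.
#'
#' @param n_per_class named integer vector/list mapping class codes to record
#'   counts (classes not mentioned get 0).
#' @param spec_overrides list of [synth_spec()] arguments applied to every
#'   record (e.g. \code{duration_s}, \code{noise}).
#' @param seed master seed.
#' @return List of [generate_record()] results (record + r_peaks + clean).
#' @export
generate_class_dataset <- function(n_per_class, spec_overrides = list(), seed = 1L) {
  counts <- unlist(n_per_class)
  check_class_code(names(counts))
  assert_that(all(counts >= 0), "counts must be non-negative")
  out <- list()
  k <- 0L
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      k <- k + 1L
      pid <- sprintf("SYN-%s-%03d", cls, i)
      rec_seed <- stage_seed(seed, paste0("synth/", pid))
      pat <- with_seed(stage_seed(seed, paste0("patient/", pid)), {
        list(hr = stats::runif(1, 55, 80), ramp = stats::rnorm(1, 1, 0.05))
      })
      args <- utils::modifyList(
        list(class_label = cls, heart_rate_bpm = pat$hr, hr_jitter_frac = 0.03,
             duration_s = 10,
             noise = list(baseline_amp_mv = 0.1, powerline_amp_mv = 0.02,
                          white_sigma_mv = 0.02),
             seed = rec_seed),
        spec_overrides)
      sp <- do.call(synth_spec, args)
      sp$waves$R$amp <- sp$waves$R$amp * pat$ramp
      out[[k]] <- generate_record(sp, record_id = pid, patient_id = pid)
    }
  }
  out
}

#' Mean amplitude of the ST window of a segmented beat
#'
#' Measures the mean signal value 0.10--0.18 s after the R peak, i.e. inside
#' the flat part of the generator's ST plateau.
#'
#' @param samples numeric beat vector.
#' @param sampling_rate_hz sampling rate.
#' @param r_index 1-based R-peak position within the beat.
#' @return Mean amplitude in mV.
#' @export
st_window_mean <- function(samples, sampling_rate_hz, r_index) {
  lo <- r_index + round(0.10 * sampling_rate_hz)
  hi <- r_index + round(0.18 * sampling_rate_hz)
  mean(samples[lo:hi])
}
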