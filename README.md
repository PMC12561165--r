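# rtcn

Single-lead ECG heartbeat classification and anatomical localization of
myocardial infarction (MI), end to end: denoising, QRS detection, beat
segmentation, Stockwell-transform time–frequency imaging, diffusion-based
class rebalancing, a ResNet-50 → Transformer-encoder cascade classifier with
Grad-CAM explainability, a patient-aware evaluation protocol, and a
deterministic synthetic-ECG generator so the whole pipeline is testable
without downloads.

**Who it is for.** Biomedical-signal researchers who want a fully inspectable
R implementation of this pipeline — every stage, including the neural
networks' backward passes, is plain R backed by BLAS matrix algebra and
verified against independent oracles in the test suite.

## The method

A heartbeat is the window of 250 samples before to 400 samples after its R
peak (651 samples at 1 kHz). After median-filter baseline removal and
five-level db6 soft-threshold wavelet shrinkage with the level-dependent
threshold

    TE_b = sigma_b * sqrt(2 ln N_b) / ln(b + 1),      sigma_b = median(|d_b|)/0.6745,

beats are located with the Pan–Tompkins detector and imaged with the discrete
Stockwell transform

    S(tau, f) = Integral x(t) (|f|/sqrt(2*pi)) exp(-(tau-t)^2 f^2 / 2) exp(-2*pi*i*f*t) dt,

whose Gaussian window narrows as frequency grows (1 Hz frequency resolution,
0–50 Hz rows by default). Class imbalance is addressed by a 1-D denoising
diffusion probabilistic model (forward process `x_t = sqrt(abar_t) x0 +
sqrt(1 - abar_t) eps`, learned reverse Gaussian chain, eps-prediction MSE
objective) that synthesizes minority-class beats, plus downsampling of
majority classes. The classifier ("RTCN") runs a full ResNet-50 (bottleneck
repeats 3/4/6/3, 7×7×2048 final map at 224×224 input, 50 trainable weight
layers), compresses channels 2048 → 512 with a 1×1 convolution, flattens the
map into 49 tokens with learnable positional embeddings and a class token,
and encodes the 50-token sequence with a 3-layer / 8-head Transformer; a
fully connected softmax head on the class token yields the 12 class
probabilities (11 MI locations + healthy control). Metrics are the standard
per-class one-vs-rest accuracy / sensitivity / precision / specificity / F1
and the overall accuracy (confusion-matrix trace over total), under both
intra-patient and leakage-free inter-patient splits.

The methods vignette (`vignettes/rtcn-methods.Rmd`) documents every model,
parameter and design decision in detail.

## Worked example

```r
library(rtcn)

# simulate one noisy lead-II record with known R peaks (AMI morphology:
# +0.2 mV ST elevation)
spec <- synth_spec("AMI", duration_s = 10, heart_rate_bpm = 72,
                   hr_jitter_frac = 0.03,
                   noise = list(baseline_amp_mv = 0.1, powerline_amp_mv = 0.02,
                                white_sigma_mv = 0.02),
                   seed = 42)
gen <- generate_record(spec)

den <- wavelet_denoise(gen$record$signal[, 1])
peaks <- detect_r_peaks(remove_baseline(den, 1000), 1000)
cat("detected", length(peaks), "of", length(gen$r_peaks), "beats; ",
    "max timing error:", max(abs(peaks - gen$r_peaks)), "ms\n")
#> detected 12 of 12 beats; max timing error: 2 ms

beats <- segment_beats(den, peaks, label = "AMI", patient_id = "SYN-AMI-001")
#> 1 boundary beat(s) discarded
print(beats)
#> <beat_set> 11 beats x 651 samples; classes: AMI=11

mean(apply(beats$samples, 2, st_window_mean, 1000, 251))
#> [1] 0.2156645   # the configured +0.2 mV ST elevation, recovered from noise

s_transform(beats$samples[, 1], 1000, f_max_hz = 50)
#> <tf_image stransform> 51 freqs (0..50 Hz) x 651 time points
```

Every detected beat lies within 2 ms of the generator's ground truth, one
peak is dropped because its window would cross the record boundary, and the
mean amplitude of the ST window recovers the class-defining elevation.

The metric suite on a small binary example (8 true positives, 2 false
negatives, 1 false positive, 9 true negatives for AMI):

```r
cm <- confusion_matrix(c(rep(1, 10), rep(2, 10)),
                       c(rep(1, 8), 2, 2, 1, rep(2, 9)), 2,
                       classes = c("AMI", "HC"))
compute_metrics(cm)
#> Per-class metrics (%):
#>  class acc sen   pre spe    f1
#>    AMI  85  80 88.89  90 84.21
#>     HC  85  90 81.82  80 85.71
#> Macro averages: Acc 85.00 Sen 85.00 Pre 85.35 Spe 85.00 F1 84.96
#> Overall AccT: 85.00%
```

A full seeded run — simulate a 12-class multi-patient dataset, preprocess,
DDPM-balance, transform, train a scaled-down cascade, evaluate inter-patient
— is one call:

```r
res <- run_pipeline(list(
  data = list(n_per_class = setNames(rep(3L, 12), rtcn_classes())),
  balance = list(enabled = TRUE),
  train = list(epochs = 4, lr = 0.01, batch_size = 16)),
  out_dir = "run1")
res$metrics          # per-class table, macro averages, overall AccT
res$confusion        # 12 x 12 confusion matrix
```

The run directory receives the exact config used, per-epoch curves, the
confusion matrix, metrics JSON and a stage log. A thin command-line wrapper
(`inst/cli/rtcn`) exposes `simulate`, `ingest`, `preprocess` and `run`
subcommands over the same functions; beat datasets are stored as two
plain-text CSV tables (samples + metadata) via `save_beats()`/`load_beats()`,
and WFDB records are read with `read_wfdb_record()` (header + format-16
signal pairs, lead II by default).

## Scope

Desk-scale only: the shipped configurations are scaled down (small images,
narrow backbone) so that training in pure R stays in the minutes range.
Reproducing published accuracies on the real PTB / PTB-XL corpora would
require those downloads and far larger training budgets, and is explicitly
not attempted; see the vignette for what the synthetic experiments do and do
not demonstrate.
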