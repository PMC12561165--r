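---
title: "Methods: ECG myocardial-infarction classification with an S-transform ResNet-Transformer cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG myocardial-infarction classification with an S-transform ResNet-Transformer cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rtcn)
```

## The problem

Myocardial infarction (MI) leaves characteristic marks on the
electrocardiogram — ST-segment elevation or depression, pathological Q waves,
T-wave changes — whose pattern across leads localizes the infarct
anatomically. This package implements a single-lead (lead II) pipeline that
classifies individual heartbeats into 12 classes: 11 MI locations (anterior,
inferior, lateral, posterior and their combinations: AMI, ALMI, ASMI, ASLMI,
IMI, ILMI, IPMI, IPLMI, LMI, PMI, PLMI) plus healthy control (HC).

The pipeline has five stages, exposed as modules and orchestrated by
`run_pipeline()`:

1. **Preprocessing** — median-filter baseline removal, level-thresholded
   wavelet shrinkage, Pan–Tompkins R-peak detection, fixed-window beat
   segmentation.
2. **Class balancing** — a 1-D denoising diffusion probabilistic model (DDPM)
   synthesizes minority-class beats; majority classes are downsampled.
3. **Time–frequency imaging** — each beat becomes a 2-D magnitude image via
   the Stockwell (S-)transform (STFT and Morlet-CWT are ablation
   alternatives).
4. **Classification** — a ResNet-50 backbone feeds a token-compression layer
   and a Transformer encoder with a class token ("RTCN" cascade).
5. **Evaluation and explanation** — a patient-aware split protocol, the
   standard per-class metric suite, Grad-CAM attribution, and
   distribution-level quality metrics for the synthetic beats.

## Preprocessing

Baseline wander (below ~0.5 Hz) is estimated by a two-stage running median —
a 200 ms window that flattens QRS complexes followed by a 600 ms window that
flattens T waves — and subtracted. The windows are configurable; the defaults
are the classic choice for 1 kHz ECG and attenuate a 0.3 Hz drift by more
than 20 dB (verified in the test suite by band-power measurement).

Residual noise is removed by soft thresholding on a five-level periodized
orthogonal db6 wavelet decomposition. For level $b$ with detail coefficients
$d_b$ (count $N_b$):

$$\hat\sigma_b = \mathrm{median}(|d_b|)/0.6745, \qquad
  TE_b = \hat\sigma_b\,\sqrt{2\ln N_b}\,/\,\ln(b+1),$$

i.e. the universal threshold scaled down at coarser levels, followed by the
usual soft-shrinkage rule $\hat d = \mathrm{sgn}(d)\,(|d| - TE_b)_+$. Design
choices worth recording: the quantity inside the logarithm is the coefficient
*count* (the universal-threshold convention — a median of a scalar norm would
be degenerate), logarithms are natural, the level count defaults to five, and
thresholding is soft. The DWT is implemented in-package (periodized
orthogonal filter bank; perfect reconstruction is asserted to 1e-8 in the
tests) because no wavelet package is available in the target R stack.

R peaks are found with the Pan–Tompkins chain: 5–15 Hz Butterworth band-pass
(applied zero-phase, so no group-delay correction is needed), five-point
derivative, squaring, 150 ms moving-window integration, adaptive signal/noise
thresholds with a 200 ms refractory period, and refinement of each detection
to the local maximum of the band-passed signal. Detections are
scale-invariant because all thresholds adapt to the data.

A heartbeat is the inclusive window from 250 samples before to 400 samples
after the R peak: 651 samples at 1 kHz, with the R peak at position 251
(1-based). Peaks too close to a record boundary are dropped and counted in
the log.

## The synthetic-ECG generator

Real PTB-style recordings require a download and carry no ground truth for
unit-level verification, so the package ships a deterministic generator used
by every test: each beat is a sum of Gaussian wave components (P, Q, R, S, T)
plus a smooth ST-segment plateau (flat 0.08–0.20 s after the R peak with
raised-cosine ramps, so a mid-window mean measures the configured offset
exactly). Class morphology is deliberately minimal: anterior-family classes
get ST elevation (+0.20 to +0.35 mV), inferior-family classes deep
pathological Q waves (−0.30 to −0.45 mV) with mild ST change,
lateral/posterior classes T-wave alterations. Noise has the three
field-typical components: a 0.3 Hz sinusoidal baseline drift, 50 Hz powerline
interference, and white Gaussian noise; defaults for multi-patient datasets
are 0.10 / 0.02 / 0.02 mV. Patients differ in heart rate (uniform 55–80 bpm),
RR jitter (±3 %), and R amplitude (±5 %), which makes the inter-patient
protocol meaningfully harder than the intra-patient one, as it should be.

What this emulates — beat-level morphology differences, patient-level
variation, realistic noise — supports testing every stage's mechanics. What
it does not emulate — genuine pathophysiology, 12-lead spatial structure,
arrhythmias, recording artifacts — means passing tests say nothing about
clinical performance on real data; headline accuracies on PTB-class corpora
are out of scope here.

## DDPM class balancing

The forward process follows the variance-preserving diffusion
$q(x_t\,|\,x_{t-1}) = \mathcal N(\sqrt{1-\beta_t}\,x_{t-1},\ \beta_t I)$ with
strictly increasing $\beta_1 < \dots < \beta_T$, equivalently
$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\varepsilon$ with
$\bar\alpha_t = \prod_{s\le t}(1-\beta_s)$. The reverse chain is Gaussian
with mean
$\mu_\theta = (x_t - \tfrac{\beta_t}{\sqrt{1-\bar\alpha_t}}\,
\varepsilon_\theta(x_t,t))/\sqrt{\alpha_t}$; the reverse variance is
$\beta_t$ by default with the posterior variance
$\tilde\beta_t = \beta_t(1-\bar\alpha_{t-1})/(1-\bar\alpha_t)$ as a switch.
The network is trained on the simplified objective
$\mathbb E\,\|\varepsilon - \varepsilon_\theta(x_t,t)\|^2$ with uniformly
sampled $t$ — the canonical choice, which the $\mu_\theta$ parameterization
presupposes.

The $\varepsilon$-predictor is a small 1-D convolutional encoder–decoder:
two hidden convolution layers (kernel 9, 16–24 channels) conditioned on a
sinusoidal timestep embedding through FiLM (per-channel scale and shift)
after the first convolution, plus a time-conditioned per-position bias field
on the output; a fixed linear position ramp is concatenated to the input so
position-dependent structure is representable. Beats are z-standardized per
training set and de-standardized after sampling; sampled beats keep the
651-sample length.

Schedules: $T = 1000$, $\beta \in [10^{-4}, 0.02]$ linear is the canonical
full-scale default. Fixture and pipeline runs use $T = 30\text{–}50$ with
$\beta \in [10^{-3}, 0.2]$, chosen so that $\bar\alpha_T < 10^{-2}$ — ancestral
sampling starts from pure noise, so a schedule that does not drive
$\bar\alpha_T$ to ~0 would leave a systematic mismatch at the start of the
reverse chain.

Balancing builds a per-class plan (default target: the median class count):
majority classes are downsampled by seeded uniform sampling without
replacement; minority classes keep every real beat and are topped up with
samples from a per-class unconditional model (the simplest reading of
per-minority-class generation; a class-conditional model is a possible
extension). Synthetic beats are flagged and the splitter confines them to the
training partition unconditionally.

## The S-transform

The Stockwell transform of $x(t)$ is

$$S(\tau, f) = \int x(t)\,\frac{|f|}{\sqrt{2\pi}}\,
  e^{-(\tau-t)^2 f^2/2}\, e^{-2\pi i f t}\, dt,$$

a Fourier analysis through a Gaussian window whose time-width is $1/|f|$:
wide at low frequencies (good frequency resolution where the P/T/ST
components live) and narrow at high frequencies (good time resolution for
the QRS complex), while preserving absolute phase. The discrete
implementation is the standard FFT formulation — for each non-zero frequency
row, shift the signal spectrum by that frequency, multiply by a sampled
Gaussian, inverse-transform — and agrees with a direct discretization of the
integral to machine precision (the suite asserts 1e-6 on 128-sample
signals). The zero-frequency row is the signal mean, since the $|f|$
prefactor vanishes at $f = 0$.

Numerical choices: signals are zero-padded to a multiple of one second so the
frequency axis has exactly 1 Hz spacing; rows run 0–50 Hz by default
(covering the QRS energy band with margin, and keeping images small at ≤ 51
rows); the network consumes plain magnitude (a `log1p` toggle exists, off by
default); phase is available from the complex intermediate via
`keep_complex` but does not enter the model input by default. STFT (Hann
window) and Morlet CWT produce the same image container for ablations.

Model inputs are built by corner-aligned separable linear interpolation to
`side x side`, per-image min–max normalization (a constant image maps to
zeros by convention), and channel replication to 3. Corner-aligned
interpolation was chosen over a library resampler because the
interpolation-identity contract (upscale, then read back the original grid)
needs explicit grid semantics.

## The RTCN classifier

The backbone is a full five-stage ResNet-50: a 7×7/stride-2 stem with 3×3
max pooling, then bottleneck stages with repeats 3/4/6/3 and output channels
256/512/1024/2048; stage entries downsample via strided 1×1 convolutions
(both on the main path's first 1×1 and on the projection shortcut). A 224×224
input yields a 7×7×2048 map. Counting main-path convolutions plus the final
fully connected head gives the canonical 50 trainable weight layers
(projection shortcuts excluded by convention).

A 1×1 convolution compresses 2048 channels to $d = 512$ (a first-class knob
with presets 128/256/512/1024/1536); the 7×7 grid is flattened to 49 tokens;
a learnable per-position embedding is added (absolute additive embeddings
indexed by grid position — the simplest form satisfying "learnable"); a
learnable class token is prepended; and a 3-layer, 8-head post-norm
Transformer encoder (attention → add & norm → feed-forward → add & norm,
feed-forward width $4d$, ReLU activation — the paper-style description gives
no activation, so the plain choice) processes the 50-token sequence. The
classification head is a fully connected layer on the class-token state with
a 12-way softmax. Attention matrices from every layer are retained for
inspection; each row sums to 1 by construction.

Two ablation variants are constructible from the same configuration:
`resnet_only` (global average pooling straight into the head) and `vit_only`
(patchify the image, linearly embed, same encoder).

Everything is trained from scratch: He fan-out initialization for
convolutions, N(0, 0.02²) for positional embeddings and the class token, and
— important for trainability of a 50-layer residual network at small batch
sizes — zero initialization of each bottleneck's final batch-norm gain, so
every residual block starts as the identity. The trainer is SGD with
momentum (defaults: learning rate 0.001, momentum 0.9, batch 64, 60 epochs —
all overridable; desk-scale runs use lr 0.01–0.02, batch 10–16, a handful of
epochs) with global-norm gradient clipping (default 5) as an optimization
safeguard. The whole network, including the conv/batch-norm/attention
backward passes, is implemented in-package on base R matrix algebra
(BLAS-backed im2col convolutions); every layer's backward pass is verified
against finite differences in the test suite, since no deep-learning
framework is available in the target R stack.

Desk-scale problem sizes: the shipped tests and the acceptance script train
scaled-down cascades (input side 32–64, stem width 4–8, one encoder layer,
$d$ = 16–32) on dozens-to-hundreds of beats. These reach perfect accuracy on
separable toy tasks in a few epochs and produce well-formed 12-class
confusion matrices on the synthetic dataset; they are demonstrations of the
machinery, not performance claims.

## Evaluation protocol and metrics

Two split paradigms: *intra-patient* (beat-level stratified random split) and
*inter-patient* (patients deduplicated, the patient set partitioned ~8:2,
beats following their patient — so no patient appears on both sides, the
anti-leakage rule asserted on every split). DDPM-synthetic beats go to the
training side in either paradigm. The validation curve uses a stratified 10 %
of the training set. No learning-rate schedule and no early stopping by
default.

From the 12×12 confusion matrix (rows true, columns predicted), each class is
reduced one-vs-rest to TP/FP/FN/TN and reported as percentages: accuracy,
sensitivity (= recall), precision, specificity, and F1 = 2·Sen·Pre/(Sen+Pre).
Per-class accuracy is the one-vs-rest binary accuracy — the only reading that
yields a per-class accuracy column alongside an overall accuracy. The overall
accuracy is trace/total. Macro averages are unweighted; cells with a zero
denominator are NA and excluded from the averages with a logged note.

## Explainability

Grad-CAM: the gradient of the target class *logit* with respect to a chosen
layer's activations is spatially averaged into per-channel weights; the
weighted activation sum is rectified, bilinearly upsampled to the input size,
and max-normalized (all-zero maps stay zero; adding a constant to all logits
provably changes nothing). Registered layers are the last backbone stage
(`"conv5"`) and the compressed token grid entering the encoder (`"tokens"`,
reshaped 49 → 7×7). Attribution on the encoder *output's* spatial tokens
would be vacuous — the head reads only the class token — so the token-grid
attribution sits at the encoder input, where class-score gradients flow
through attention. Attribution through the S-transform back to the raw 1-D
signal is not provided: the transform is a fixed preprocessing step and no
mechanism for attributing through it is defined here. A band-energy helper
reports the fraction of heatmap mass inside a frequency band (e.g. the
5–15 Hz QRS band), and `overlay()` renders the heatmap over the S-transform
image with time/frequency axes.

## Synthetic-beat quality metrics

* **Fréchet distance** between Gaussian fits (sample mean, population
  covariance, small diagonal jitter) of real vs generated features;
  the cross-term matrix square root is computed symmetrically as
  $(S_r^{1/2} S_g S_r^{1/2})^{1/2}$ with eigenvalue clamping. The feature
  extractor is pluggable; the default downsamples beats to 32 points, which
  keeps closed-form oracles exact. Classes with fewer than two beats on a
  side report NA.
* **CRPS** via the exact discrete identity (mean member–truth deviation minus
  half the mean member–member deviation), averaged over time points; the
  suite checks it against numerical integration of the CDF-based definition.
* **DTW** by the classic dynamic program with absolute-difference cost and
  match/insert/delete steps; an optional Sakoe–Chiba band bounds the runtime
  on 651-sample beats. Pairing: positional when real and synthetic sets have
  equal sizes (each synthetic beat has a designated counterpart — and
  identical sets then score 0, as they should), seeded random same-class
  pairing otherwise. Each statistic carries a bootstrap standard deviation.

Absolute values of these metrics depend on the feature extractor and the
generative training budget, so no external numbers are targeted; the tests
check closed forms, symmetry, and monotone degradation under added noise.

## Known limitations

* Pure-R training is slow; full-size (224×224, width-64) training is out of
  reach, which is why all shipped runs are scaled down.
* The generator's class morphology is a caricature; results on it do not
  transfer to real ECG.
* Batch-norm running statistics live in mutable per-layer state, so copies of
  a model object share them; each model should be built fresh (as
  `rtcn_model()` does).
* Single-lead only; multi-lead fusion and PTB-XL metadata beyond
  patient/label/signal are out of scope.
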