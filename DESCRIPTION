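Package: rtcn
Title: ECG Myocardial Infarction Classification with an S-Transform
    ResNet-Transformer Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for myocardial-infarction classification and
    localization from single-lead electrocardiograms. Provides wavelet-threshold
    denoising with median-filter baseline removal, Pan-Tompkins QRS detection and
    fixed-window beat segmentation, Stockwell (S-)transform time-frequency imaging
    (with STFT and Morlet-CWT alternatives), a 1-D denoising diffusion probabilistic
    model for minority-class rebalancing, a ResNet-50 to Transformer-encoder cascade
    classifier with Grad-CAM explainability, a patient-aware evaluation protocol with
    the standard per-class metric suite, generation-quality metrics (Frechet distance,
    CRPS, dynamic time warping), and a deterministic synthetic-ECG generator so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
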