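# Shared fixtures (built in code, cached per session) and a generic
# finite-difference gradient checker for the layer framework.

.fx <- new.env()

# clean 10 s, 60 bpm healthy-control record with light broadband noise
fx_hc_record <- function() {
  if (is.null(.fx$hc)) {
    sp <- synth_spec("HC", duration_s = 10, heart_rate_bpm = 60,
                     noise = list(white_sigma_mv = 0.02), seed = 3)
    .fx$hc <- generate_record(sp)
  }
  .fx$hc
}

# small 12-class multi-patient dataset (2 records per class)
fx_dataset <- function() {
  if (is.null(.fx$ds)) {
    counts <- stats::setNames(rep(2L, 12), rtcn_classes())
    .fx$ds <- generate_class_dataset(counts,
                                     spec_overrides = list(duration_s = 6),
                                     seed = 11)
  }
  .fx$ds
}

# beats segmented from the clean HC record
fx_hc_beats <- function() {
  if (is.null(.fx$hcb)) {
    g <- fx_hc_record()
    .fx$hcb <- suppressMessages(
      segment_beats(g$record$signal[, 1], g$r_peaks,
                    label = "HC", patient_id = "SYN-HC-001"))
  }
  .fx$hcb
}

# separable two-class image problem (bright quadrant encodes the class)
fx_two_class_images <- function(n = 40, side = 32, seed = 7) {
  withr::with_seed(seed, {
    x <- array(0, c(3, side, side, n)); y <- integer(n)
    h <- side / 2
    for (i in seq_len(n)) {
      img <- matrix(stats::rnorm(side * side, 0, 0.2), side, side)
      if (i %% 2 == 0) {
        img[1:h, 1:h] <- img[1:h, 1:h] + 1; y[i] <- 1
      } else {
        img[(h + 1):side, (h + 1):side] <- img[(h + 1):side, (h + 1):side] + 1
        y[i] <- 2
      }
      for (ch in 1:3) x[ch, , , i] <- img
    }
    list(x = x, y = y)
  })
}

# finite-difference check of a layer's input and parameter gradients against
# the analytic backward pass, using the scalar probe loss sum(out * R)
fd_check_layer <- function(layer, x, training = TRUE, eps = 1e-5,
                           n_probe = 10) {
  nf <- rtcn:::nn_forward; nb <- rtcn:::nn_backward
  fw <- nf(layer, x, training)
  R <- array(stats::rnorm(length(fw$out)),
             if (is.null(dim(fw$out))) length(fw$out) else dim(fw$out))
  bw <- nb(layer, fw$cache, R)
  errs <- c()
  for (i in sample(length(x), min(n_probe, length(x)))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gn <- (sum(nf(layer, xp, training)$out * R) -
             sum(nf(layer, xm, training)$out * R)) / (2 * eps)
    errs <- c(errs, abs(gn - bw$dx[i]))
  }
  for (nm in names(layer$params)) {
    p <- layer$params[[nm]]
    for (i in sample(length(p), min(n_probe, length(p)))) {
      lp <- layer; lp$params[[nm]][i] <- p[i] + eps
      lm <- layer; lm$params[[nm]][i] <- p[i] - eps
      gn <- (sum(nf(lp, x, training)$out * R) -
               sum(nf(lm, x, training)$out * R)) / (2 * eps)
      errs <- c(errs, abs(gn - bw$grads[[nm]][i]))
    }
  }
  max(errs)
}
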