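# Generation-quality metrics for DDPM-synthesized beats: Frechet distance
# between Gaussian feature fits, the continuous ranked probability score, and
# dynamic time warping.

# Symmetric PSD matrix square root via eigendecomposition (negative
# eigenvalues from numerical noise are clamped to zero).
sqrtm_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between feature distributions
#'
#' Fits a Gaussian (sample mean and covariance) to each feature set and
#' returns \code{||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})},
#' the Frechet inception distance when the features come from a pretrained
#' extractor. The cross-term square root is computed symmetrically as
#' \code{(S_r^{1/2} S_g S_r^{1/2})^{1/2}}; a small diagonal jitter guards
#' near-singular covariances.
#'
#' @param real_features,gen_features matrices, one row per sample, equal
#'   column (feature) counts, at least 2 rows each.
#' @param jitter diagonal regularization added to both covariances.
#' @return Non-negative scalar.
#' @export
fid <- function(real_features, gen_features, jitter = 1e-8) {
  A <- as.matrix(real_features); B <- as.matrix(gen_features)
  assert_that(ncol(A) == ncol(B), "feature dimensions differ")
  assert_that(nrow(A) >= 2 && nrow(B) >= 2,
              "need at least 2 samples per side")
  mu_r <- colMeans(A); mu_g <- colMeans(B)
  # population covariance: the Gaussian fit of the observed sample
  Sr <- stats::cov(A) * (nrow(A) - 1) / nrow(A) + diag(jitter, ncol(A))
  Sg <- stats::cov(B) * (nrow(B) - 1) / nrow(B) + diag(jitter, ncol(B))
  Sr_h <- sqrtm_psd(Sr)
  cross <- sqrtm_psd(Sr_h %*% Sg %*% Sr_h)
  val <- sum((mu_r - mu_g)^2) + sum(diag(Sr)) + sum(diag(Sg)) -
    2 * sum(diag(cross))
  max(val, 0)
}

#' Continuous ranked probability score of an ensemble
#'
#' Per time point, the CRPS of the ensemble's empirical CDF against the step
#' function at the observed value, via the exact discrete identity
#' mean member-truth absolute deviation minus half the mean member-member
#' absolute deviation, averaged over all time points.
#'
#' @param ensemble matrix \code{n_members x T} (one row per ensemble member),
#'   or a vector for a single member.
#' @param truth numeric vector of length \code{T}.
#' @return Non-negative scalar.
#' @export
crps <- function(ensemble, truth) {
  if (is.vector(ensemble)) ensemble <- matrix(ensemble, nrow = 1)
  assert_that(ncol(ensemble) == length(truth),
              "ensemble and truth lengths differ")
  n <- nrow(ensemble)
  assert_that(n >= 1, "at least one ensemble member required")
  vals <- vapply(seq_along(truth), function(t) {
    m <- ensemble[, t]
    term1 <- mean(abs(m - truth[t]))
    term2 <- if (n > 1) mean(abs(outer(m, m, "-"))) / 2 else 0
    term1 - term2
  }, 0)
  mean(vals)
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment with absolute-difference local cost
#' and match/insert/delete steps; returns the minimal cumulative cost.
#' Symmetric in its arguments. An optional Sakoe-Chiba band limits the
#' alignment window for speed on long sequences.
#'
#' @param a,b non-empty numeric vectors.
#' @param band optional window half-width (in samples); \code{Inf} for the
#'   unconstrained alignment.
#' @return Non-negative scalar.
#' @export
dtw <- function(a, b, band = Inf) {
  n <- length(a); m <- length(b)
  assert_that(n > 0 && m > 0, "inputs must be non-empty")
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    jlo <- max(1L, if (is.finite(band)) i - as.integer(band) else 1L)
    jhi <- min(m, if (is.finite(band)) i + as.integer(band) else m)
    for (j in jlo:jhi) {
      cost <- abs(a[i] - b[j])
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

#' Generation-quality report
#'
#' Per class present on both sides: Frechet distance on extracted features
#' (NA when a side has fewer than two beats), mean CRPS of the synthetic
#' ensemble against each real beat, and mean DTW over seeded same-class
#' real/synthetic pairs (positional pairing when both sides have equal size,
#' random pairing otherwise), each with a bootstrap standard deviation.
#' Classes present on one side only are listed as missing.
#'
#' @param real,synthetic [beat_set()]s.
#' @param feature_extractor function mapping a beat matrix \code{L x n} to a
#'   feature matrix \code{n x p}; the default downsamples each beat to 32
#'   evenly spaced samples (identity-style features with closed-form
#'   behaviour).
#' @param seed seed for pairing and bootstrap.
#' @param n_boot bootstrap resamples for the dispersion estimates.
#' @param dtw_pairs maximum number of real/synthetic DTW pairs.
#' @param dtw_band Sakoe-Chiba half-width passed to [dtw()].
#' @return Object of class \code{gen_quality_report}: data.frame \code{per_class}
#'   (fid, crps, dtw and their bootstrap sds) plus \code{missing}.
#' @export
quality_report <- function(real, synthetic,
                           feature_extractor = default_beat_features,
                           seed = 1L, n_boot = 20, dtw_pairs = 25,
                           dtw_band = 30) {
  assert_that(n_beats(real) > 0 && n_beats(synthetic) > 0,
              "both beat sets must be non-empty")
  rcls <- unique(real$meta$label); scls <- unique(synthetic$meta$label)
  common <- intersect(rcls, scls)
  missing <- setdiff(union(rcls, scls), common)
  rows <- list()
  for (cls in common) {
    R <- real$samples[, real$meta$label == cls, drop = FALSE]
    S <- synthetic$samples[, synthetic$meta$label == cls, drop = FALSE]
    fr <- feature_extractor(R); fs <- feature_extractor(S)
    # the Frechet fit needs at least two samples per side
    fid_val <- if (nrow(fr) >= 2 && nrow(fs) >= 2) fid(fr, fs) else NA_real_
    crps_vals <- apply(R, 2, function(y) crps(t(S), y))
    pair_stats <- with_seed(stage_seed(seed, paste0("dtw/", cls)), {
      np <- min(ncol(R), ncol(S), dtw_pairs)
      ri <- sample(ncol(R), np)
      # equal-sized sides are treated as positionally paired (each synthetic
      # beat has a designated counterpart); otherwise pair at random
      si <- if (ncol(R) == ncol(S)) ri else sample(ncol(S), np)
      vapply(seq_len(np), function(i) dtw(R[, ri[i]], S[, si[i]], band = dtw_band), 0)
    })
    boots <- with_seed(stage_seed(seed, paste0("boot/", cls)), {
      t(vapply(seq_len(n_boot), function(i) {
        bi_r <- sample(nrow(fr), replace = TRUE)
        bi_s <- sample(nrow(fs), replace = TRUE)
        c(fid = if (is.na(fid_val)) NA_real_ else
            tryCatch(fid(fr[bi_r, , drop = FALSE], fs[bi_s, , drop = FALSE]),
                     error = function(e) NA_real_),
          crps = mean(sample(crps_vals, replace = TRUE)),
          dtw = mean(sample(pair_stats, replace = TRUE)))
      }, c(fid = 0, crps = 0, dtw = 0)))
    })
    rows[[cls]] <- data.frame(class = cls, fid = fid_val,
                              fid_sd = stats::sd(boots[, "fid"], na.rm = TRUE),
                              crps = mean(crps_vals),
                              crps_sd = stats::sd(boots[, "crps"]),
                              dtw = mean(pair_stats),
                              dtw_sd = stats::sd(boots[, "dtw"]),
                              n_real = ncol(R), n_synthetic = ncol(S))
  }
  structure(list(per_class = do.call(rbind, unname(rows)), missing = missing),
            class = "gen_quality_report")
}

#' Default beat features for the Frechet distance
#'
#' Downsamples each beat to 32 evenly spaced samples. A trained backbone
#' truncated at global pooling can be plugged in instead via the
#' \code{feature_extractor} argument of [quality_report()].
#'
#' @param beats matrix \code{L x n}.
#' @return Feature matrix \code{n x 32}.
#' @export
default_beat_features <- function(beats) {
  idx <- round(seq(1, nrow(beats), length.out = 32))
  t(beats[idx, , drop = FALSE])
}

#' @export
print.gen_quality_report <- function(x, ...) {
  cat("Generation quality (per class):\n")
  df <- x$per_class
  df[c("fid", "crps", "dtw")] <- round(df[c("fid", "crps", "dtw")], 4)
  print(df[, c("class", "fid", "crps", "dtw", "n_real", "n_synthetic")],
        row.names = FALSE)
  if (length(x$missing)) {
    cat("classes missing on one side:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
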