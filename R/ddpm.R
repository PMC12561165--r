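# Denoising diffusion probabilistic model over segmented heartbeats, used
# (together with majority downsampling) to balance the class distribution.
#
# Forward process: q(x_t | x_{t-1}) = N(sqrt(1 - beta_t) x_{t-1}, beta_t I)
# with strictly increasing variances beta_1 < ... < beta_T, equivalently the
# closed form x_t = sqrt(abar_t) x0 + sqrt(1 - abar_t) eps. The reverse chain
# is Gaussian with network-predicted mean mu_theta derived from an
# eps-predictor trained on the simplified MSE objective; the reverse variance
# is beta_t by default, with the posterior variance
# beta_t (1 - abar_{t-1}) / (1 - abar_t) as a configurable alternative.

#' Construct a diffusion noise schedule
#'
#' @param T_ number of diffusion steps (1000 with beta in [1e-4, 0.02] is the
#'   canonical full-scale setting; fixtures use far fewer).
#' @param beta_start,beta_end first and last variance, 0 < start < end < 1.
#' @param kind schedule shape; \code{"linear"}.
#' @param sigma reverse-process variance: \code{"beta"} (default) or
#'   \code{"posterior"}.
#' @return Object of class \code{noise_schedule} with \code{betas},
#'   \code{alphas}, \code{alpha_bars}, \code{sigma2}.
#' @export
make_schedule <- function(T_, beta_start = 1e-4, beta_end = 0.02,
                          kind = "linear", sigma = c("beta", "posterior")) {
  sigma <- match.arg(sigma)
  assert_that(T_ >= 2, "schedule needs at least 2 steps")
  assert_that(beta_start > 0 && beta_end < 1 && beta_start < beta_end,
              "need 0 < beta_start < beta_end < 1 (betas must increase)")
  if (!identical(kind, "linear")) stop_rtcn("unknown schedule kind: ", kind)
  betas <- seq(beta_start, beta_end, length.out = T_)
  alphas <- 1 - betas
  abars <- cumprod(alphas)
  sigma2 <- if (sigma == "beta") betas else {
    abar_prev <- c(1, abars[-T_])
    betas * (1 - abar_prev) / (1 - abars)
  }
  structure(list(T_ = as.integer(T_), betas = betas, alphas = alphas,
                 alpha_bars = abars, sigma2 = sigma2, sigma_kind = sigma),
            class = "noise_schedule")
}

#' Sample from the forward (noising) process
#'
#' Closed form \code{x_t = sqrt(abar_t) x0 + sqrt(1 - abar_t) eps} with
#' \code{eps ~ N(0, I)}; \code{method = "chain"} instead composes the
#' per-step transition t times (equal in distribution, used as a
#' cross-check).
#'
#' @param x0 numeric vector or matrix (columns are beats).
#' @param t step index in \code{1..T}.
#' @param schedule a [make_schedule()].
#' @param seed RNG seed.
#' @param method \code{"closed_form"} or \code{"chain"}.
#' @return Noised signal, same shape as \code{x0}.
#' @export
forward_sample <- function(x0, t, schedule, seed = NULL,
                           method = c("closed_form", "chain")) {
  method <- match.arg(method)
  assert_that(t >= 1 && t <= schedule$T_, "t out of schedule range")
  with_seed(seed, {
    if (method == "closed_form") {
      ab <- schedule$alpha_bars[t]
      x0 * sqrt(ab) + stats::rnorm(length(x0)) * sqrt(1 - ab)
    } else {
      x <- x0
      for (s in seq_len(t)) {
        x <- sqrt(1 - schedule$betas[s]) * x +
          sqrt(schedule$betas[s]) * stats::rnorm(length(x0))
      }
      x
    }
  })
}

# ---------------------------------------------------------------------------
# eps-predictor: a small 1-D convolutional encoder-decoder conditioned on the
# timestep through a sinusoidal embedding: FiLM (per-channel scale/shift)
# modulation after the first convolution plus a time-conditioned per-position
# bias field on the output. A fixed linear position ramp is concatenated to
# the input channel so position-dependent structure is representable.

#' Construct a DDPM denoiser network
#'
#' @param L beat length (651 by default).
#' @param channels hidden channel width.
#' @param k convolution kernel length (odd).
#' @param emb_dim sinusoidal timestep-embedding dimension (even).
#' @return Object of class \code{ddpm_net}/\code{nn_layer}.
#' @export
ddpm_denoiser <- function(L = 651, channels = 16, k = 9, emb_dim = 16) {
  assert_that(emb_dim %% 2 == 0, "emb_dim must be even")
  nn_layer("ddpm_net",
           layers = list(c_in = conv1d(2, channels, k),
                         film = linear(emb_dim, 2 * channels, init_sd = 0.02),
                         c_mid = conv1d(channels, channels, k),
                         c_out = conv1d(channels, 1, k),
                         field = linear(emb_dim, L, bias = FALSE,
                                        init_sd = 0.02)),
           L = L, channels = channels, emb_dim = emb_dim)
}

ddpm_net_forward <- function(net, x, t) {
  # x: [L, N]; t: integer vector length N
  L <- net$L; N <- ncol(x); ch <- net$channels
  emb <- time_embedding(t, net$emb_dim)              # [emb, N]
  xin <- array(0, c(2, L, N))
  xin[1, , ] <- x
  xin[2, , ] <- (seq_len(L) - 1) / (L - 1)           # position ramp
  f1 <- nn_forward(net$layers$c_in, xin)
  fl <- nn_forward(net$layers$film, emb)
  scale <- 1 + fl$out[seq_len(ch), , drop = FALSE]   # [ch, N]
  shift <- fl$out[ch + seq_len(ch), , drop = FALSE]
  h1 <- f1$out * aperm(array(scale, c(ch, N, L)), c(1, 3, 2)) +
    aperm(array(shift, c(ch, N, L)), c(1, 3, 2))
  m1 <- h1 > 0
  a1 <- h1 * m1
  f2 <- nn_forward(net$layers$c_mid, a1)
  m2 <- f2$out > 0
  a2 <- f2$out * m2
  f3 <- nn_forward(net$layers$c_out, a2)
  fld <- nn_forward(net$layers$field, emb)           # [L, N]
  out <- matrix(f3$out, L, N) + fld$out
  list(out = out,
       cache = list(c_in = f1$cache, film = fl$cache, c_mid = f2$cache,
                    c_out = f3$cache, field = fld$cache, emb = emb,
                    f1_out = f1$out, scale = scale, m1 = m1, a1 = a1,
                    m2 = m2, a2 = a2, L = L, N = N))
}

ddpm_net_backward <- function(net, cache, dout) {
  ch <- net$channels; L <- cache$L; N <- cache$N
  b_fld <- nn_backward(net$layers$field, cache$field, dout)
  d3 <- array(dout, c(1, L, N))
  b3 <- nn_backward(net$layers$c_out, cache$c_out, d3)
  da2 <- b3$dx * cache$m2
  b2 <- nn_backward(net$layers$c_mid, cache$c_mid, da2)
  dh1 <- b2$dx * cache$m1
  scale_arr <- aperm(array(cache$scale, c(ch, N, L)), c(1, 3, 2))
  df1 <- dh1 * scale_arr
  dscale <- apply(dh1 * cache$f1_out, c(1, 3), sum)  # [ch, N]
  dshift <- apply(dh1, c(1, 3), sum)
  b_fl <- nn_backward(net$layers$film, cache$film, rbind(dscale, dshift))
  b1 <- nn_backward(net$layers$c_in, cache$c_in, df1)
  grads <- list(layers = list(c_in = b1$grads, film = b_fl$grads,
                              c_mid = b2$grads, c_out = b3$grads,
                              field = b_fld$grads))
  list(dx = matrix(b1$dx[1, , ], L, N), grads = grads)
}

#' Train a DDPM denoiser on one class of beats
#'
#' Beats are z-standardized over the set; training minimizes the mean squared
#' error between the injected noise and the network prediction
#' \code{eps_theta(x_t, t)} at uniformly sampled timesteps, by SGD with
#' momentum. Deterministic given the seed.
#'
#' @param beats a [beat_set()] or a numeric matrix \code{L x n}.
#' @param schedule a [make_schedule()].
#' @param hparams list overriding \code{steps}, \code{batch_size}, \code{lr},
#'   \code{momentum}, \code{channels}, \code{k}, \code{emb_dim},
#'   \code{clip_norm}.
#' @param seed RNG seed.
#' @return Object of class \code{ddpm_model}: the network, the loss trace,
#'   and the standardization constants.
#' @export
train_denoiser <- function(beats, schedule, hparams = list(), seed = 1L) {
  X <- if (inherits(beats, "beat_set")) beats$samples else as.matrix(beats)
  assert_that(ncol(X) >= 1, "at least one beat required")
  hp <- utils::modifyList(list(steps = 400, batch_size = 16, lr = 0.005,
                               momentum = 0.9, channels = 16, k = 9,
                               emb_dim = 16, clip_norm = 10), hparams)
  mu <- mean(X); sd_ <- stats::sd(as.vector(X))
  if (!is.finite(sd_) || sd_ == 0) sd_ <- 1
  Z <- (X - mu) / sd_
  L <- nrow(Z); n <- ncol(Z)
  with_seed(seed, {
    net <- ddpm_denoiser(L, hp$channels, hp$k, hp$emb_dim)
    vel <- sgd_init(net)
    trace <- numeric(hp$steps)
    for (it in seq_len(hp$steps)) {
      bi <- sample.int(n, min(hp$batch_size, n), replace = n < hp$batch_size)
      x0 <- Z[, bi, drop = FALSE]
      t <- sample.int(schedule$T_, length(bi), replace = TRUE)
      eps <- matrix(stats::rnorm(length(x0)), L)
      ab <- schedule$alpha_bars[t]
      xt <- sweep(x0, 2, sqrt(ab), "*") + sweep(eps, 2, sqrt(1 - ab), "*")
      fw <- ddpm_net_forward(net, xt, t)
      diff <- fw$out - eps
      trace[it] <- mean(diff^2)
      bw <- ddpm_net_backward(net, fw$cache, 2 * diff / length(diff))
      grads <- clip_grads(bw$grads, hp$clip_norm)
      st <- sgd_step(net, grads, vel, hp$lr, hp$momentum)
      net <- st$layer; vel <- st$vel
    }
    structure(list(net = net, loss_trace = trace, mean = mu, sd = sd_,
                   L = L), class = "ddpm_model")
  })
}

#' Ancestral sampling from a trained DDPM
#'
#' Starts from \code{x_T ~ N(0, I)} and applies the learned reverse Gaussian
#' transitions down to \code{x_0}, using
#' \code{mu_theta = (x_t - beta_t / sqrt(1 - abar_t) eps_theta) / sqrt(alpha_t)}
#' and the schedule's reverse variances (no noise at the final step). Output
#' is de-standardized to millivolts and keeps the training beat length.
#'
#' @param model a [train_denoiser()] result.
#' @param schedule the schedule used in training.
#' @param n number of beats to draw.
#' @param seed RNG seed.
#' @return Matrix \code{L x n} of synthetic beats.
#' @export
sample_ddpm <- function(model, schedule, n, seed = 1L) {
  assert_that(n > 0, "n must be positive")
  L <- model$L
  with_seed(seed, {
    x <- matrix(stats::rnorm(L * n), L, n)
    for (t in seq(schedule$T_, 1)) {
      epshat <- ddpm_net_forward(model$net, x, rep(t, n))$out
      a <- schedule$alphas[t]; ab <- schedule$alpha_bars[t]
      mu <- (x - schedule$betas[t] / sqrt(1 - ab) * epshat) / sqrt(a)
      x <- if (t > 1) {
        mu + sqrt(schedule$sigma2[t]) * matrix(stats::rnorm(L * n), L, n)
      } else mu
    }
    x * model$sd + model$mean
  })
}

# ---------------------------------------------------------------------------
# Class balancing.

#' Build a class-balance plan
#'
#' Maps each present class to a target count and an action: majority classes
#' are downsampled, minority classes topped up with DDPM-synthesized beats.
#' The default target (the median class count) reproduces the near one-to-one
#' balance strategy.
#'
#' @param counts named integer vector of per-class beat counts.
#' @param targets named integer vector of target counts; a single unnamed
#'   value applies to all classes; default median of \code{counts}.
#' @param seed seed used by [balance_dataset()] for downsampling/sampling.
#' @return Object of class \code{balance_plan}.
#' @export
balance_plan <- function(counts, targets = NULL, seed = 1L) {
  counts <- unlist(counts)
  check_class_code(names(counts))
  if (is.null(targets)) targets <- round(stats::median(counts))
  if (length(targets) == 1 && is.null(names(targets))) {
    targets <- stats::setNames(rep(round(targets), length(counts)), names(counts))
  }
  assert_that(all(names(counts) %in% names(targets)),
              "plan must cover every present class")
  action <- ifelse(targets[names(counts)] >= counts, "synthesize", "downsample")
  structure(list(counts = counts, targets = targets[names(counts)],
                 action = action, seed = as.integer(seed)),
            class = "balance_plan")
}

#' Balance a labeled beat dataset
#'
#' Majority classes are reduced by seeded uniform sampling without
#' replacement; minority classes keep every real beat and are topped up with
#' DDPM samples flagged \code{source = "synthetic"} (which the splitter later
#' confines to the training side). Classes whose target equals their count
#' pass through unchanged.
#'
#' @param beats a [beat_set()].
#' @param plan a [balance_plan()].
#' @param models named list of [train_denoiser()] models, one per class that
#'   needs synthesis.
#' @param schedule the [make_schedule()] the models were trained with.
#' @return A [beat_set()] with per-class counts equal to the plan targets.
#' @export
balance_dataset <- function(beats, plan, models = list(), schedule = NULL) {
  labs <- beats$meta$label
  present <- unique(labs)
  assert_that(all(present %in% names(plan$targets)),
              "plan must cover every present class")
  out <- list()
  for (cls in present) {
    idx <- which(labs == cls)
    tgt <- plan$targets[[cls]]
    if (tgt < length(idx)) {
      keep <- with_seed(stage_seed(plan$seed, paste0("down/", cls)),
                        sample(idx, tgt))
      out[[cls]] <- beat_subset(beats, sort(keep))
    } else if (tgt == length(idx)) {
      out[[cls]] <- beat_subset(beats, idx)
    } else {
      need <- tgt - length(idx)
      mdl <- models[[cls]]
      if (is.null(mdl) || is.null(schedule)) {
        stop_rtcn("class ", cls, " needs ", need,
                  " synthetic beats but no model/schedule was supplied")
      }
      syn <- sample_ddpm(mdl, schedule, need,
                         seed = stage_seed(plan$seed, paste0("synth/", cls)))
      syn_set <- beat_set(syn, cls, paste0("ddpm-", cls),
                          beats$meta$r_index[idx[1]], "synthetic")
      out[[cls]] <- beat_bind(beat_subset(beats, idx), syn_set)
    }
  }
  do.call(beat_bind, unname(out))
}
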