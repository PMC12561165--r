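# Minimal neural-network layer framework with explicit forward/backward
# passes, written on base R matrix algebra (BLAS-backed im2col convolutions).
#
# Conventions:
#   * conv feature tensors are arrays [C, H, W, N] (channel fastest);
#   * dense activations are matrices [d, N];
#   * token sequences are arrays [d, T, N] (embedding dim fastest).
# Layers are plain lists with a `params` list; `nn_forward()` returns
# (out, cache), `nn_backward()` returns (dx, grads) with grads mirroring
# params. Composite layers nest children under `layers` and their grads
# nest the same way, so one recursive SGD walks any model. BatchNorm running
# statistics and captured attention maps live in per-layer environments
# (reference semantics) since they are state, not parameters.

nn_layer <- function(type, params = list(), ...) {
  structure(c(list(type = type, params = params), list(...)),
            class = c(type, "nn_layer"))
}

#' @export
nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")

#' @export
nn_backward <- function(layer, cache, dout) UseMethod("nn_backward")

zeros_like_params <- function(layer) {
  g <- lapply(layer$params, function(p) p * 0)
  if (!is.null(layer$layers)) {
    g$layers <- lapply(layer$layers, zeros_like_params)
  }
  g
}

# ---- im2col machinery ------------------------------------------------------

im2col_idx <- function(C, H, W, kh, kw, stride, pad) {
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Hout <- (Hp - kh) %/% stride + 1
  Wout <- (Wp - kw) %/% stride + 1
  ci <- rep(seq_len(C), times = kh * kw)
  ki <- rep(rep(seq_len(kh), each = C), times = kw)
  kj <- rep(seq_len(kw), each = C * kh)
  oi <- rep(seq_len(Hout), times = Wout)
  oj <- rep(seq_len(Wout), each = Hout)
  P <- Hout * Wout
  si <- outer((oi - 1) * stride, ki, "+")          # [P, CKK]
  sj <- outer((oj - 1) * stride, kj, "+")
  lin <- t(matrix(ci, nrow = P, ncol = length(ci), byrow = TRUE) +
             C * ((si - 1) + Hp * (sj - 1)))       # [CKK, P]
  list(lin = lin, Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp, P = P)
}

pad_tensor <- function(x, pad, fill = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

im2col <- function(x, kh, kw, stride, pad, fill = 0) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  info <- im2col_idx(C, H, W, kh, kw, stride, pad)
  xp <- pad_tensor(x, pad, fill)
  per <- C * info$Hp * info$Wp
  idx <- as.vector(info$lin)
  full <- rep(idx, times = N) + rep((seq_len(N) - 1) * per, each = length(idx))
  Xcol <- matrix(xp[full], nrow = nrow(info$lin))
  c(info, list(Xcol = Xcol, per = per, C = C, H = H, W = W,
               N = N, pad = pad, kh = kh, kw = kw, stride = stride))
}

# accumulate patch-matrix gradients back onto the (padded) input: one strided
# slice-add per kernel offset, which keeps everything vectorized
col2im <- function(dXcol, info) {
  dxp <- array(0, c(info$C, info$Hp, info$Wp, info$N))
  blk <- array(dXcol, c(info$C, info$kh, info$kw, info$Hout, info$Wout, info$N))
  for (ki in seq_len(info$kh)) {
    si <- seq(ki, by = info$stride, length.out = info$Hout)
    for (kj in seq_len(info$kw)) {
      sj <- seq(kj, by = info$stride, length.out = info$Wout)
      dxp[, si, sj, ] <- dxp[, si, sj, , drop = FALSE] +
        array(blk[, ki, kj, , , ], c(info$C, info$Hout, info$Wout, info$N))
    }
  }
  if (info$pad > 0) {
    dxp <- dxp[, info$pad + seq_len(info$H), info$pad + seq_len(info$W), ,
               drop = FALSE]
  }
  dxp
}

# ---- conv2d ----------------------------------------------------------------

conv2d <- function(cin, cout, k, stride = 1, pad = 0, bias = FALSE,
                   role = "main") {
  kh <- k[1]; kw <- if (length(k) > 1) k[2] else k[1]
  sd <- sqrt(2 / (kh * kw * cout))                  # He fan-out
  params <- list(W = matrix(stats::rnorm(cout * cin * kh * kw, 0, sd),
                            nrow = cout))
  if (bias) params$b <- numeric(cout)
  nn_layer("conv2d", params, cin = cin, cout = cout, kh = kh, kw = kw,
           stride = stride, pad = pad, role = role)
}

#' @export
nn_forward.conv2d <- function(layer, x, training = FALSE) {
  info <- im2col(x, layer$kh, layer$kw, layer$stride, layer$pad)
  Y <- layer$params$W %*% info$Xcol
  if (!is.null(layer$params$b)) Y <- Y + layer$params$b
  out <- array(Y, c(layer$cout, info$Hout, info$Wout, info$N))
  list(out = out, cache = info)
}

#' @export
nn_backward.conv2d <- function(layer, cache, dout) {
  dY <- matrix(dout, nrow = layer$cout)
  grads <- list(W = dY %*% t(cache$Xcol))
  if (!is.null(layer$params$b)) grads$b <- rowSums(dY)
  dXcol <- t(layer$params$W) %*% dY
  list(dx = col2im(dXcol, cache), grads = grads)
}

# ---- conv1d (stride 1, odd kernel, same-length zero padding) ---------------

conv1d <- function(cin, cout, k, bias = TRUE) {
  assert_that(k %% 2 == 1, "conv1d kernel must be odd")
  sd <- sqrt(2 / (k * cout))
  params <- list(W = matrix(stats::rnorm(cout * cin * k, 0, sd), nrow = cout))
  if (bias) params$b <- numeric(cout)
  nn_layer("conv1d", params, cin = cin, cout = cout, k = k)
}

im2col_1d <- function(x, k) {
  # x: [cin, L, N]; returns Xcol [cin*k, L*N] with zero padding
  d <- dim(x); cin <- d[1]; L <- d[2]; N <- d[3]
  pad <- (k - 1) / 2
  Lp <- L + 2 * pad
  xp <- array(0, c(cin, Lp, N))
  xp[, pad + seq_len(L), ] <- x
  ci <- rep(seq_len(cin), times = k)
  ki <- rep(seq_len(k), each = cin)
  pos <- seq_len(L)
  lin <- t(outer(pos - 1, ki, "+") * cin - cin + matrix(ci, L, cin * k, byrow = TRUE))
  per <- cin * Lp
  idx <- as.vector(lin)
  full <- rep(idx, times = N) + rep((seq_len(N) - 1) * per, each = length(idx))
  list(Xcol = matrix(xp[full], nrow = cin * k), per = per,
       cin = cin, L = L, N = N, pad = pad, Lp = Lp, k = k)
}

#' @export
nn_forward.conv1d <- function(layer, x, training = FALSE) {
  info <- im2col_1d(x, layer$k)
  Y <- layer$params$W %*% info$Xcol
  if (!is.null(layer$params$b)) Y <- Y + layer$params$b
  list(out = array(Y, c(layer$cout, info$L, info$N)), cache = info)
}

#' @export
nn_backward.conv1d <- function(layer, cache, dout) {
  dY <- matrix(dout, nrow = layer$cout)
  grads <- list(W = dY %*% t(cache$Xcol))
  if (!is.null(layer$params$b)) grads$b <- rowSums(dY)
  dXcol <- t(layer$params$W) %*% dY
  dxp <- array(0, c(cache$cin, cache$Lp, cache$N))
  blk <- array(dXcol, c(cache$cin, cache$k, cache$L, cache$N))
  for (m in seq_len(cache$k)) {
    sm <- seq(m, length.out = cache$L)
    dxp[, sm, ] <- dxp[, sm, , drop = FALSE] +
      array(blk[, m, , ], c(cache$cin, cache$L, cache$N))
  }
  dx <- dxp[, cache$pad + seq_len(cache$L), , drop = FALSE]
  list(dx = dx, grads = grads)
}

# ---- batchnorm2d -----------------------------------------------------------

batchnorm2d <- function(C, eps = 1e-5, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C); st$var <- rep(1, C)
  nn_layer("batchnorm2d", list(gamma = rep(1, C), beta = numeric(C)),
           C = C, eps = eps, momentum = momentum, state = st)
}

#' @export
nn_forward.batchnorm2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  m <- matrix(x, nrow = layer$C)
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m^2) - mu^2
    layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * mu
    layer$state$var <- (1 - layer$momentum) * layer$state$var + layer$momentum * v
  } else {
    mu <- layer$state$mean; v <- layer$state$var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (m - mu) * invstd
  out <- array(layer$params$gamma * xhat + layer$params$beta, d)
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training))
}

#' @export
nn_backward.batchnorm2d <- function(layer, cache, dout) {
  dm <- matrix(dout, nrow = layer$C)
  xhat <- cache$xhat
  grads <- list(gamma = rowSums(dm * xhat), beta = rowSums(dm))
  dxhat <- dm * layer$params$gamma
  if (cache$training) {
    M <- ncol(dm)
    dx <- cache$invstd *
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dx <- dxhat * cache$invstd
  }
  list(dx = array(dx, cache$dims), grads = grads)
}

# ---- relu / dropout --------------------------------------------------------

relu <- function() nn_layer("relu")

#' @export
nn_forward.relu <- function(layer, x, training = FALSE) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

#' @export
nn_backward.relu <- function(layer, cache, dout) {
  list(dx = dout * cache, grads = list())
}

dropout <- function(rate = 0.1) nn_layer("dropout", rate = rate)

#' @export
nn_forward.dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

#' @export
nn_backward.dropout <- function(layer, cache, dout) {
  if (is.null(cache)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache, grads = list())
}

# ---- maxpool ---------------------------------------------------------------

maxpool2d <- function(k = 3, stride = 2, pad = 1) {
  nn_layer("maxpool2d", k = k, stride = stride, pad = pad)
}

#' @export
nn_forward.maxpool2d <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  xr <- aperm(x, c(2, 3, 1, 4))                     # [H, W, C, N]
  dim(xr) <- c(1, H, W, C * N)
  info <- im2col(xr, layer$k, layer$k, layer$stride, layer$pad, fill = -Inf)
  tX <- t(info$Xcol)                                # [P*C*N, KK]
  arg <- max.col(tX, ties.method = "first")
  vals <- tX[cbind(seq_len(nrow(tX)), arg)]
  out <- array(vals, c(info$Hout, info$Wout, C, N))
  out <- aperm(out, c(3, 1, 2, 4))
  list(out = out,
       cache = list(info = info, arg = arg, C = C, H = H, W = W, N = N))
}

#' @export
nn_backward.maxpool2d <- function(layer, cache, dout) {
  info <- cache$info
  dr <- aperm(dout, c(2, 3, 1, 4))                  # [Hout, Wout, C, N]
  dvals <- as.vector(dr)
  # position of each output's argmax in the padded flat input
  ncols <- length(dvals)
  col_in_sample <- ((seq_len(ncols) - 1) %% info$P) + 1
  sample_id <- ((seq_len(ncols) - 1) %/% info$P)
  flat_idx <- info$lin[cbind(cache$arg, col_in_sample)] + sample_id * info$per
  dxp_flat <- numeric(info$per * cache$C * cache$N)
  r <- rowsum(dvals, flat_idx)
  dxp_flat[as.numeric(rownames(r))] <- r
  dxp <- array(dxp_flat, c(1, info$Hp, info$Wp, cache$C * cache$N))
  if (info$pad > 0) {
    dxp <- dxp[, info$pad + seq_len(cache$H), info$pad + seq_len(cache$W), ,
               drop = FALSE]
  }
  dx <- array(dxp, c(cache$H, cache$W, cache$C, cache$N))
  list(dx = aperm(dx, c(3, 1, 2, 4)), grads = list())
}

# ---- global average pool ---------------------------------------------------

global_avg_pool <- function() nn_layer("gap")

#' @export
nn_forward.gap <- function(layer, x, training = FALSE) {
  d <- dim(x)
  m <- array(x, c(d[1], d[2] * d[3], d[4]))
  out <- apply(m, 3, rowMeans)
  out <- matrix(out, nrow = d[1])
  list(out = out, cache = d)
}

#' @export
nn_backward.gap <- function(layer, cache, dout) {
  d <- cache
  dx <- array(0, d)
  scale <- 1 / (d[2] * d[3])
  for (n in seq_len(d[4])) {
    dx[, , , n] <- array(rep(dout[, n] * scale, d[2] * d[3]), d[1:3])
  }
  list(dx = dx, grads = list())
}

# ---- linear ----------------------------------------------------------------

linear <- function(din, dout_, bias = TRUE, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / din)
  params <- list(W = matrix(stats::rnorm(dout_ * din, 0, init_sd), nrow = dout_))
  if (bias) params$b <- numeric(dout_)
  nn_layer("linear", params, din = din, dout = dout_)
}

#' @export
nn_forward.linear <- function(layer, x, training = FALSE) {
  out <- layer$params$W %*% x
  if (!is.null(layer$params$b)) out <- out + layer$params$b
  list(out = out, cache = x)
}

#' @export
nn_backward.linear <- function(layer, cache, dout) {
  grads <- list(W = dout %*% t(cache))
  if (!is.null(layer$params$b)) grads$b <- rowSums(dout)
  list(dx = t(layer$params$W) %*% dout, grads = grads)
}

# ---- layer norm (tokens [d, T, N], normalized over d) ----------------------

layer_norm <- function(d, eps = 1e-6) {
  nn_layer("layernorm", list(gamma = rep(1, d), beta = numeric(d)),
           d = d, eps = eps)
}

#' @export
nn_forward.layernorm <- function(layer, x, training = FALSE) {
  dims <- dim(x)
  m <- matrix(x, nrow = layer$d)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (m - rep(mu, each = layer$d)) * rep(invstd, each = layer$d)
  out <- array(layer$params$gamma * xhat + layer$params$beta, dims)
  list(out = out, cache = list(xhat = xhat, invstd = invstd, dims = dims))
}

#' @export
nn_backward.layernorm <- function(layer, cache, dout) {
  d <- layer$d
  dm <- matrix(dout, nrow = d)
  xhat <- cache$xhat
  grads <- list(gamma = rowSums(dm * xhat), beta = rowSums(dm))
  dxhat <- dm * layer$params$gamma
  cm1 <- colMeans(dxhat)
  cm2 <- colMeans(dxhat * xhat)
  dx <- rep(cache$invstd, each = d) *
    (dxhat - rep(cm1, each = d) - xhat * rep(cm2, each = d))
  list(dx = array(dx, cache$dims), grads = grads)
}

# ---- multi-head self-attention --------------------------------------------

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

multihead_attention <- function(d, n_heads, init_sd = 0.02) {
  assert_that(d %% n_heads == 0, "embedding dim must be divisible by n_heads")
  mk <- function() matrix(stats::rnorm(d * d, 0, init_sd), d, d)
  st <- new.env(parent = emptyenv())
  nn_layer("mha",
           list(Wq = mk(), Wk = mk(), Wv = mk(), Wo = mk(),
                bq = numeric(d), bk = numeric(d), bv = numeric(d),
                bo = numeric(d)),
           d = d, n_heads = n_heads, dh = d %/% n_heads, state = st)
}

#' @export
nn_forward.mha <- function(layer, x, training = FALSE) {
  dims <- dim(x); d <- layer$d; T_ <- dims[2]; N <- dims[3]
  h <- layer$n_heads; dh <- layer$dh
  p <- layer$params
  out <- array(0, dims)
  caches <- vector("list", N)
  attn <- array(0, c(h, T_, T_, N))
  for (n in seq_len(N)) {
    X <- x[, , n, drop = TRUE]; dim(X) <- c(d, T_)
    Q <- p$Wq %*% X + p$bq; K <- p$Wk %*% X + p$bk; V <- p$Wv %*% X + p$bv
    O <- matrix(0, d, T_)
    As <- vector("list", h)
    for (i in seq_len(h)) {
      rows <- ((i - 1) * dh + 1):(i * dh)
      S <- crossprod(Q[rows, , drop = FALSE], K[rows, , drop = FALSE]) / sqrt(dh)
      A <- row_softmax(S)
      As[[i]] <- A
      attn[i, , , n] <- A
      O[rows, ] <- V[rows, , drop = FALSE] %*% t(A)
    }
    out[, , n] <- p$Wo %*% O + p$bo
    caches[[n]] <- list(X = X, Q = Q, K = K, V = V, O = O, As = As)
  }
  layer$state$attention <- attn
  list(out = out, cache = list(per_sample = caches, dims = dims))
}

#' @export
nn_backward.mha <- function(layer, cache, dout) {
  dims <- cache$dims; d <- layer$d; T_ <- dims[2]; N <- dims[3]
  h <- layer$n_heads; dh <- layer$dh
  p <- layer$params
  g <- lapply(p, function(z) z * 0)
  dx <- array(0, dims)
  for (n in seq_len(N)) {
    cc <- cache$per_sample[[n]]
    dO_out <- dout[, , n, drop = TRUE]; dim(dO_out) <- c(d, T_)
    g$Wo <- g$Wo + dO_out %*% t(cc$O)
    g$bo <- g$bo + rowSums(dO_out)
    dO <- t(p$Wo) %*% dO_out
    dQ <- matrix(0, d, T_); dK <- matrix(0, d, T_); dV <- matrix(0, d, T_)
    for (i in seq_len(h)) {
      rows <- ((i - 1) * dh + 1):(i * dh)
      A <- cc$As[[i]]
      Vh <- cc$V[rows, , drop = FALSE]
      dOh <- dO[rows, , drop = FALSE]
      dV[rows, ] <- dOh %*% A
      dA <- t(crossprod(Vh, dOh))                  # [T, T]
      dS <- (dA - rowSums(dA * A)) * A
      dQ[rows, ] <- cc$K[rows, , drop = FALSE] %*% t(dS) / sqrt(dh)
      dK[rows, ] <- cc$Q[rows, , drop = FALSE] %*% dS / sqrt(dh)
    }
    g$Wq <- g$Wq + dQ %*% t(cc$X); g$bq <- g$bq + rowSums(dQ)
    g$Wk <- g$Wk + dK %*% t(cc$X); g$bk <- g$bk + rowSums(dK)
    g$Wv <- g$Wv + dV %*% t(cc$X); g$bv <- g$bv + rowSums(dV)
    dx[, , n] <- t(p$Wq) %*% dQ + t(p$Wk) %*% dK + t(p$Wv) %*% dV
  }
  list(dx = dx, grads = g)
}

# ---- sequential composite --------------------------------------------------

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  nn_layer("seq", layers = layers)
}

#' @export
nn_forward.seq <- function(layer, x, training = FALSE) {
  caches <- vector("list", length(layer$layers))
  for (i in seq_along(layer$layers)) {
    fw <- nn_forward(layer$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, cache = caches)
}

#' @export
nn_backward.seq <- function(layer, cache, dout) {
  grads <- vector("list", length(layer$layers))
  for (i in rev(seq_along(layer$layers))) {
    bw <- nn_backward(layer$layers[[i]], cache[[i]], dout)
    dout <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dout, grads = list(layers = grads))
}

# ---- ResNet bottleneck -----------------------------------------------------

# 1x1 (stride s) -> BN -> ReLU -> 3x3 -> BN -> ReLU -> 1x1 -> BN, plus an
# identity or 1x1-projection shortcut, final ReLU. The stride sits on the
# first 1x1 convolution (and the projection), matching a downsampling scheme
# of 1x1 convolutions with stride 2 at each stage entry.
bottleneck <- function(cin, cmid, cout, stride = 1) {
  bn_last <- batchnorm2d(cout)
  # zero-init the last BN gain so every residual block starts as the identity
  # mapping: the standard conditioning trick for training deep residual nets
  bn_last$params$gamma <- bn_last$params$gamma * 0
  main <- list(conv2d(cin, cmid, 1, stride = stride), batchnorm2d(cmid), relu(),
               conv2d(cmid, cmid, 3, pad = 1), batchnorm2d(cmid), relu(),
               conv2d(cmid, cout, 1), bn_last)
  proj <- if (cin != cout || stride != 1) {
    list(conv2d(cin, cout, 1, stride = stride, role = "projection"),
         batchnorm2d(cout))
  } else NULL
  nn_layer("bottleneck", layers = c(main, proj),
           n_main = length(main), has_proj = !is.null(proj))
}

#' @export
nn_forward.bottleneck <- function(layer, x, training = FALSE) {
  caches <- vector("list", length(layer$layers))
  h <- x
  for (i in seq_len(layer$n_main)) {
    fw <- nn_forward(layer$layers[[i]], h, training)
    h <- fw$out; caches[[i]] <- fw$cache
  }
  s <- x
  if (layer$has_proj) {
    for (i in (layer$n_main + 1):length(layer$layers)) {
      fw <- nn_forward(layer$layers[[i]], s, training)
      s <- fw$out; caches[[i]] <- fw$cache
    }
  }
  pre <- h + s
  mask <- pre > 0
  list(out = pre * mask, cache = list(caches = caches, mask = mask))
}

#' @export
nn_backward.bottleneck <- function(layer, cache, dout) {
  dpre <- dout * cache$mask
  grads <- vector("list", length(layer$layers))
  dh <- dpre
  for (i in rev(seq_len(layer$n_main))) {
    bw <- nn_backward(layer$layers[[i]], cache$caches[[i]], dh)
    dh <- bw$dx; grads[[i]] <- bw$grads
  }
  if (layer$has_proj) {
    ds <- dpre
    for (i in rev((layer$n_main + 1):length(layer$layers))) {
      bw <- nn_backward(layer$layers[[i]], cache$caches[[i]], ds)
      ds <- bw$dx; grads[[i]] <- bw$grads
    }
    dx <- dh + ds
  } else {
    dx <- dh + dpre
  }
  list(dx = dx, grads = list(layers = grads))
}

# ---- transformer encoder layer (post-LN) -----------------------------------

transformer_layer <- function(d, n_heads, ff_dim = 4 * d, dropout_rate = 0.1) {
  nn_layer("transformer_layer",
           layers = list(mha = multihead_attention(d, n_heads),
                         drop1 = dropout(dropout_rate),
                         ln1 = layer_norm(d),
                         ff1 = linear(d, ff_dim),
                         ff2 = linear(ff_dim, d),
                         drop2 = dropout(dropout_rate),
                         ln2 = layer_norm(d)),
           d = d, ff_dim = ff_dim)
}

#' @export
nn_forward.transformer_layer <- function(layer, x, training = FALSE) {
  L <- layer$layers
  dims <- dim(x)
  a <- nn_forward(L$mha, x, training)
  a_d <- nn_forward(L$drop1, a$out, training)
  h1 <- nn_forward(L$ln1, x + a_d$out, training)
  m <- matrix(h1$out, nrow = layer$d)
  f1 <- nn_forward(L$ff1, m, training)
  fr <- nn_forward(relu(), f1$out, training)
  f2 <- nn_forward(L$ff2, fr$out, training)
  f_d <- nn_forward(L$drop2, array(f2$out, dims), training)
  out <- nn_forward(L$ln2, h1$out + f_d$out, training)
  list(out = out$out,
       cache = list(mha = a$cache, drop1 = a_d$cache, ln1 = h1$cache,
                    ff1 = f1$cache, relu_mask = fr$cache, ff2 = f2$cache,
                    drop2 = f_d$cache, ln2 = out$cache, dims = dims))
}

#' @export
nn_backward.transformer_layer <- function(layer, cache, dout) {
  L <- layer$layers
  dims <- cache$dims
  b_ln2 <- nn_backward(L$ln2, cache$ln2, dout)
  d_h1a <- b_ln2$dx                                 # into h1 + f_d
  b_d2 <- nn_backward(L$drop2, cache$drop2, d_h1a)
  df2 <- matrix(b_d2$dx, nrow = layer$d)
  b_f2 <- nn_backward(L$ff2, cache$ff2, df2)
  dfr <- b_f2$dx * cache$relu_mask
  b_f1 <- nn_backward(L$ff1, cache$ff1, dfr)
  d_h1 <- d_h1a + array(b_f1$dx, dims)
  b_ln1 <- nn_backward(L$ln1, cache$ln1, d_h1)
  d_xa <- b_ln1$dx                                  # into x + a_d
  b_d1 <- nn_backward(L$drop1, cache$drop1, d_xa)
  b_mha <- nn_backward(L$mha, cache$mha, b_d1$dx)
  dx <- d_xa + b_mha$dx
  grads <- list(layers = list(mha = b_mha$grads, drop1 = list(),
                              ln1 = b_ln1$grads, ff1 = b_f1$grads,
                              ff2 = b_f2$grads, drop2 = list(),
                              ln2 = b_ln2$grads))
  list(dx = dx, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

sgd_init <- function(layer) {
  v <- lapply(layer$params, function(p) p * 0)
  if (!is.null(layer$layers)) v$layers <- lapply(layer$layers, sgd_init)
  v
}

# sum of squared entries of a gradient tree (for global-norm clipping)
grad_sq_sum <- function(grads) {
  s <- 0
  for (nm in setdiff(names(grads), "layers")) {
    g <- grads[[nm]]
    if (is.numeric(g)) s <- s + sum(g^2)
  }
  if (!is.null(grads$layers)) {
    for (gi in grads$layers) if (!is.null(gi)) s <- s + grad_sq_sum(gi)
  }
  s
}

scale_grads <- function(grads, k) {
  for (nm in setdiff(names(grads), "layers")) {
    if (is.numeric(grads[[nm]])) grads[[nm]] <- grads[[nm]] * k
  }
  if (!is.null(grads$layers)) {
    grads$layers <- lapply(grads$layers, function(gi)
      if (is.null(gi)) NULL else scale_grads(gi, k))
  }
  grads
}

# clip the global gradient norm to max_norm (no-op when already smaller)
clip_grads <- function(grads, max_norm) {
  nrm <- sqrt(grad_sq_sum(grads))
  if (is.finite(nrm) && nrm > max_norm) grads <- scale_grads(grads, max_norm / nrm)
  grads
}

sgd_step <- function(layer, grads, vel, lr, momentum = 0.9) {
  for (nm in names(layer$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    vel[[nm]] <- momentum * vel[[nm]] - lr * g
    layer$params[[nm]] <- layer$params[[nm]] + vel[[nm]]
  }
  if (!is.null(layer$layers)) {
    for (i in seq_along(layer$layers)) {
      gi <- grads$layers[[i]]
      if (is.null(gi)) next
      st <- sgd_step(layer$layers[[i]], gi, vel$layers[[i]], lr, momentum)
      layer$layers[[i]] <- st$layer
      vel$layers[[i]] <- st$vel
    }
  }
  list(layer = layer, vel = vel)
}

# ---- losses ----------------------------------------------------------------

softmax_cols <- function(logits) {
  E <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(E, 2, colSums(E), "/")
}

# Cross-entropy over logits [K, N] with integer labels in 1..K.
# Returns loss and dlogits (mean over the batch).
cross_entropy <- function(logits, labels) {
  P <- softmax_cols(logits)
  N <- ncol(logits)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(P[cbind(labels, seq_len(N))], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}

# Sinusoidal timestep embedding (DDPM-style), dim must be even.
time_embedding <- function(t, dim) {
  half <- dim / 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  emb <- outer(freqs, t)                            # [half, n]
  rbind(sin(emb), cos(emb))
}
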