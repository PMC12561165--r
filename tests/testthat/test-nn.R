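# The layer framework: every backward pass is checked against finite
# differences, including composites, plus mode semantics (dropout, BN).

test_that("convolutional and pooling layers backpropagate exactly", {
  withr::with_seed(42, {
    x <- array(rnorm(3 * 8 * 8 * 2), c(3, 8, 8, 2))
    expect_lt(fd_check_layer(rtcn:::conv2d(3, 4, 3, stride = 2, pad = 1,
                                           bias = TRUE), x), 1e-6)
    expect_lt(fd_check_layer(rtcn:::batchnorm2d(3), x), 1e-6)
    expect_lt(fd_check_layer(rtcn:::maxpool2d(), x), 1e-6)
    expect_lt(fd_check_layer(rtcn:::global_avg_pool(), x), 1e-6)
    expect_lt(fd_check_layer(rtcn:::bottleneck(3, 2, 8, stride = 2), x), 1e-6)
    x1 <- array(rnorm(2 * 20 * 3), c(2, 20, 3))
    expect_lt(fd_check_layer(rtcn:::conv1d(2, 4, 5), x1), 1e-6)
  })
})

test_that("dense, norm and attention layers backpropagate exactly", {
  withr::with_seed(43, {
    expect_lt(fd_check_layer(rtcn:::linear(6, 5), matrix(rnorm(24), 6)), 1e-6)
    xt <- array(rnorm(8 * 5 * 2), c(8, 5, 2))
    expect_lt(fd_check_layer(rtcn:::layer_norm(8), xt), 1e-6)
    expect_lt(fd_check_layer(rtcn:::multihead_attention(8, 2), xt), 1e-6)
    expect_lt(fd_check_layer(rtcn:::transformer_layer(8, 2, 16,
                                                      dropout_rate = 0), xt),
              1e-6)
  })
})

test_that("nested composite parameters receive correct gradients", {
  withr::with_seed(44, {
    net <- rtcn:::nn_seq(rtcn:::conv2d(2, 3, 3, pad = 1), rtcn:::batchnorm2d(3),
                         rtcn:::relu(), rtcn:::maxpool2d(),
                         rtcn:::global_avg_pool())
    x <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
    fw <- rtcn:::nn_forward(net, x, TRUE)
    R <- matrix(rnorm(length(fw$out)), nrow(fw$out))
    bw <- rtcn:::nn_backward(net, fw$cache, R)
    W <- net$layers[[1]]$params$W
    eps <- 1e-5
    for (i in sample(length(W), 5)) {
      np <- net; np$layers[[1]]$params$W[i] <- W[i] + eps
      nm <- net; nm$layers[[1]]$params$W[i] <- W[i] - eps
      gn <- (sum(rtcn:::nn_forward(np, x, TRUE)$out * R) -
               sum(rtcn:::nn_forward(nm, x, TRUE)$out * R)) / (2 * eps)
      expect_equal(bw$grads$layers[[1]]$W[i], gn, tolerance = 1e-5)
    }
  })
})

test_that("dropout is inverted at train time and inert at inference", {
  withr::with_seed(45, x <- array(rnorm(4000), c(10, 400)))
  l <- rtcn:::dropout(0.3)
  expect_identical(rtcn:::nn_forward(l, x, training = FALSE)$out, x)
  withr::with_seed(46, out <- rtcn:::nn_forward(l, x, training = TRUE)$out)
  expect_gt(sum(out == 0), 0)
  expect_equal(mean(out), mean(x), tolerance = 0.05)
})

test_that("batch norm switches between batch and running statistics", {
  withr::with_seed(47, x <- array(rnorm(3 * 4 * 4 * 8, 5, 2), c(3, 4, 4, 8)))
  l <- rtcn:::batchnorm2d(3)
  tr <- rtcn:::nn_forward(l, x, training = TRUE)$out
  m <- matrix(tr, 3)
  expect_equal(rowMeans(m), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(m, 1, stats::sd), rep(1, 3), tolerance = 0.01)
  # inference uses the (momentum-updated) running statistics, not batch ones
  inf <- rtcn:::nn_forward(l, x, training = FALSE)$out
  expect_gt(max(abs(inf - tr)), 0.1)
})

test_that("softmax cross-entropy matches direct computation", {
  withr::with_seed(48, logits <- matrix(rnorm(12), 4))
  y <- c(2, 1, 4)
  ce <- rtcn:::cross_entropy(logits, y)
  P <- apply(logits, 2, function(z) exp(z) / sum(exp(z)))
  expect_equal(ce$loss, -mean(log(P[cbind(y, 1:3)])), tolerance = 1e-12)
  expect_equal(colSums(ce$dlogits), rep(0, 3), tolerance = 1e-12)
})

test_that("gradient clipping preserves direction and caps the global norm", {
  g <- list(W = matrix(3, 2, 2), layers = list(list(b = rep(4, 5))))
  n0 <- sqrt(rtcn:::grad_sq_sum(g))
  cl <- rtcn:::clip_grads(g, 1)
  expect_equal(sqrt(rtcn:::grad_sq_sum(cl)), 1, tolerance = 1e-12)
  expect_equal(cl$W / g$W, matrix(1 / n0, 2, 2), tolerance = 1e-12)
  expect_identical(rtcn:::clip_grads(g, 1e6), g)
})
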