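# Architecture contracts of the ResNet-Transformer cascade.

scaled_cfg <- function(...) {
  rtcn_config(n_classes = 4, input_side = 32, base_width = 4,
              compressed_dim = 16, n_layers = 1, n_heads = 2, ff_dim = 32,
              dropout_rate = 0, token_dropout = 0, ...)
}

test_that("the backbone stage plan reproduces the standard ResNet-50 table", {
  plan <- backbone_plan(rtcn_config())
  expect_equal(plan$repeats, c(3, 4, 6, 3))
  expect_equal(plan$mid_channels, c(64, 128, 256, 512))
  expect_equal(plan$out_channels, c(256, 512, 1024, 2048))
  expect_true(all(plan$kernels == "1x1,3x3,1x1"))
})

test_that("weight-layer count is 50 and scales with nothing", {
  m <- withr::with_seed(1, rtcn_model(scaled_cfg()))
  expect_equal(count_weight_layers(m), 50)
})

test_that("token and head contracts hold on a scaled model", {
  withr::with_seed(2, {
    m <- rtcn_model(scaled_cfg())
    x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
    fw <- rtcn_forward(m, x, capture = TRUE)
    # 32/32 = 1 spatial cell -> 1 token + class token
    expect_equal(dim(fw$featmap), c(128, 1, 1, 2))
    expect_equal(dim(fw$encoded), c(16, 2, 2))
    expect_equal(colSums(fw$probs), c(1, 1), tolerance = 1e-6)
    expect_true(all(fw$probs >= 0))
    # attention rows sum to 1
    att <- attention_maps(m)[[1]]
    expect_equal(apply(att, c(1, 2, 4), sum), array(1, c(2, 2, 2)),
                 tolerance = 1e-6)
  })
})

test_that("compress_and_tokenize preserves spatial structure", {
  withr::with_seed(3, {
    cfg <- rtcn_config(n_classes = 4, input_side = 64, base_width = 4,
                       compressed_dim = 16, n_layers = 1, n_heads = 2,
                       ff_dim = 32, dropout_rate = 0, token_dropout = 0)
    m <- rtcn_model(cfg)
    fmap <- array(rnorm(128 * 2 * 2 * 1), c(128, 2, 2, 1))
    tok <- compress_and_tokenize(m, fmap)
    expect_equal(dim(tok), c(16, 5, 1))        # 4 spatial tokens + class token
    # constant feature map with zeroed positional embeddings: identical tokens
    m0 <- m; m0$params$pos[] <- 0
    fconst <- array(rep(rnorm(128), 4), c(128, 2, 2, 1))
    tok0 <- compress_and_tokenize(m0, fconst)
    for (k in 3:5) expect_equal(tok0[, k, 1], tok0[, 2, 1], tolerance = 1e-12)
    # permuting spatial positions permutes tokens identically (pos zeroed)
    perm <- c(3, 1, 4, 2)
    fperm <- array(array(fmap, c(128, 4))[, perm], c(128, 2, 2, 1))
    tokp <- compress_and_tokenize(m0, fperm)
    tok_base <- compress_and_tokenize(m0, fmap)
    expect_equal(tokp[, -1, 1], tok_base[, perm + 1, 1], tolerance = 1e-12)
    expect_error(compress_and_tokenize(m, array(0, c(64, 2, 2, 1))), "channel")
  })
})

test_that("a transformer layer with zeroed mixing reduces to layer norm", {
  withr::with_seed(4, {
    tl <- rtcn:::transformer_layer(8, 2, 16, dropout_rate = 0)
    tl$layers$mha$params$Wo[] <- 0; tl$layers$mha$params$bo[] <- 0
    tl$layers$ff2$params$W[] <- 0; tl$layers$ff2$params$b[] <- 0
    x <- array(rnorm(8 * 3 * 1), c(8, 3, 1))
    out <- rtcn:::nn_forward(tl, x)$out
    ln <- rtcn:::layer_norm(8)
    expect_equal(out, rtcn:::nn_forward(ln, x)$out, tolerance = 1e-4)
  })
})

test_that("classification head follows the softmax contracts", {
  withr::with_seed(5, {
    m <- rtcn_model(scaled_cfg())
    enc <- array(rnorm(16 * 2 * 3), c(16, 2, 3))
    p <- classify_tokens(m, enc)
    expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
    # zero weights and bias: uniform probabilities
    m0 <- m; m0$layers$head$params$W[] <- 0; m0$layers$head$params$b[] <- 0
    expect_equal(classify_tokens(m0, enc), matrix(0.25, 4, 3), tolerance = 1e-12)
    # shifting all logits leaves probabilities unchanged
    mshift <- m; mshift$layers$head$params$b <- mshift$layers$head$params$b + 7
    expect_equal(classify_tokens(mshift, enc), p, tolerance = 1e-9)
  })
})

test_that("inference is deterministic and batching is consistent", {
  withr::with_seed(6, {
    m <- rtcn_model(scaled_cfg())
    x <- array(rnorm(3 * 32 * 32 * 2), c(3, 32, 32, 2))
    p1 <- rtcn_predict(m, x)
    p2 <- rtcn_predict(m, x)
    expect_identical(p1, p2)
    s1 <- rtcn_predict(m, x[, , , 1])
    s2 <- rtcn_predict(m, x[, , , 2])
    expect_equal(cbind(s1, s2), p1, tolerance = 1e-6)
  })
})

test_that("ablation variants are constructible from the same config surface", {
  withr::with_seed(7, {
    x <- array(rnorm(3 * 32 * 32), c(3, 32, 32, 1))
    mr <- rtcn_model(scaled_cfg(variant = "resnet_only"))
    pr <- rtcn_predict(mr, x)
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    mv <- rtcn_model(scaled_cfg(variant = "vit_only", patch_size = 8))
    pv <- rtcn_predict(mv, x)
    expect_equal(sum(pv), 1, tolerance = 1e-6)
    expect_equal(mv$n_tokens, 16)
  })
})

test_that("config invariants are enforced", {
  expect_error(rtcn_config(compressed_dim = 30, n_heads = 8), "divisible")
  expect_error(rtcn_config(input_side = 100), "multiple of 32")
  expect_error(rtcn_config(variant = "bogus"), "variant")
})
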