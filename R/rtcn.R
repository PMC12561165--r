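# The ResNet-50 -> token-compression -> Transformer-encoder cascade.
#
# Full five-stage ResNet-50 backbone (bottleneck repeats 3/4/6/3) producing,
# for a 3 x 224 x 224 input, a 7 x 7 feature map with 2048 channels; a 1 x 1
# convolution compresses channels to d (512 by default); the map is flattened
# to 49 spatial tokens, learnable per-position embeddings are added, a
# learnable class token is prepended, and a 3-layer / 8-head Transformer
# encoder plus a fully connected softmax head on the class-token state
# produces the 12-way class probabilities. ResNet-only and ViT-only ablation
# variants are constructible from the same configuration surface.

#' RTCN model configuration
#'
#' @param n_classes number of output classes (12: 11 MI locations + HC).
#' @param input_side input image side; the backbone downsamples by 32, so 224
#'   yields the 7x7 token grid.
#' @param base_width channels of the stem convolution (64 for the standard
#'   ResNet-50; smaller values give scaled-down models with the same shape
#'   plan).
#' @param compressed_dim token embedding dim d after the 1x1 compression
#'   (presets of interest: 128, 256, 512, 1024, 1536).
#' @param n_layers,n_heads Transformer encoder depth and head count.
#' @param ff_dim encoder feed-forward width (default 4 d).
#' @param dropout_rate dropout inside the encoder (training only).
#' @param token_dropout dropout on the token sequence before the encoder.
#' @param variant \code{"full"}, \code{"resnet_only"} (global-pool head, no
#'   encoder) or \code{"vit_only"} (patchify the image directly into tokens).
#' @param patch_size patch side for the ViT-only variant.
#' @return Object of class \code{rtcn_config}.
#' @export
rtcn_config <- function(n_classes = 12, input_side = 224, base_width = 64,
                        compressed_dim = 512, n_layers = 3, n_heads = 8,
                        ff_dim = 4 * compressed_dim, dropout_rate = 0.1,
                        token_dropout = 0.1, variant = "full",
                        patch_size = 32) {
  assert_that(compressed_dim %% n_heads == 0,
              "compressed_dim must be divisible by n_heads")
  assert_that(input_side %% 32 == 0, "input_side must be a multiple of 32")
  assert_that(variant %in% c("full", "resnet_only", "vit_only"),
              "unknown variant")
  if (variant == "vit_only") {
    assert_that(input_side %% patch_size == 0,
                "input_side must be a multiple of patch_size")
  }
  structure(list(n_classes = n_classes, input_side = input_side,
                 base_width = base_width, compressed_dim = compressed_dim,
                 n_layers = n_layers, n_heads = n_heads, ff_dim = ff_dim,
                 dropout_rate = dropout_rate, token_dropout = token_dropout,
                 variant = variant, patch_size = patch_size),
            class = "rtcn_config")
}

#' Build the ResNet-50 backbone
#'
#' Stem 7x7 convolution (stride 2) + 3x3 max pool (stride 2), then four
#' bottleneck stages with repeats 3, 4, 6, 3 and output channels 4x the
#' stage's mid width (256/512/1024/2048 at \code{base_width = 64}); stages
#' 2-4 downsample by 2 via strided 1x1 convolutions. 49 convolutional weight
#' layers in total (the fully connected head makes 50).
#'
#' @param config an [rtcn_config()].
#' @return A sequential layer stack (class \code{seq}/\code{nn_layer}).
#' @export
build_backbone <- function(config) {
  b <- config$base_width
  layers <- list(conv2d(3, b, 7, stride = 2, pad = 3),
                 batchnorm2d(b), relu(), maxpool2d(3, 2, 1))
  repeats <- c(3, 4, 6, 3)
  mids <- b * c(1, 2, 4, 8)
  cin <- b
  for (g in 1:4) {
    cmid <- mids[g]; cout <- 4 * cmid
    stride <- if (g == 1) 1 else 2
    for (r in seq_len(repeats[g])) {
      layers <- c(layers, list(bottleneck(cin, cmid, cout,
                                          stride = if (r == 1) stride else 1)))
      cin <- cout
    }
  }
  nn_seq(layers)
}

backbone_out_channels <- function(config) 32 * config$base_width

#' Construct an RTCN model
#'
#' Initializes all weights (He fan-out for convolutions; positional
#' embeddings and class token from N(0, 0.02^2)); trained from scratch, no
#' pretrained weights. Seed the RNG before calling for reproducible
#' initialization.
#'
#' @param config an [rtcn_config()].
#' @return Object of classes \code{rtcn}/\code{nn_layer}.
#' @export
rtcn_model <- function(config) {
  d <- config$compressed_dim
  if (config$variant == "resnet_only") {
    cfin <- backbone_out_channels(config)
    return(nn_layer("rtcn", params = list(),
                    layers = list(backbone = build_backbone(config),
                                  head = linear(cfin, config$n_classes)),
                    config = config))
  }
  if (config$variant == "vit_only") {
    T_ <- (config$input_side / config$patch_size)^2
    enc <- nn_seq(lapply(seq_len(config$n_layers), function(i)
      transformer_layer(d, config$n_heads, config$ff_dim, config$dropout_rate)))
    return(nn_layer("rtcn",
                    params = list(pos = matrix(stats::rnorm(d * T_, 0, 0.02), d, T_),
                                  cls = stats::rnorm(d, 0, 0.02)),
                    layers = list(embed = linear(3 * config$patch_size^2, d),
                                  encoder = enc,
                                  head = linear(d, config$n_classes)),
                    config = config, n_tokens = T_))
  }
  side_out <- config$input_side / 32
  T_ <- side_out^2
  cfin <- backbone_out_channels(config)
  enc <- nn_seq(lapply(seq_len(config$n_layers), function(i)
    transformer_layer(d, config$n_heads, config$ff_dim, config$dropout_rate)))
  nn_layer("rtcn",
           params = list(pos = matrix(stats::rnorm(d * T_, 0, 0.02), d, T_),
                         cls = stats::rnorm(d, 0, 0.02)),
           layers = list(backbone = build_backbone(config),
                         compress = conv2d(cfin, d, 1, bias = TRUE),
                         tok_drop = dropout(config$token_dropout),
                         encoder = enc,
                         head = linear(d, config$n_classes)),
           config = config, n_tokens = T_)
}

# flatten a [d, s, s, N] compressed map into [d, T, N] tokens (spatial
# positions in array order: row index fastest)
flatten_tokens <- function(cmap) {
  d <- dim(cmap)
  array(cmap, c(d[1], d[2] * d[3], d[4]))
}

patchify <- function(x, p) {
  d <- dim(x)                                      # [3, side, side, N]
  side <- d[2]; np <- side / p; N <- d[4]
  T_ <- np * np
  out <- array(0, c(3 * p * p, T_, N))
  k <- 0
  for (pj in seq_len(np)) for (pi in seq_len(np)) {
    k <- k + 1
    blk <- x[, ((pi - 1) * p + 1):(pi * p), ((pj - 1) * p + 1):(pj * p), ,
             drop = FALSE]
    out[, k, ] <- array(blk, c(3 * p * p, N))
  }
  out
}

#' Add positional embeddings and the class token to spatial tokens
#'
#' @param model an [rtcn_model()].
#' @param tokens array \code{[d, T, N]} of spatial tokens.
#' @param add_pos add the learnable per-position embedding.
#' @return Array \code{[d, T + 1, N]}; position 1 is the class token.
#' @export
prepend_class_token <- function(model, tokens, add_pos = TRUE) {
  d <- dim(tokens)
  if (add_pos) tokens <- tokens + array(model$params$pos, d)
  out <- array(0, c(d[1], d[2] + 1, d[3]))
  out[, 1, ] <- model$params$cls
  out[, -1, ] <- tokens
  out
}

#' Compress a backbone feature map into the token sequence
#'
#' 1x1 convolution from the backbone's channel width down to the embedding
#' dim, row-major flatten of the spatial grid into tokens, addition of the
#' learnable per-position embedding, and prepending of the class token.
#'
#' @param model a full-variant [rtcn_model()].
#' @param featmap array \code{[C, s, s, N]} from [build_backbone()].
#' @param training apply token dropout.
#' @return Token array \code{[d, T + 1, N]} (50 x 512 columns-per-sample at
#'   the defaults); position 1 is the class token.
#' @export
compress_and_tokenize <- function(model, featmap, training = FALSE) {
  assert_that(model$config$variant == "full", "needs the full cascade variant")
  if (length(dim(featmap)) == 3) dim(featmap) <- c(dim(featmap), 1)
  assert_that(dim(featmap)[1] == model$layers$compress$cin,
              "feature-map channel count does not match the model")
  cp <- nn_forward(model$layers$compress, featmap, training)
  seqin <- prepend_class_token(model, flatten_tokens(cp$out))
  nn_forward(model$layers$tok_drop, seqin, training)$out
}

#' Run the Transformer encoder over a token sequence
#'
#' Three (by default) standard post-norm encoder layers with multi-head
#' self-attention; the per-layer attention matrices are retained for
#' [attention_maps()].
#'
#' @param model a [rtcn_model()] with an encoder.
#' @param tokens array \code{[d, T + 1, N]}.
#' @param training training mode.
#' @return Encoded array of the same shape.
#' @export
transformer_encode <- function(model, tokens, training = FALSE) {
  nn_forward(model$layers$encoder, tokens, training)$out
}

#' Classify an encoded token sequence
#'
#' Fully connected layer on the class-token state followed by softmax.
#'
#' @param model a [rtcn_model()].
#' @param encoded encoder output \code{[d, T + 1, N]}.
#' @return Probability matrix \code{[n_classes, N]}; columns sum to 1.
#' @export
classify_tokens <- function(model, encoded) {
  clsst <- matrix(encoded[, 1, ], nrow = model$config$compressed_dim)
  softmax_cols(nn_forward(model$layers$head, clsst)$out)
}

#' RTCN forward pass
#'
#' Runs the configured variant end to end and returns logits and class
#' probabilities (softmax over \code{n_classes}); with \code{capture = TRUE}
#' all intermediate caches plus the backbone feature map and token states are
#' returned, which [rtcn_backward()] and Grad-CAM consume.
#'
#' @param model an [rtcn_model()].
#' @param x input array \code{[3, side, side]} or batch \code{[3, side, side, N]}.
#' @param training training mode (dropout active, batch-norm batch
#'   statistics); inference is deterministic.
#' @param capture keep caches for a subsequent backward pass.
#' @return List with \code{logits} \code{[K, N]}, \code{probs} \code{[K, N]},
#'   and if captured: \code{featmap}, \code{tokens}, \code{encoded},
#'   \code{caches}.
#' @export
rtcn_forward <- function(model, x, training = FALSE, capture = training) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  cfg <- model$config
  caches <- list()
  if (cfg$variant == "resnet_only") {
    bb <- nn_forward(model$layers$backbone, x, training)
    gp <- nn_forward(global_avg_pool(), bb$out, training)
    hd <- nn_forward(model$layers$head, gp$out, training)
    logits <- hd$out
    if (capture) caches <- list(backbone = bb$cache, gap_dims = dim(bb$out),
                                head = hd$cache, featmap = bb$out)
  } else if (cfg$variant == "vit_only") {
    tok_raw <- patchify(x, cfg$patch_size)
    d3 <- dim(tok_raw)
    emb <- nn_forward(model$layers$embed, matrix(tok_raw, nrow = d3[1]), training)
    tokens <- array(emb$out, c(cfg$compressed_dim, d3[2], d3[3]))
    seqin <- prepend_class_token(model, tokens)
    enc <- nn_forward(model$layers$encoder, seqin, training)
    clsst <- matrix(enc$out[, 1, ], nrow = cfg$compressed_dim)
    hd <- nn_forward(model$layers$head, clsst, training)
    logits <- hd$out
    if (capture) caches <- list(embed = emb$cache, tok_dims = d3,
                                encoder = enc$cache, head = hd$cache,
                                encoded = enc$out)
  } else {
    bb <- nn_forward(model$layers$backbone, x, training)
    cp <- nn_forward(model$layers$compress, bb$out, training)
    tokens <- flatten_tokens(cp$out)
    seqin <- prepend_class_token(model, tokens)
    dp <- nn_forward(model$layers$tok_drop, seqin, training)
    enc <- nn_forward(model$layers$encoder, dp$out, training)
    clsst <- matrix(enc$out[, 1, ], nrow = cfg$compressed_dim)
    hd <- nn_forward(model$layers$head, clsst, training)
    logits <- hd$out
    if (capture) {
      caches <- list(backbone = bb$cache, compress = cp$cache,
                     cmap_dims = dim(cp$out), tok_drop = dp$cache,
                     encoder = enc$cache, head = hd$cache,
                     featmap = bb$out, tokens = tokens, encoded = enc$out)
    }
  }
  out <- list(logits = logits, probs = softmax_cols(logits))
  if (capture) out <- c(out, caches)
  out
}

#' RTCN backward pass
#'
#' Backpropagates \code{dlogits} through a captured forward pass, returning a
#' gradient tree aligned with the model for [sgd] updates, plus the gradient
#' at the backbone feature map (used by Grad-CAM).
#'
#' @param model an [rtcn_model()].
#' @param fw result of \code{rtcn_forward(..., capture = TRUE)}.
#' @param dlogits gradient at the logits \code{[K, N]}.
#' @param into_backbone backpropagate through the backbone (set \code{FALSE}
#'   when only token/head gradients are needed).
#' @return List with \code{grads} and \code{dfeatmap} (NULL for vit_only).
#' @export
rtcn_backward <- function(model, fw, dlogits, into_backbone = TRUE) {
  cfg <- model$config
  if (cfg$variant == "resnet_only") {
    b_hd <- nn_backward(model$layers$head, fw$head, dlogits)
    b_gp <- nn_backward(global_avg_pool(), fw$gap_dims, b_hd$dx)
    dfeat <- b_gp$dx
    g_bb <- if (into_backbone)
      nn_backward(model$layers$backbone, fw$backbone, dfeat)$grads else NULL
    return(list(grads = list(layers = list(backbone = g_bb, head = b_hd$grads)),
                dfeatmap = dfeat))
  }
  d <- cfg$compressed_dim
  b_hd <- nn_backward(model$layers$head, fw$head, dlogits)
  denc <- array(0, dim(fw$encoded))
  denc[, 1, ] <- b_hd$dx
  b_enc <- nn_backward(model$layers$encoder, fw$encoder, denc)
  dseq <- b_enc$dx
  if (cfg$variant == "vit_only") {
    dcls <- rowSums(matrix(dseq[, 1, ], nrow = d))
    dtok <- dseq[, -1, , drop = FALSE]
    dpos <- apply(dtok, c(1, 2), sum)
    d3 <- fw$tok_dims
    b_emb <- nn_backward(model$layers$embed, fw$embed, matrix(dtok, nrow = d))
    return(list(grads = list(pos = dpos, cls = dcls,
                             layers = list(embed = b_emb$grads,
                                           encoder = b_enc$grads,
                                           head = b_hd$grads)),
                dfeatmap = NULL))
  }
  b_dp <- nn_backward(model$layers$tok_drop, fw$tok_drop, dseq)
  dseq <- b_dp$dx
  dcls <- rowSums(matrix(dseq[, 1, ], nrow = d))
  dtok <- dseq[, -1, , drop = FALSE]
  dpos <- apply(dtok, c(1, 2), sum)
  dcmap <- array(dtok, fw$cmap_dims)
  b_cp <- nn_backward(model$layers$compress, fw$compress, dcmap)
  dfeat <- b_cp$dx
  g_bb <- if (into_backbone)
    nn_backward(model$layers$backbone, fw$backbone, dfeat)$grads else NULL
  list(grads = list(pos = dpos, cls = dcls,
                    layers = list(backbone = g_bb, compress = b_cp$grads,
                                  tok_drop = list(), encoder = b_enc$grads,
                                  head = b_hd$grads)),
       dfeatmap = dfeat, dtokens = dtok)
}

#' Class probabilities for a batch of images
#'
#' @param model an [rtcn_model()].
#' @param x input image or batch.
#' @return Matrix \code{[n_classes, N]} of softmax probabilities (columns sum
#'   to 1).
#' @export
rtcn_predict <- function(model, x) rtcn_forward(model, x)$probs

#' Attention maps of the last forward pass
#'
#' @param model an [rtcn_model()].
#' @return List (one element per encoder layer) of arrays
#'   \code{[n_heads, T+1, T+1, N]}; each attention row sums to 1.
#' @export
attention_maps <- function(model) {
  enc <- model$layers$encoder
  lapply(enc$layers, function(tl) tl$layers$mha$state$attention)
}

#' Count trainable weight layers
#'
#' Convolutional layers on the main paths (projection shortcuts excluded, the
#' standard ResNet counting convention) plus the fully connected head: 50 for
#' the full configuration.
#'
#' @param model an [rtcn_model()].
#' @return Integer count.
#' @export
count_weight_layers <- function(model) {
  count_layer <- function(l) {
    n <- 0L
    if (inherits(l, "conv2d") && identical(l$role, "main")) n <- n + 1L
    if (!is.null(l$layers)) n <- n + sum(vapply(l$layers, count_layer, 0L))
    n
  }
  n <- count_layer(model$layers$backbone %||% list())
  n + 1L  # fully connected head
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit the backbone stage plan
#'
#' Returns the per-stage bottleneck plan actually built: kernel sizes,
#' mid/out channel widths and repeat counts, for comparison against the
#' standard ResNet-50 table.
#'
#' @param config an [rtcn_config()].
#' @return data.frame with one row per stage.
#' @export
backbone_plan <- function(config) {
  b <- config$base_width
  data.frame(stage = paste0("conv", 2:5, "_x"),
             kernels = "1x1,3x3,1x1",
             mid_channels = b * c(1, 2, 4, 8),
             out_channels = 4 * b * c(1, 2, 4, 8),
             repeats = c(3, 4, 6, 3))
}
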