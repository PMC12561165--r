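# Grad-CAM attribution over the time-frequency inputs, for both the final
# convolutional feature map and the token grid feeding the encoder.

#' Grad-CAM heatmap
#'
#' Gradients of the target class score (the pre-softmax logit) with respect
#' to the chosen layer's activations are spatially averaged into per-channel
#' weights; the weighted activation sum is rectified, bilinearly upsampled to
#' the input's spatial size and normalized to a maximum of 1 (an all-zero map
#' is returned unnormalized). Registered layers: \code{"conv5"} (the last
#' backbone stage's 2048-channel map) and \code{"tokens"} (the 49 compressed
#' spatial tokens entering the encoder, reshaped back to their grid).
#'
#' @param model an [rtcn_model()] (full or resnet_only variant for
#'   \code{"conv5"}; full for \code{"tokens"}).
#' @param image input array \code{[3, side, side]}.
#' @param target_class class index in \code{1..n_classes} or class code.
#' @param layer \code{"conv5"} or \code{"tokens"}.
#' @return Object of class \code{heatmap}: \code{values} (side x side,
#'   non-negative, max 1 unless all-zero), \code{target_class},
#'   \code{source_layer}.
#' @export
grad_cam <- function(model, image, target_class, layer = "conv5") {
  registered <- c("conv5", "tokens")
  if (!layer %in% registered) {
    stop_rtcn("unknown layer '", layer, "'; registered layers: ",
              paste(registered, collapse = ", "))
  }
  if (is.character(target_class)) {
    target_class <- label_to_index(target_class)
  }
  cfg <- model$config
  assert_that(target_class >= 1 && target_class <= cfg$n_classes,
              "target_class out of range")
  if (layer == "tokens") {
    assert_that(cfg$variant == "full",
                "token-grid attribution needs the full cascade variant")
  } else {
    assert_that(cfg$variant %in% c("full", "resnet_only"),
                "conv5 attribution needs a backbone variant")
  }
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1)
  side <- dim(image)[2]
  fw <- rtcn_forward(model, image, training = FALSE, capture = TRUE)
  dlogits <- matrix(0, cfg$n_classes, 1)
  dlogits[target_class, 1] <- 1
  bw <- rtcn_backward(model, fw, dlogits, into_backbone = FALSE)
  if (layer == "conv5") {
    A <- fw$featmap[, , , 1, drop = FALSE]
    G <- bw$dfeatmap[, , , 1, drop = FALSE]
    C <- dim(A)[1]
    w <- rowMeans(matrix(G, nrow = C))
    cam <- apply(array(w * matrix(A, nrow = C), dim(A)[1:3]), c(2, 3), sum)
  } else {
    tok <- matrix(fw$tokens[, , 1], nrow = cfg$compressed_dim)   # [d, T]
    gtk <- matrix(bw$dtokens[, , 1], nrow = cfg$compressed_dim)
    w <- rowMeans(gtk)
    relev <- colSums(w * tok)                                    # [T]
    s <- sqrt(length(relev))
    cam <- matrix(relev, s, s)
  }
  cam <- pmax(cam, 0)
  up <- bilinear_resize(cam, side, side)
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  structure(list(values = up, target_class = target_class,
                 source_layer = layer), class = "heatmap")
}

#' Fraction of heatmap mass inside a frequency band
#'
#' Maps the heatmap rows onto the time-frequency image's frequency axis and
#' reports the fraction of total relevance falling inside \code{band_hz}
#' (e.g. the 5--15 Hz QRS energy band).
#'
#' @param heatmap a [grad_cam()] result.
#' @param image the \code{tf_image} the model input was derived from.
#' @param band_hz length-2 numeric, band edges in Hz.
#' @return Scalar in [0, 1] (NA for an all-zero heatmap).
#' @export
band_energy_fraction <- function(heatmap, image, band_hz = c(5, 15)) {
  v <- heatmap$values
  total <- sum(v)
  if (total == 0) return(NA_real_)
  f <- seq(min(image$freq_axis_hz), max(image$freq_axis_hz),
           length.out = nrow(v))
  inside <- f >= band_hz[1] & f <= band_hz[2]
  sum(v[inside, ]) / total
}

#' Render a Grad-CAM overlay
#'
#' Writes a raster figure with the S-transform magnitude as the base layer
#' (time on x in seconds, frequency on y in Hz) and the heatmap as a
#' semi-transparent heat overlay.
#'
#' @param heatmap a [grad_cam()] result.
#' @param image the underlying \code{tf_image}.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
overlay <- function(heatmap, image, path) {
  assert_that(inherits(heatmap, "heatmap"), "heatmap must come from grad_cam()")
  assert_that(inherits(image, "tf_image"), "image must be a tf_image")
  base <- image$values
  hm <- bilinear_resize(heatmap$values, nrow(base), ncol(base))
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(x = image$time_axis_s, y = image$freq_axis_hz, z = t(base),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = sprintf("Grad-CAM (%s, class %s)",
                                 heatmap$source_layer, heatmap$target_class))
  heat_cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE,
                                     alpha = seq(0, 0.7, length.out = 64))
  if (max(hm) > 0) {
    graphics::image(x = image$time_axis_s, y = image$freq_axis_hz, z = t(hm),
                    col = heat_cols, add = TRUE)
  }
  invisible(path)
}
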