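# Patient-aware splitting, supervised training, and the per-class /
# overall metric suite.

#' Split specification
#'
#' @param paradigm \code{"inter_patient"} (train and test patient sets are
#'   disjoint; beats follow their patient) or \code{"intra_patient"}
#'   (beat-level stratified random split).
#' @param train_fraction fraction of patients (inter) or beats (intra)
#'   assigned to training; approximately 8:2 by default.
#' @param seed split seed.
#' @return Object of class \code{split_spec}.
#' @export
split_spec <- function(paradigm = c("inter_patient", "intra_patient"),
                       train_fraction = 0.8, seed = 1L) {
  paradigm <- match.arg(paradigm)
  assert_that(train_fraction > 0 && train_fraction <= 1,
              "train_fraction must be in (0, 1]")
  structure(list(paradigm = paradigm, train_fraction = train_fraction,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split a beat dataset into train and test
#'
#' Under the inter-patient paradigm patients are deduplicated, the patient set
#' is partitioned (approximately \code{train_fraction} : rest), and every beat
#' follows its patient, so no patient contributes to both sides. Synthetic
#' beats are always assigned to the training side, never to test.
#'
#' @param beats a [beat_set()].
#' @param spec a [split_spec()].
#' @return List with elements \code{train} and \code{test} (beat sets).
#' @export
split_dataset <- function(beats, spec) {
  assert_that(inherits(beats, "beat_set"), "beats must be a beat_set")
  is_syn <- beats$meta$source == "synthetic"
  real_idx <- which(!is_syn)
  if (spec$paradigm == "inter_patient") {
    pids <- beats$meta$patient_id[real_idx]
    assert_that(!any(pids %in% c("", "unknown", NA)),
                "inter-patient split requires a patient ID on every real beat")
    upat <- unique(pids)
    assert_that(length(upat) >= 2,
                "inter-patient split needs at least 2 patients")
    n_train <- min(max(round(spec$train_fraction * length(upat)), 1),
                   length(upat) - 1)
    train_pat <- with_seed(spec$seed, sample(upat, n_train))
    tr <- real_idx[pids %in% train_pat]
    te <- real_idx[!(pids %in% train_pat)]
  } else {
    labs <- beats$meta$label[real_idx]
    tr_local <- with_seed(spec$seed, {
      unlist(lapply(split(seq_along(real_idx), labs), function(ix) {
        k <- round(spec$train_fraction * length(ix))
        if (k >= length(ix)) ix else sample(ix, k)
      }))
    })
    tr <- real_idx[sort(tr_local)]
    te <- setdiff(real_idx, tr)
    if (length(te) == 0) warning("intra-patient split produced an empty test set")
  }
  list(train = beat_subset(beats, sort(c(tr, which(is_syn)))),
       test = beat_subset(beats, te))
}

label_to_index <- function(labels, classes = rtcn_classes()) {
  idx <- match(labels, classes)
  assert_that(!any(is.na(idx)),
              "labels outside the known class set (unknown labels are rejected at training time)")
  idx
}

#' Train a classifier
#'
#' Cross-entropy loss minimized by stochastic gradient descent with momentum
#' (learning rate 0.001, momentum 0.9, batch size 64, 60 epochs by default,
#' all overridable for desk-scale runs). A stratified fraction of the training
#' data is held out for the per-epoch validation curve. Seeded runs are
#' reproducible.
#'
#' @param model an [rtcn_model()].
#' @param x input batch array \code{[3, side, side, N]}.
#' @param y labels: integer indices in \code{1..n_classes} or class codes.
#' @param hparams list overriding \code{lr}, \code{momentum},
#'   \code{batch_size}, \code{epochs}, \code{val_fraction}.
#' @param seed training seed (shuffling, dropout).
#' @param classes class codes used to map character labels.
#' @param verbose print per-epoch progress.
#' @return List with \code{model} and \code{history} (data.frame: epoch,
#'   train_loss, train_acc, val_acc).
#' @export
train_model <- function(model, x, y, hparams = list(), seed = 1L,
                        classes = rtcn_classes(), verbose = FALSE) {
  hp <- utils::modifyList(list(lr = 0.001, momentum = 0.9, batch_size = 64,
                               epochs = 60, val_fraction = 0.1,
                               clip_norm = 5), hparams)
  if (is.character(y) || is.factor(y)) y <- label_to_index(as.character(y), classes)
  N <- dim(x)[4]
  assert_that(N > 0 && length(y) == N, "x and y sizes must agree")
  assert_that(length(unique(y)) >= 2,
              "training set must span at least 2 classes")
  with_seed(seed, {
    val_idx <- integer(0)
    if (hp$val_fraction > 0 && N >= 10) {
      val_idx <- unlist(lapply(split(seq_len(N), y), function(ix) {
        k <- max(0, round(hp$val_fraction * length(ix)))
        if (k > 0 && k < length(ix)) sample(ix, k) else integer(0)
      }))
    }
    tr_idx <- setdiff(seq_len(N), val_idx)
    vel <- sgd_init(model)
    hist <- data.frame()
    for (ep in seq_len(hp$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, length(ord), by = hp$batch_size)) {
        bi <- ord[b0:min(b0 + hp$batch_size - 1, length(ord))]
        xb <- x[, , , bi, drop = FALSE]
        yb <- y[bi]
        fw <- rtcn_forward(model, xb, training = TRUE, capture = TRUE)
        ce <- cross_entropy(fw$logits, yb)
        ep_loss <- ep_loss + ce$loss * length(bi)
        ep_correct <- ep_correct + sum(apply(fw$logits, 2, which.max) == yb)
        bw <- rtcn_backward(model, fw, ce$dlogits)
        grads <- if (is.finite(hp$clip_norm)) clip_grads(bw$grads, hp$clip_norm)
                 else bw$grads
        st <- sgd_step(model, grads, vel, hp$lr, hp$momentum)
        model <- st$layer; vel <- st$vel
      }
      val_acc <- NA_real_
      if (length(val_idx) > 0) {
        pv <- rtcn_forward(model, x[, , , val_idx, drop = FALSE])$logits
        val_acc <- mean(apply(pv, 2, which.max) == y[val_idx])
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / length(tr_idx),
                                     train_acc = ep_correct / length(tr_idx),
                                     val_acc = val_acc))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f val %.3f", ep,
                        hist$train_loss[ep], hist$train_acc[ep], val_acc))
      }
    }
    list(model = model, history = hist)
  })
}

#' Evaluate a model into a confusion matrix
#'
#' Argmax prediction per input; rows are true classes, columns predictions.
#'
#' @param model an [rtcn_model()].
#' @param x input batch array.
#' @param y true labels (indices or class codes).
#' @param classes class codes labelling the matrix.
#' @return Integer \code{K x K} matrix of class \code{confusion_matrix}.
#' @export
evaluate_model <- function(model, x, y, classes = rtcn_classes()) {
  if (is.character(y) || is.factor(y)) y <- label_to_index(as.character(y), classes)
  assert_that(dim(x)[4] == length(y) && length(y) > 0,
              "non-empty matching test set required")
  K <- model$config$n_classes
  pred <- integer(length(y))
  for (b0 in seq(1, length(y), by = 32)) {
    bi <- b0:min(b0 + 31, length(y))
    lg <- rtcn_forward(model, x[, , , bi, drop = FALSE])$logits
    pred[bi] <- apply(lg, 2, which.max)
  }
  confusion_matrix(y, pred, K, classes[seq_len(K)])
}

#' Build a confusion matrix from labels and predictions
#'
#' @param truth,pred integer class indices in \code{1..K}.
#' @param K number of classes.
#' @param classes optional class names for the dimnames.
#' @return Integer \code{K x K} matrix (rows true, columns predicted).
#' @export
confusion_matrix <- function(truth, pred, K = max(truth, pred),
                             classes = NULL) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (!is.null(classes)) dimnames(cm) <- list(truth = classes, pred = classes)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class and overall classification metrics
#'
#' Reduces the \code{K x K} confusion matrix to one-vs-rest TP/FP/FN/TN per
#' class and reports accuracy, sensitivity (recall), precision, specificity
#' and F1 per class (percentages), their unweighted macro averages, and the
#' overall accuracy \code{AccT = trace / total}. Cells with a zero
#' denominator are reported as \code{NA} and excluded from the macro
#' averages (with a message).
#'
#' @param cm a [confusion_matrix()] (non-degenerate: at least one count).
#' @return List of class \code{metrics_report}: \code{per_class} data.frame,
#'   \code{macro} named vector, \code{acc_total} (percent).
#' @export
compute_metrics <- function(cm) {
  total <- sum(cm)
  assert_that(total > 0, "confusion matrix is all zero")
  K <- nrow(cm)
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  rows <- lapply(seq_len(K), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    sen <- pct(TP, TP + FN)
    pre <- pct(TP, TP + FP)
    f1 <- if (!is.na(sen) && !is.na(pre) && (sen + pre) > 0)
      2 * sen * pre / (sen + pre) else NA_real_
    data.frame(class = if (!is.null(rownames(cm))) rownames(cm)[k] else as.character(k),
               acc = pct(TP + TN, total), sen = sen, pre = pre,
               spe = pct(TN, TN + FP), f1 = f1,
               TP = TP, FP = FP, FN = FN, TN = TN)
  })
  per_class <- do.call(rbind, rows)
  metric_cols <- c("acc", "sen", "pre", "spe", "f1")
  if (anyNA(per_class[metric_cols])) {
    message("zero-denominator metric cells reported as NA and excluded from macro averages")
  }
  macro <- colMeans(per_class[metric_cols], na.rm = TRUE)
  structure(list(per_class = per_class, macro = macro,
                 acc_total = 100 * sum(diag(as.matrix(cm))) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(cbind(x$per_class[, "class", drop = FALSE],
              round(x$per_class[, c("acc", "sen", "pre", "spe", "f1")], 2)),
        row.names = FALSE)
  cat(sprintf("Macro averages: Acc %.2f Sen %.2f Pre %.2f Spe %.2f F1 %.2f\n",
              x$macro["acc"], x$macro["sen"], x$macro["pre"], x$macro["spe"],
              x$macro["f1"]))
  cat(sprintf("Overall AccT: %.2f%%\n", x$acc_total))
  invisible(x)
}
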