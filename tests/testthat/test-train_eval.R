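# Patient-aware splitting, training contracts, and the metric suite.

mk_beats <- function(n_pat = 10, beats_per = 4, classes = c("HC", "AMI")) {
  withr::with_seed(1, {
    n <- n_pat * beats_per
    beat_set(matrix(rnorm(100 * n), 100),
             label = rep(classes, length.out = n),
             patient_id = rep(sprintf("P%02d", seq_len(n_pat)), each = beats_per),
             r_index = 50)
  })
}

test_that("inter-patient splits have disjoint patient sets at the 8:2 ratio", {
  b <- mk_beats(10)
  sp <- split_dataset(b, split_spec("inter_patient", 0.8, seed = 4))
  tr_pat <- unique(sp$train$meta$patient_id)
  te_pat <- unique(sp$test$meta$patient_id)
  expect_length(tr_pat, 8)
  expect_length(te_pat, 2)
  expect_length(intersect(tr_pat, te_pat), 0)
  expect_equal(n_beats(sp$train) + n_beats(sp$test), n_beats(b))
})

test_that("degenerate splits are rejected or warned about", {
  one <- beat_set(matrix(0, 10, 3), "HC", "P01", 5)
  expect_error(split_dataset(one, split_spec("inter_patient")), "2 patients")
  anon <- beat_set(matrix(0, 10, 3), "HC", "unknown", 5)
  expect_error(split_dataset(anon, split_spec("inter_patient")), "patient ID")
  expect_warning(split_dataset(mk_beats(4), split_spec("intra_patient", 1.0)),
                 "empty test")
})

test_that("synthetic beats always land in the training partition", {
  b <- mk_beats(10)
  b$meta$source[seq(1, 40, by = 3)] <- "synthetic"
  for (par in c("inter_patient", "intra_patient")) {
    sp <- split_dataset(b, split_spec(par, 0.7, seed = 2))
    expect_true(all(sp$test$meta$source == "real"))
    expect_equal(sum(sp$train$meta$source == "synthetic"),
                 sum(b$meta$source == "synthetic"))
  }
})

test_that("training improves accuracy on a separable task; lr 0 freezes; seeds reproduce", {
  d <- fx_two_class_images(n = 24, side = 32)
  cfg <- rtcn_config(n_classes = 2, input_side = 32, base_width = 4,
                     compressed_dim = 16, n_layers = 1, n_heads = 2,
                     ff_dim = 32, dropout_rate = 0, token_dropout = 0)
  m <- withr::with_seed(3, rtcn_model(cfg))
  tr <- train_model(m, d$x, d$y, hparams = list(lr = 0.05, batch_size = 8,
                                                epochs = 4, val_fraction = 0),
                    seed = 5)
  expect_gt(max(tr$history$train_acc), 0.8)
  # frozen training: lr = 0 leaves every parameter untouched; the loss curve
  # is flat up to batch-norm batch-composition noise under reshuffling
  m0 <- withr::with_seed(3, rtcn_model(cfg))
  fr <- train_model(m0, d$x, d$y, hparams = list(lr = 0, batch_size = 8,
                                                 epochs = 2, val_fraction = 0),
                    seed = 5)
  expect_equal(fr$model$layers$head$params$W, m0$layers$head$params$W)
  expect_equal(fr$model$layers$compress$params$W, m0$layers$compress$params$W)
  expect_lt(max(abs(diff(fr$history$train_loss))) / fr$history$train_loss[1],
            0.1)
  # seeded reproducibility
  m1 <- withr::with_seed(3, rtcn_model(cfg))
  t1 <- train_model(m1, d$x, d$y, hparams = list(lr = 0.05, batch_size = 8,
                                                 epochs = 2, val_fraction = 0),
                    seed = 5)
  m2 <- withr::with_seed(3, rtcn_model(cfg))
  t2 <- train_model(m2, d$x, d$y, hparams = list(lr = 0.05, batch_size = 8,
                                                 epochs = 2, val_fraction = 0),
                    seed = 5)
  expect_identical(t1$history$train_loss, t2$history$train_loss)
})

test_that("single-class and unknown-label training sets are rejected", {
  d <- fx_two_class_images(n = 8, side = 32)
  cfg <- rtcn_config(n_classes = 2, input_side = 32, base_width = 4,
                     compressed_dim = 16, n_layers = 1, n_heads = 2,
                     ff_dim = 32)
  m <- withr::with_seed(4, rtcn_model(cfg))
  expect_error(train_model(m, d$x, rep(1L, 8)), "2 classes")
  expect_error(train_model(m, d$x, rep("unknown", 8)), "unknown labels")
})

test_that("evaluation accumulates a conserving confusion matrix", {
  truth <- c(1, 1, 2, 3, 2, 1)
  pred <- c(1, 2, 2, 3, 2, 1)
  cm <- confusion_matrix(truth, pred, 3)
  expect_equal(sum(cm), 6)
  expect_equal(diag(as.matrix(cm)), c(2, 2, 1))
  # perfect predictor: diagonal; constant predictor: one non-zero column
  expect_true(all(confusion_matrix(1:3, 1:3, 3)[upper.tri(diag(3))] == 0))
  const <- confusion_matrix(c(1, 2, 3, 1), rep(2, 4), 3)
  expect_equal(colSums(const), c(0, 4, 0))
})

test_that("metric formulas match the hand-computed binary example", {
  # TP=8 FN=2 FP=1 TN=9 for class 1
  cm <- confusion_matrix(c(rep(1, 10), rep(2, 10)),
                         c(rep(1, 8), 2, 2, 1, rep(2, 9)), 2)
  rep_ <- compute_metrics(cm)
  r1 <- rep_$per_class[1, ]
  expect_equal(r1$sen, 80)
  expect_equal(r1$pre, 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(r1$spe, 90)
  expect_equal(r1$acc, 85)
  expect_equal(r1$f1, 2 * r1$sen * r1$pre / (r1$sen + r1$pre), tolerance = 1e-9)
  expect_equal(rep_$acc_total, 85)
})

test_that("metrics agree with brute-force counting and are permutation-invariant", {
  withr::with_seed(6, {
    truth <- sample(1:4, 300, replace = TRUE)
    pred <- ifelse(stats::runif(300) < 0.7, truth, sample(1:4, 300, TRUE))
  })
  cm <- confusion_matrix(truth, pred, 4)
  rep_ <- suppressMessages(compute_metrics(cm))
  # overall accuracy equals the direct fraction of correct predictions
  expect_equal(rep_$acc_total, 100 * mean(truth == pred), tolerance = 1e-12)
  # per-class counts equal brute-force one-vs-rest tallies
  for (k in 1:4) {
    expect_equal(rep_$per_class$TP[k], sum(truth == k & pred == k))
    expect_equal(rep_$per_class$FN[k], sum(truth == k & pred != k))
    expect_equal(rep_$per_class$FP[k], sum(truth != k & pred == k))
    expect_equal(rep_$per_class$TN[k], sum(truth != k & pred != k))
  }
  # relabeling classes permutes rows but not values
  perm <- c(3, 1, 4, 2)
  cmp <- confusion_matrix(perm[truth], perm[pred], 4)
  repp <- suppressMessages(compute_metrics(cmp))
  expect_equal(repp$acc_total, rep_$acc_total)
  expect_equal(repp$per_class$f1[perm], rep_$per_class$f1, tolerance = 1e-9)
  # diagonal matrix: every metric 100
  d <- compute_metrics(confusion_matrix(1:3, 1:3, 3))
  expect_true(all(abs(unlist(d$per_class[c("acc", "sen", "pre", "spe", "f1")]) -
                        100) < 1e-12))
  expect_equal(d$acc_total, 100)
  expect_error(compute_metrics(matrix(0, 3, 3)), "all zero")
})
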