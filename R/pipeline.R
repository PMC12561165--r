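# One-call orchestration of the full pipeline:
# simulate/ingest -> preprocess -> DDPM balance -> time-frequency transform ->
# train -> evaluate (-> explain -> generation QC), with a single master seed
# fanned out per stage and full provenance written to the run directory.

#' Default pipeline configuration
#'
#' Returns the full configuration tree with desk-scale defaults; override
#' any subset via [run_pipeline()]'s \code{config} argument. Unknown keys are
#' rejected before any stage runs.
#'
#' @return Nested named list.
#' @export
pipeline_defaults <- function() {
  list(
    data = list(source = "simulate",       # or a directory of WFDB records
                input_dir = NULL,
                lead = "ii",
                n_per_class = stats::setNames(rep(4L, 12), rtcn_classes()),
                duration_s = 10,
                noise = list(baseline_amp_mv = 0.1, powerline_amp_mv = 0.02,
                             white_sigma_mv = 0.02)),
    preprocess = list(n_levels = 5, wavelet = "db6", pre_n = 250, post_n = 400),
    balance = list(enabled = FALSE, targets = NULL,
                   ddpm = list(T_ = 30, beta_start = 1e-3, beta_end = 0.2,
                               steps = 200, channels = 8, lr = 0.01,
                               batch_size = 8)),
    transform = list(method = "stransform", f_max_hz = 50, side = 64,
                     log1p = FALSE),
    model = list(base_width = 8, compressed_dim = 32, n_layers = 1,
                 n_heads = 4, dropout_rate = 0, token_dropout = 0,
                 variant = "full"),
    split = list(paradigm = "inter_patient", train_fraction = 0.8),
    train = list(lr = 0.01, momentum = 0.9, batch_size = 16, epochs = 4,
                 val_fraction = 0.1),
    explain = list(enabled = FALSE, layer = "conv5"),
    genqc = list(enabled = FALSE),
    seed = 1L)
}

check_config_keys <- function(config, template = pipeline_defaults(),
                              path = "config") {
  extra <- setdiff(names(config), names(template))
  if (length(extra) > 0) {
    stop_rtcn("unknown ", path, " key(s): ", paste(extra, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]]) && !nm %in% c("n_per_class", "targets")) {
      check_config_keys(config[[nm]], template[[nm]], paste0(path, "$", nm))
    }
  }
  invisible(TRUE)
}

#' Convert beats to a batch of model input images
#'
#' Applies the configured time-frequency transform to every beat and stacks
#' the resized, normalized images into one input array.
#'
#' @param beats a [beat_set()].
#' @param sampling_rate_hz beat sampling rate.
#' @param method \code{"stransform"}, \code{"stft"} or \code{"cwt"}.
#' @param side model input side.
#' @param f_max_hz top frequency row.
#' @param log1p log-compress magnitudes before normalization.
#' @return Array \code{[3, side, side, n_beats]}.
#' @export
images_from_beats <- function(beats, sampling_rate_hz = 1000,
                              method = "stransform", side = 64,
                              f_max_hz = 50, log1p = FALSE) {
  n <- n_beats(beats)
  assert_that(n > 0, "no beats to transform")
  x <- array(0, c(3, side, side, n))
  for (i in seq_len(n)) {
    b <- beats$samples[, i]
    img <- switch(method,
                  stransform = s_transform(b, sampling_rate_hz, f_max_hz),
                  stft = stft_image(b, sampling_rate_hz, f_max_hz = f_max_hz),
                  cwt = cwt_image(b, sampling_rate_hz, f_max_hz = f_max_hz),
                  stop_rtcn("unknown transform method: ", method))
    x[, , , i] <- to_model_input(img, side, log1p = log1p)
  }
  x
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, preprocessing, optional DDPM class balancing,
#' time-frequency transformation, training, evaluation and the optional
#' explainability / generation-QC stages, in that order. The run directory
#' receives the exact configuration used (\code{config.json}), per-epoch
#' curves (\code{curves.csv}), the confusion matrix (\code{confusion.csv}),
#' the metric report (\code{metrics.json}) and a stage log with per-stage
#' counts. The master seed makes the whole run reproducible.
#'
#' @param config nested list overriding [pipeline_defaults()].
#' @param out_dir run directory (created).
#' @return List with \code{metrics}, \code{confusion}, \code{history},
#'   \code{out_dir} and stage artifacts.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("rtcn_run_")) {
  check_config_keys(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  log_path <- file.path(out_dir, "log.txt")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_rtcn("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  master <- cfg$seed

  # ---- ingest / simulate
  records <- stage("ingest", {
    if (identical(cfg$data$source, "simulate")) {
      generate_class_dataset(cfg$data$n_per_class,
                             spec_overrides = list(duration_s = cfg$data$duration_s,
                                                   noise = cfg$data$noise),
                             seed = stage_seed(master, "simulate"))
    } else {
      heas <- list.files(cfg$data$input_dir, pattern = "\\.hea$",
                         full.names = TRUE)
      assert_that(length(heas) > 0, "no WFDB records found in input_dir")
      lapply(heas, function(h) list(record = read_wfdb_record(h, cfg$data$lead)))
    }
  })
  log_line(log_path, "ingest: ", length(records), " records")

  # ---- preprocess
  beats <- stage("preprocess", {
    sets <- lapply(records, function(r) {
      suppressMessages(preprocess_record(r$record,
                                         n_levels = cfg$preprocess$n_levels,
                                         wavelet = cfg$preprocess$wavelet,
                                         pre_n = cfg$preprocess$pre_n,
                                         post_n = cfg$preprocess$post_n))
    })
    sets <- sets[vapply(sets, n_beats, 0L) > 0]
    do.call(beat_bind, sets)
  })
  log_line(log_path, "preprocess: ", n_beats(beats), " beats from ",
           length(records), " records")

  # ---- balance (before the split is finalized; synthetic stays in train)
  models <- list(); schedule <- NULL
  if (isTRUE(cfg$balance$enabled)) {
    beats <- stage("balance", {
      counts <- table(beats$meta$label)
      plan <- balance_plan(as.list(counts), targets = cfg$balance$targets,
                           seed = stage_seed(master, "balance"))
      schedule <- make_schedule(cfg$balance$ddpm$T_, cfg$balance$ddpm$beta_start,
                                cfg$balance$ddpm$beta_end)
      need <- names(plan$targets)[plan$action == "synthesize" &
                                    plan$targets > plan$counts]
      models <- stats::setNames(lapply(need, function(cls) {
        train_denoiser(beat_subset(beats, beats$meta$label == cls), schedule,
                       hparams = list(steps = cfg$balance$ddpm$steps,
                                      channels = cfg$balance$ddpm$channels,
                                      lr = cfg$balance$ddpm$lr,
                                      batch_size = cfg$balance$ddpm$batch_size %||% 16),
                       seed = stage_seed(master, paste0("ddpm/", cls)))
      }), need)
      balance_dataset(beats, plan, models, schedule)
    })
    log_line(log_path, "balance: ", n_beats(beats), " beats after balancing (",
             sum(beats$meta$source == "synthetic"), " synthetic)")
  }

  # ---- split
  split <- stage("split", {
    split_dataset(beats, split_spec(cfg$split$paradigm,
                                    cfg$split$train_fraction,
                                    seed = stage_seed(master, "split")))
  })
  log_line(log_path, "split: ", n_beats(split$train), " train / ",
           n_beats(split$test), " test beats; paradigm ", cfg$split$paradigm)

  # ---- transform
  fs <- records[[1]]$record$sampling_rate_hz
  x_train <- stage("transform", {
    images_from_beats(split$train, fs, cfg$transform$method,
                      cfg$transform$side, cfg$transform$f_max_hz,
                      cfg$transform$log1p)
  })
  x_test <- images_from_beats(split$test, fs, cfg$transform$method,
                              cfg$transform$side, cfg$transform$f_max_hz,
                              cfg$transform$log1p)
  log_line(log_path, "transform: ", cfg$transform$method, " images ",
           cfg$transform$side, "x", cfg$transform$side)

  # ---- train
  trained <- stage("train", {
    mcfg <- rtcn_config(n_classes = 12, input_side = cfg$transform$side,
                        base_width = cfg$model$base_width,
                        compressed_dim = cfg$model$compressed_dim,
                        n_layers = cfg$model$n_layers,
                        n_heads = cfg$model$n_heads,
                        dropout_rate = cfg$model$dropout_rate,
                        token_dropout = cfg$model$token_dropout,
                        variant = cfg$model$variant)
    model <- with_seed(stage_seed(master, "init"), rtcn_model(mcfg))
    train_model(model, x_train, split$train$meta$label, hparams = cfg$train,
                seed = stage_seed(master, "train"))
  })
  utils::write.csv(trained$history, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  log_line(log_path, "train: ", nrow(trained$history), " epochs, final acc ",
           round(utils::tail(trained$history$train_acc, 1), 3))

  # ---- evaluate
  cm <- stage("evaluate", {
    evaluate_model(trained$model, x_test, split$test$meta$label)
  })
  metrics <- suppressMessages(compute_metrics(cm))
  utils::write.csv(as.data.frame(unclass(cm)), file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(list(acc_total = metrics$acc_total,
                            macro = as.list(metrics$macro),
                            per_class = metrics$per_class),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(log_path, "evaluate: AccT ", round(metrics$acc_total, 2), "% on ",
           sum(cm), " test beats")

  # ---- explain (optional)
  heat <- NULL
  if (isTRUE(cfg$explain$enabled) && n_beats(split$test) > 0) {
    heat <- stage("explain", {
      img <- s_transform(split$test$samples[, 1], fs, cfg$transform$f_max_hz)
      hm <- grad_cam(trained$model, x_test[, , , 1],
                     label_to_index(split$test$meta$label[1]),
                     layer = cfg$explain$layer)
      overlay(hm, img, file.path(out_dir, "gradcam.png"))
      hm
    })
    log_line(log_path, "explain: gradcam.png written")
  }

  # ---- generation QC (optional)
  qc <- NULL
  if (isTRUE(cfg$genqc$enabled) && any(beats$meta$source == "synthetic")) {
    qc <- stage("genqc", {
      quality_report(beat_subset(beats, beats$meta$source == "real"),
                     beat_subset(beats, beats$meta$source == "synthetic"),
                     seed = stage_seed(master, "genqc"))
    })
    jsonlite::write_json(qc$per_class, file.path(out_dir, "genqc.json"),
                         pretty = TRUE, digits = NA)
    log_line(log_path, "genqc: report written")
  }

  list(metrics = metrics, confusion = cm, history = trained$history,
       model = trained$model, split = split, beats = beats,
       heatmap = heat, genqc = qc, out_dir = out_dir)
}
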