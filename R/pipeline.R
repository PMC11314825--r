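#' Prepare segments as recurrence-plot image inputs for the classifier
#'
#' For each segment: min-max normalise, wavelet-denoise, optionally decimate
#' (Fourier resampling) to a fixed length to bound the recurrence-matrix
#' size, embed, threshold, and pool the recurrence matrix to an image.
#'
#' @param segments List of `ecg_signal` objects.
#' @param image_size Side length of the pooled recurrence image (default 64).
#' @param decimate_to Target sample count before embedding (`NULL` keeps the
#'   native length); default 500.
#' @param denoise Apply the wavelet denoiser first (default `TRUE`).
#' @param wavelet A [wavelet_config()].
#' @param m,tau,eps_frac Embedding and threshold parameters.
#' @return A list: `x` (array `image_size` x `image_size` x 1 x N), `y`
#'   (integer labels, `NA` where unlabelled), `record_ids`.
#' @export
prepare_rp_dataset <- function(segments, image_size = 64L, decimate_to = 500L,
                               denoise = TRUE, wavelet = wavelet_config(),
                               m = 3L, tau = 3L, eps_frac = 0.10) {
  n <- length(segments)
  x <- array(0, c(image_size, image_size, 1L, n))
  y <- integer(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- minmax_normalize(segments[[i]])
    if (denoise) s <- denoise_ecg(s, wavelet)
    if (!is.null(decimate_to) && length(s$samples) != decimate_to) {
      s <- resample_ecg(s, s$fs * decimate_to / length(s$samples))
    }
    R <- recurrence_matrix(embed_trajectory(s, m = m, tau = tau),
                           eps_frac = eps_frac)
    x[, , 1L, i] <- rp_to_image(R, size = image_size)
    y[i] <- segments[[i]]$label
    ids[i] <- segments[[i]]$record_id
  }
  list(x = x, y = y, record_ids = ids)
}

#' Pipeline configuration
#'
#' One nested configuration object drives the whole pipeline; it serialises
#' losslessly to YAML via [write_pipeline_config()].
#'
#' @param seed Master seed for every random stage.
#' @param simulate List: `n_per_class`, `duration` (s), `fs` (Hz) for the
#'   synthetic source.
#' @param preprocess List: `fL` (Hz), `remove_baseline`, `denoise`.
#' @param recurrence List: `m`, `tau`, `eps_frac`, `lmin`, `vmin`,
#'   `decimate_to`, `image_size`.
#' @param model List passed to [model_config()] (minus `input_size`, taken
#'   from `recurrence$image_size`).
#' @param train List passed to [train_config()] (minus `seed`).
#' @param split List: `train`, `validation`, `test` fractions and `unit`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = list(n_per_class = 50L, duration = 10,
                                            fs = 500),
                            preprocess = list(fL = 0.5, remove_baseline = TRUE,
                                              denoise = TRUE),
                            recurrence = list(m = 3L, tau = 3L,
                                              eps_frac = 0.10, lmin = 2L,
                                              vmin = 2L, decimate_to = 500L,
                                              image_size = 64L),
                            model = list(variant = "rp2d",
                                         stem_channels = 16L,
                                         block_channels = c(16L, 32L, 64L),
                                         fc_units = 32L),
                            train = list(lr = 1e-3, batch_size = 16L,
                                         epochs = 20L, patience = 5L),
                            split = list(train = 0.7, validation = 0.2,
                                         test = 0.1, unit = "record")) {
  structure(list(seed = as.integer(seed), simulate = simulate,
                 preprocess = preprocess, recurrence = recurrence,
                 model = model, train = train, split = split),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the end-to-end pipeline
#'
#' Ingest (synthetic generation or a directory of CSV segments plus a
#' `labels.tsv`), normalise, denoise, compute recurrence statistics and
#' recurrence-plot images, split record-wise, train the classifier, and
#' evaluate on the held-out test set. All artifacts are written to
#' `out_dir`: `config.yaml` (snapshot), `features.tsv`, `rp_images/`
#' (PNG previews), `model.rds`, `report.json`, `manifest.json` (file
#' checksums). Rerunning with an identical configuration reproduces the
#' report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param input_dir Directory with `*.csv` segments and `labels.tsv`
#'   (columns `file`, `label`); `NULL` (default) simulates instead.
#' @param write_images Write PNG previews of the recurrence images
#'   (default `TRUE`).
#' @param verbose Log stage boundaries.
#' @return Invisibly, a list: `report` (metrics, confusion counts, ROC),
#'   `features` (data frame), `paths` of the artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         input_dir = NULL, write_images = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # -- ingest ------------------------------------------------------------
  segments <- if (is.null(input_dir)) {
    stage_msg(verbose, "ingest", "simulating %d signals per class",
              config$simulate$n_per_class)
    generate_dataset(config$simulate$n_per_class,
                     duration = config$simulate$duration,
                     fs = config$simulate$fs, seed = config$seed)
  } else {
    lab_path <- file.path(input_dir, "labels.tsv")
    if (!file.exists(lab_path)) {
      stop(sprintf("stage ingest: labels.tsv not found in %s", input_dir),
           call. = FALSE)
    }
    labs <- utils::read.delim(lab_path)
    lapply(seq_len(nrow(labs)), function(i) {
      read_ecg_csv(file.path(input_dir, labs$file[i]),
                   label = as.integer(labs$label[i]))
    })
  }
  if (length(segments) == 0L) stop("stage ingest: no input segments",
                                   call. = FALSE)

  # -- preprocess + recurrence features ----------------------------------
  stage_msg(verbose, "preprocess", "normalising and denoising %d segments",
            length(segments))
  wl <- wavelet_config(fL = config$preprocess$fL,
                       remove_baseline = config$preprocess$remove_baseline)
  rc <- config$recurrence
  clean <- lapply(segments, function(s) {
    s <- minmax_normalize(s)
    if (isTRUE(config$preprocess$denoise)) s <- denoise_ecg(s, wl)
    s
  })
  dec <- lapply(clean, function(s) {
    if (!is.null(rc$decimate_to) && length(s$samples) != rc$decimate_to) {
      resample_ecg(s, s$fs * rc$decimate_to / length(s$samples))
    } else s
  })
  stage_msg(verbose, "rqa", "computing recurrence statistics")
  features <- rqa_feature_table(dec, m = rc$m, tau = rc$tau,
                                eps_frac = rc$eps_frac, lmin = rc$lmin,
                                vmin = rc$vmin)
  feat_path <- file.path(out_dir, "features.tsv")
  utils::write.table(features, feat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- recurrence images -------------------------------------------------
  stage_msg(verbose, "rp", "pooling recurrence plots to %d x %d images",
            rc$image_size, rc$image_size)
  n <- length(dec)
  x <- array(0, c(rc$image_size, rc$image_size, 1L, n))
  for (i in seq_len(n)) {
    R <- recurrence_matrix(embed_trajectory(dec[[i]], m = rc$m, tau = rc$tau),
                           eps_frac = rc$eps_frac)
    x[, , 1L, i] <- rp_to_image(R, size = rc$image_size)
  }
  y <- vapply(segments, function(s) s$label, integer(1))
  ids <- vapply(segments, function(s) s$record_id, character(1))
  img_dir <- file.path(out_dir, "rp_images")
  if (write_images) {
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(1 - x[, , 1L, i],
                    file.path(img_dir, sprintf("rp_%04d.png", i)))
    }
  }

  # -- split -------------------------------------------------------------
  sp <- split_spec(config$split$train, config$split$validation,
                   config$split$test, unit = config$split$unit,
                   seed = config$seed)
  idx_of <- function(part) which(ids %in% unique(vapply(part, function(s)
    s$record_id, character(1))))
  parts <- split_dataset(segments, sp)
  tr_i <- idx_of(parts$train); va_i <- idx_of(parts$validation)
  te_i <- idx_of(parts$test)
  stage_msg(verbose, "split", "train/val/test = %d/%d/%d segments",
            length(tr_i), length(va_i), length(te_i))

  # -- train -------------------------------------------------------------
  mc <- model_config(variant = config$model$variant,
                     input_size = rc$image_size,
                     stem_channels = config$model$stem_channels,
                     block_channels = config$model$block_channels,
                     fc_units = config$model$fc_units)
  tc <- train_config(lr = config$train$lr,
                     batch_size = config$train$batch_size,
                     epochs = config$train$epochs,
                     patience = config$train$patience, seed = config$seed)
  stage_msg(verbose, "train", "training %s for up to %d epochs",
            mc$variant, tc$epochs)
  fit <- train_model(build_model(mc, seed = config$seed),
                     list(x = x[, , , tr_i, drop = FALSE], y = y[tr_i]),
                     list(x = x[, , , va_i, drop = FALSE], y = y[va_i]),
                     tc)
  model_path <- file.path(out_dir, "model.rds")
  saveRDS(list(config = mc, layers = fit$model$layers,
               history = fit$history), model_path)

  # -- evaluate ----------------------------------------------------------
  p <- predict_proba(fit, x[, , , te_i, drop = FALSE])
  cm <- confusion_counts(y[te_i], as.integer(p >= 0.5))
  met <- classification_metrics(cm)
  roc <- roc_auc(p, y[te_i])
  stage_msg(verbose, "evaluate", "test accuracy %.3f, AUC %.3f",
            met$accuracy, roc$auc)
  report <- list(
    seed = config$seed,
    n_segments = n,
    split_sizes = list(train = length(tr_i), validation = length(va_i),
                       test = length(te_i)),
    best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
    confusion = list(TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN),
    metrics = list(accuracy = met$accuracy, precision = met$precision,
                   recall = met$recall, F1 = met$F1, AUC = roc$auc),
    roc_curve = roc$curve)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)

  # -- manifest ----------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(report = report, features = features,
                 paths = list(features = feat_path, report = report_path,
                              model = model_path, config = cfg_path,
                              manifest = file.path(out_dir, "manifest.json"),
                              images = if (write_images) img_dir else NULL)))
}
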