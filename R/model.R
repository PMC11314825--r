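#' Model configuration for the residual classifier
#'
#' The network is a convolutional stem followed by three residual blocks and
#' two fully connected layers. Block 1 uses 2x2 kernels, blocks 2 and 3 use
#' 3x3 kernels; each block is two convolution + batch-normalisation + ReLU
#' stages with an additive skip connection (1x1 projection when shape
#' changes). The `rp2d` variant consumes S x S recurrence-plot images; the
#' `raw1d` variant mirrors it with 1-D convolutions (kernel lengths 2/3/3)
#' on the raw segment.
#'
#' @param variant `"rp2d"` or `"raw1d"`.
#' @param input_size Image side length S (rp2d) or series length L (raw1d).
#' @param stem_channels Channels out of the stem convolution (default 16).
#' @param block_channels Channel widths of the three residual blocks
#'   (default 16, 32, 64).
#' @param fc_units Width of the hidden fully connected layer (default 32).
#' @param num_classes Number of output classes (2).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("rp2d", "raw1d"), input_size = 64L,
                         stem_channels = 16L, block_channels = c(16L, 32L, 64L),
                         fc_units = 32L, num_classes = 2L) {
  variant <- match.arg(variant)
  if (length(block_channels) != 3L) {
    stop("exactly three residual blocks are used", call. = FALSE)
  }
  structure(list(variant = variant, input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 block_channels = as.integer(block_channels),
                 fc_units = as.integer(fc_units),
                 num_classes = as.integer(num_classes)),
            class = "model_config")
}

# He-normal initialisation for a conv/dense weight matrix.
he_init <- function(W) {
  fan_in <- nrow(W)
  W[] <- stats::rnorm(length(W), sd = sqrt(2 / fan_in))
  W
}

res_block <- function(in_ch, out_ch, k, stride) {
  kv <- k  # c(kh, kw)
  proj <- NULL
  proj_bn <- NULL
  if (in_ch != out_ch || any(stride != 1L)) {
    proj <- conv_layer(in_ch, out_ch, 1L, 1L, stride = stride,
                       pad = c(0L, 0L, 0L, 0L))
    proj_bn <- bn_layer(out_ch)
  }
  list(type = "resblock",
       conv1 = conv_layer(in_ch, out_ch, kv[1], kv[2], stride = stride),
       bn1 = bn_layer(out_ch),
       conv2 = conv_layer(out_ch, out_ch, kv[1], kv[2], stride = c(1L, 1L)),
       bn2 = bn_layer(out_ch),
       proj = proj, proj_bn = proj_bn)
}

#' Build the residual network classifier
#'
#' Constructs the network described by a [model_config()] with He-normal
#' initial weights drawn deterministically from `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `rp_resnet`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  oned <- config$variant == "raw1d"
  kdim <- function(k) if (oned) c(1L, k) else c(k, k)
  sdim <- function(s) if (oned) c(1L, s) else c(s, s)
  ch <- config$block_channels
  layers <- list(
    stem_conv = conv_layer(1L, config$stem_channels, kdim(3L)[1], kdim(3L)[2],
                           stride = sdim(2L)),
    stem_bn = bn_layer(config$stem_channels),
    stem_relu = list(type = "relu"),
    block1 = res_block(config$stem_channels, ch[1], kdim(2L), sdim(1L)),
    block2 = res_block(ch[1], ch[2], kdim(3L), sdim(2L)),
    block3 = res_block(ch[2], ch[3], kdim(3L), sdim(2L)),
    gap = list(type = "gap"),
    fc1 = dense_layer(ch[3], config$fc_units),
    fc1_relu = list(type = "relu"),
    fc2 = dense_layer(config$fc_units, config$num_classes, head = TRUE)
  )
  model <- structure(list(layers = layers, config = config),
                     class = "rp_resnet")
  with_seed(seed, init_weights(model))
}

init_weights <- function(model) {
  walk <- function(l) {
    if (!is.list(l)) return(l)
    if (!is.null(l$type) && l$type == "conv") {
      l$W <- he_init(l$W)
    } else if (!is.null(l$type) && l$type == "dense") {
      # The classification head starts near zero so an untrained model
      # predicts near-chance probabilities; hidden layers use He init.
      l$W <- if (isTRUE(l$head)) {
        matrix(stats::rnorm(length(l$W), sd = 0.01), nrow(l$W))
      } else he_init(l$W)
    } else if (!is.null(l$type) && l$type == "resblock") {
      for (nm in c("conv1", "conv2", "proj")) {
        if (!is.null(l[[nm]])) l[[nm]]$W <- he_init(l[[nm]]$W)
      }
    }
    l
  }
  model$layers <- lapply(model$layers, walk)
  model
}

block_forward <- function(block, A, training) {
  c1 <- conv_forward(block$conv1, A)
  b1 <- bn_forward(block$bn1, c1$out, training)
  block$bn1 <- b1$layer
  r1 <- relu_forward(b1$out)
  c2 <- conv_forward(block$conv2, r1$out)
  b2 <- bn_forward(block$bn2, c2$out, training)
  block$bn2 <- b2$layer
  if (!is.null(block$proj)) {
    pc <- conv_forward(block$proj, A)
    pb <- bn_forward(block$proj_bn, pc$out, training)
    block$proj_bn <- pb$layer
    skip <- pb$out
    proj_cache <- list(conv = pc$cache, bn = pb$cache)
  } else {
    skip <- A
    proj_cache <- NULL
  }
  sum_pre <- b2$out + skip
  r2 <- relu_forward(sum_pre)
  list(out = r2$out, block = block,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    proj = proj_cache))
}

block_backward <- function(block, cache, dOut) {
  dSum <- relu_backward(cache$r2, dOut)
  db2 <- bn_backward(block$bn2, cache$b2, dSum)
  dc2 <- conv_backward(block$conv2, cache$c2, db2$dIn)
  dr1 <- relu_backward(cache$r1, dc2$dIn)
  db1 <- bn_backward(block$bn1, cache$b1, dr1)
  dc1 <- conv_backward(block$conv1, cache$c1, db1$dIn)
  dA <- dc1$dIn
  grads <- list(conv1 = dc1$grads, bn1 = db1$grads,
                conv2 = dc2$grads, bn2 = db2$grads)
  if (!is.null(block$proj)) {
    dpb <- bn_backward(block$proj_bn, cache$proj$bn, dSum)
    dpc <- conv_backward(block$proj, cache$proj$conv, dpb$dIn)
    dA <- dA + dpc$dIn
    grads$proj <- dpc$grads
    grads$proj_bn <- dpb$grads
  } else {
    dA <- dA + dSum
  }
  list(dIn = dA, grads = grads)
}

# Full forward pass. `x` is (H, W, 1, N). Returns logits plus caches and the
# model (batch-norm running stats update during training).
model_forward <- function(model, x, training = FALSE) {
  L <- model$layers
  caches <- list()
  sc <- conv_forward(L$stem_conv, x);            caches$stem_conv <- sc$cache
  sb <- bn_forward(L$stem_bn, sc$out, training); caches$stem_bn <- sb$cache
  L$stem_bn <- sb$layer
  sr <- relu_forward(sb$out);                    caches$stem_relu <- sr$cache
  caches$stem_out_dim <- dim(sr$out)
  a <- sr$out
  for (bn in c("block1", "block2", "block3")) {
    bf <- block_forward(L[[bn]], a, training)
    L[[bn]] <- bf$block
    caches[[bn]] <- bf$cache
    a <- bf$out
  }
  gp <- gap_forward(a);                          caches$gap <- gp$cache
  f1 <- dense_forward(L$fc1, gp$out);            caches$fc1 <- f1$cache
  fr <- relu_forward(f1$out);                    caches$fc1_relu <- fr$cache
  f2 <- dense_forward(L$fc2, fr$out);            caches$fc2 <- f2$cache
  model$layers <- L
  list(logits = f2$out, model = model, caches = caches)
}

# Backward pass from dlogits; returns gradient tree parallel to the layers
# and the gradient w.r.t. the stem output (used by diagnostics).
model_backward <- function(model, caches, dlogits) {
  L <- model$layers
  g <- list()
  d2 <- dense_backward(L$fc2, caches$fc2, dlogits)
  g$fc2 <- d2$grads
  dfr <- relu_backward(caches$fc1_relu, d2$dIn)
  d1 <- dense_backward(L$fc1, caches$fc1, dfr)
  g$fc1 <- d1$grads
  da <- gap_backward(caches$gap, d1$dIn)
  for (bn in c("block3", "block2", "block1")) {
    bb <- block_backward(L[[bn]], caches[[bn]], da)
    g[[bn]] <- bb$grads
    da <- bb$dIn
  }
  d_stem_out <- da
  dsr <- relu_backward(caches$stem_relu, da)
  dsb <- bn_backward(L$stem_bn, caches$stem_bn, dsr)
  g$stem_bn <- dsb$grads
  dsc <- conv_backward(L$stem_conv, caches$stem_conv, dsb$dIn)
  g$stem_conv <- dsc$grads
  list(grads = g, d_stem_out = d_stem_out, dIn = dsc$dIn)
}

# ---- Adam over the nested parameter tree -------------------------------

trainable_names <- c("W", "b", "gamma", "beta")

adam_init <- function(layers) {
  walk <- function(l) {
    if (!is.list(l)) return(NULL)
    st <- list()
    for (nm in trainable_names) {
      if (!is.null(l[[nm]])) {
        st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
      }
    }
    for (nm in c("conv1", "bn1", "conv2", "bn2", "proj", "proj_bn")) {
      if (!is.null(l[[nm]])) st[[nm]] <- walk(l[[nm]])
    }
    st
  }
  lapply(layers, walk)
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(l, g, s) {
    if (is.null(g)) return(list(l = l, s = s))
    for (nm in trainable_names) {
      if (!is.null(g[[nm]]) && !is.null(l[[nm]])) {
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * g[[nm]]
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * g[[nm]]^2
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        l[[nm]] <- l[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    for (nm in c("conv1", "bn1", "conv2", "bn2", "proj", "proj_bn")) {
      if (!is.null(g[[nm]]) && !is.null(l[[nm]])) {
        r <- walk(l[[nm]], g[[nm]], s[[nm]])
        l[[nm]] <- r$l
        s[[nm]] <- r$s
      }
    }
    list(l = l, s = s)
  }
  for (nm in names(grads)) {
    if (!is.null(layers[[nm]]) && is.list(grads[[nm]])) {
      r <- walk(layers[[nm]], grads[[nm]], state[[nm]])
      layers[[nm]] <- r$l
      state[[nm]] <- r$s
    }
  }
  list(layers = layers, state = state)
}

#' @export
print.rp_resnet <- function(x, ...) {
  cat(sprintf("<rp_resnet> variant %s, input %d, %s trainable parameters\n",
              x$config$variant, x$config$input_size,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `rp_resnet`.
#' @return Integer parameter count (convolution and dense weights and
#'   biases, batch-norm scales and shifts).
#' @export
n_parameters <- function(model) {
  total <- 0L
  walk <- function(l) {
    if (!is.list(l)) return(invisible(NULL))
    for (nm in trainable_names) {
      if (!is.null(l[[nm]])) total <<- total + length(l[[nm]])
    }
    for (nm in c("conv1", "bn1", "conv2", "bn2", "proj", "proj_bn")) {
      if (!is.null(l[[nm]])) walk(l[[nm]])
    }
  }
  lapply(model$layers, walk)
  total
}

#' @export
summary.rp_resnet <- function(object, ...) {
  cat(sprintf("rp_resnet (%s)\n", object$config$variant))
  cat(sprintf("  input size   : %d\n", object$config$input_size))
  cat(sprintf("  stem channels: %d\n", object$config$stem_channels))
  cat(sprintf("  block widths : %s\n",
              paste(object$config$block_channels, collapse = " -> ")))
  cat(sprintf("  parameters   : %s (%.2f MB at 32-bit)\n",
              format(n_parameters(object), big.mark = ","),
              n_parameters(object) * 4 / 2^20))
  invisible(n_parameters(object))
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-5, the protocol's setting; the
#'   scaled-down synthetic benchmark uses 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (>= 1, default 10).
#' @param seed Integer seed controlling shuffling (default 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-5, batch_size = 16L, epochs = 100L,
                         patience = 10L, seed = 1L) {
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Evaluate mean loss and accuracy on a dataset in eval mode.
eval_on <- function(model, x, y, batch_size = 64L) {
  n <- dim(x)[4]
  losses <- numeric(0)
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    cl <- crossentropy_loss(fw$logits, y[idx])
    losses <- c(losses, cl$loss * length(idx))
    correct <- correct + sum(max.col(cl$probs) - 1L == y[idx])
  }
  list(loss = sum(losses) / n, acc = correct / n)
}

#' Train the residual classifier with early stopping
#'
#' Minibatch Adam on the cross-entropy loss. After every epoch the model is
#' scored on the validation set; training stops when the validation loss has
#' not improved for `patience` epochs, and the weights from the best
#' validation epoch are returned.
#'
#' @param model An `rp_resnet` from [build_model()].
#' @param train,validation Datasets: lists with `x` (array H x W x 1 x N)
#'   and `y` (integer labels in 0/1).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A list of class `rp_fit`: `model` (best weights), `history`
#'   (data frame with per-epoch train/validation loss and accuracy),
#'   `best_epoch`, `epochs_run`.
#' @export
train_model <- function(model, train, validation, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "rp_resnet"), inherits(config, "train_config"))
  y <- as.integer(train$y)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  n <- dim(train$x)[4]
  stopifnot(length(y) == n)

  state <- adam_init(model$layers)
  history <- data.frame()
  best_loss <- Inf
  best_layers <- model$layers
  best_epoch <- 0L
  stall <- 0L
  t_step <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- train$x[, , , idx, drop = FALSE]
        fw <- model_forward(model, xb, training = TRUE)
        model <- fw$model
        cl <- crossentropy_loss(fw$logits, y[idx])
        bw <- model_backward(model, fw$caches, cl$dlogits)
        t_step <- t_step + 1L
        up <- adam_step(model$layers, bw$grads, state, config$lr, t_step)
        model$layers <- up$layers
        state <- up$state
        ep_loss <- ep_loss + cl$loss * length(idx)
        ep_correct <- ep_correct + sum(max.col(cl$probs) - 1L == y[idx])
      }
      val <- eval_on(model, validation$x, as.integer(validation$y))
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val$loss, val_acc = val$acc))
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, val$loss, val$acc))
      }
      if (val$loss < best_loss - 1e-9) {
        best_loss <- val$loss
        best_layers <- model$layers
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$layers <- best_layers
  structure(list(model = model, history = history,
                 best_epoch = best_epoch, epochs_run = nrow(history)),
            class = "rp_fit")
}

#' Class-1 probabilities for a batch of inputs
#'
#' @param model An `rp_resnet` (trained or untrained) or an `rp_fit`.
#' @param x Input array (H x W x 1 x N) matching the model's configured
#'   input size.
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of length N: probability of class 1 (pre-AF), in
#'   input order.
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  if (inherits(model, "rp_fit")) model <- model$model
  stopifnot(inherits(model, "rp_resnet"))
  if (length(dim(x)) != 4L) stop("`x` must be a 4-d array", call. = FALSE)
  n <- dim(x)[4]
  p <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    p[idx] <- softmax_rows(fw$logits)[, 2L]
  }
  p
}

#' Stratified record-disjoint k-fold cross-validation
#'
#' Records (not segments) are assigned to folds, stratified by class, so no
#' record contributes to both a training and a validation fold. Each fold is
#' trained from scratch and scored on its validation fold.
#'
#' @param x Input array (H x W x 1 x N).
#' @param y Integer labels (0/1), length N.
#' @param record_ids Character record ids, length N.
#' @param config A [model_config()].
#' @param tconfig A [train_config()].
#' @param k Number of folds (default 5).
#' @return A list of class `rp_cv`: `folds` (per-fold `eval_metrics`),
#'   `mean` and `sd` of the metric vector across folds, `assignments`.
#' @export
crossvalidate <- function(x, y, record_ids, config = model_config(),
                          tconfig = train_config(), k = 5L) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(dim(x)[4] == n, length(record_ids) == n, k >= 2L)
  rec_lab <- tapply(y, record_ids, function(v) round(mean(v)))
  for (cls in c(0, 1)) {
    if (sum(rec_lab == cls) < k) {
      stop("each class needs at least k records for stratified folds",
           call. = FALSE)
    }
  }
  fold_of_rec <- with_seed(tconfig$seed, {
    f <- integer(length(rec_lab))
    names(f) <- names(rec_lab)
    for (cls in c(0, 1)) {
      recs <- sample(names(rec_lab)[rec_lab == cls])
      f[recs] <- rep_len(seq_len(k), length(recs))
    }
    f
  })
  fold <- fold_of_rec[record_ids]
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i
    model <- build_model(config, seed = tconfig$seed + i)
    fit <- train_model(model,
                       list(x = x[, , , tr, drop = FALSE], y = y[tr]),
                       list(x = x[, , , !tr, drop = FALSE], y = y[!tr]),
                       tconfig)
    p <- predict_proba(fit, x[, , , !tr, drop = FALSE])
    cm <- confusion_counts(y[!tr], as.integer(p >= 0.5))
    met <- classification_metrics(cm)
    met$AUC <- roc_auc(p, y[!tr])$auc
    folds[[i]] <- met
  }
  metnames <- c("accuracy", "precision", "recall", "F1", "AUC")
  tab <- sapply(folds, function(f) unlist(f[metnames]))
  structure(list(folds = folds,
                 mean = rowMeans(tab), sd = apply(tab, 1L, stats::sd),
                 assignments = fold),
            class = "rp_cv")
}
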