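# Small configurations keep these tests fast; the architecture is identical
# to the default apart from widths and input size.
tiny_config <- function(input_size = 8L) {
  model_config(input_size = input_size, stem_channels = 2L,
               block_channels = c(2L, 3L, 4L), fc_units = 5L)
}

rand_input <- function(n, s = 8L, seed = 1L) {
  set.seed(seed)
  array(runif(s * s * n), c(s, s, 1L, n))
}

test_that("forward pass yields two scores per input and softmax sums to one", {
  m <- build_model(tiny_config(), seed = 2L)
  x <- rand_input(5)
  fw <- rpaf:::model_forward(m, x)
  expect_identical(dim(fw$logits), c(5L, 2L))
  probs <- rpaf:::softmax_rows(fw$logits)
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)

  p <- predict_proba(m, x)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated inputs get identical probabilities; batch order is preserved
  x2 <- x[, , , c(1L, 1L, 3L, 2L), drop = FALSE]
  p2 <- predict_proba(m, x2)
  expect_equal(p2[1], p2[2])
  expect_equal(p2[3], p[3])
  expect_equal(p2[4], p[2])
})

test_that("a zeroed residual block passes non-negative input through unchanged", {
  blk <- rpaf:::res_block(3L, 3L, c(2L, 2L), c(1L, 1L))  # no projection
  blk$conv1$W[] <- 0; blk$conv2$W[] <- 0
  # batch norm in pass-through state: gamma 1, beta 0, running stats 0/1
  x <- array(abs(rnorm(6 * 6 * 3 * 2)), c(6, 6, 3, 2))
  out <- rpaf:::block_forward(blk, x, training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-6)
})

test_that("parameter count is positive, seed-invariant, and within the loose size bound", {
  n1 <- n_parameters(build_model(model_config(input_size = 64L), seed = 1L))
  n2 <- n_parameters(build_model(model_config(input_size = 64L), seed = 99L))
  expect_identical(n1, n2)
  expect_gt(n1, 0L)
  expect_lt(n1 * 4 / 2^20, 11)  # default fits in 11 MB at 32-bit
})

test_that("analytic gradients match numeric differentiation", {
  m <- build_model(tiny_config(), seed = 3L)
  x <- rand_input(4, seed = 5L)
  y <- c(0L, 1L, 1L, 0L)
  lossfun <- function(model) {
    fw <- rpaf:::model_forward(model, x, training = FALSE)
    rpaf:::crossentropy_loss(fw$logits, y)$loss
  }
  fw <- rpaf:::model_forward(m, x, training = FALSE)
  cl <- rpaf:::crossentropy_loss(fw$logits, y)
  bw <- rpaf:::model_backward(fw$model, fw$caches, cl$dlogits)

  eps <- 1e-5
  paths <- list(
    list(g = function(m) m$layers$stem_conv$W,
         s = function(m, v) { m$layers$stem_conv$W[] <- v; m },
         grad = bw$grads$stem_conv$W),
    list(g = function(m) m$layers$block2$conv1$W,
         s = function(m, v) { m$layers$block2$conv1$W[] <- v; m },
         grad = bw$grads$block2$conv1$W),
    list(g = function(m) m$layers$block1$bn1$gamma,
         s = function(m, v) { m$layers$block1$bn1$gamma <- v; m },
         grad = bw$grads$block1$bn1$gamma),
    list(g = function(m) m$layers$block3$proj$W,
         s = function(m, v) { m$layers$block3$proj$W[] <- v; m },
         grad = bw$grads$block3$proj$W),
    list(g = function(m) m$layers$fc1$W,
         s = function(m, v) { m$layers$fc1$W[] <- v; m },
         grad = bw$grads$fc1$W))
  set.seed(8)
  for (p in paths) {
    v <- p$g(m)
    for (i in sample(length(v), min(3L, length(v)))) {
      m2 <- m
      v2 <- v; v2[i] <- v[i] + eps; m2 <- p$s(m2, v2)
      up <- lossfun(m2)
      v2[i] <- v[i] - eps; m2 <- p$s(m2, v2)
      dn <- lossfun(m2)
      expect_equal(p$grad[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("gradient reaches the stem through three stacked blocks at initialization", {
  m <- build_model(tiny_config(16L), seed = 4L)
  x <- rand_input(4, 16L, seed = 6L)
  fw <- rpaf:::model_forward(m, x, training = FALSE)
  cl <- rpaf:::crossentropy_loss(fw$logits, c(0L, 1L, 0L, 1L))
  bw <- rpaf:::model_backward(fw$model, fw$caches, cl$dlogits)
  expect_gt(max(abs(bw$d_stem_out)), 0)
  expect_gt(max(abs(bw$grads$stem_conv$W)), 0)
})

test_that("an untrained model sits at chance: loss near ln 2, calibrated probabilities", {
  pbars <- vapply(1:10, function(s) {
    m <- build_model(tiny_config(16L), seed = s)
    x <- rand_input(16, 16L, seed = 100 + s)
    fw <- rpaf:::model_forward(m, x)
    loss <- rpaf:::crossentropy_loss(fw$logits, rep(0:1, 8))$loss
    expect_lt(abs(loss - log(2)), 0.2)
    mean(predict_proba(m, x))
  }, numeric(1))
  expect_true(all(pbars >= 0.2 & pbars <= 0.8))
})

test_that("training is seed-reproducible and rejects single-class sets", {
  x <- rand_input(12, seed = 9L)
  y <- rep(0:1, 6)
  ds <- list(x = x, y = y)
  cfg <- train_config(lr = 1e-3, batch_size = 4L, epochs = 2L, patience = 5L,
                      seed = 11L)
  f1 <- train_model(build_model(tiny_config(), 7L), ds, ds, cfg)
  f2 <- train_model(build_model(tiny_config(), 7L), ds, ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), 2L)

  expect_error(train_model(build_model(tiny_config(), 7L),
                           list(x = x, y = rep(0L, 12)), ds, cfg),
               "both classes")
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(patience = 0), "patience")
})

test_that("early stopping halts a run whose validation loss rises immediately", {
  set.seed(20)
  n <- 16
  x <- array(0, c(8, 8, 1, n))
  y <- rep(0:1, n / 2)
  # strong train signal; validation carries the opposite signal so fitting
  # the training set raises the validation loss monotonically
  for (i in 1:n) x[, , 1, i] <- y[i] + rnorm(64, sd = 0.05)
  xv <- x[, , , n:1, drop = FALSE]  # same images, flipped labels
  fit <- train_model(build_model(tiny_config(), 5L),
                     list(x = x, y = y), list(x = xv, y = y),
                     train_config(lr = 1e-2, batch_size = 8L, epochs = 50L,
                                  patience = 1L, seed = 3L))
  expect_lt(fit$epochs_run, 50L)
  expect_lte(fit$epochs_run, fit$best_epoch + 1L + 1L)
})

test_that("cross-validation partitions records stratified and reproducibly", {
  set.seed(30)
  n <- 40
  x <- array(runif(8 * 8 * n), c(8, 8, 1, n))
  y <- rep(0:1, each = n / 2)
  ids <- paste0("r", seq_len(n))  # one record per segment
  tc <- train_config(lr = 1e-3, batch_size = 8L, epochs = 1L, patience = 2L,
                     seed = 2L)
  cv <- crossvalidate(x, y, ids, tiny_config(), tc, k = 5L)
  # every record is validated exactly once
  expect_identical(sort(unique(cv$assignments)), 1:5)
  expect_identical(as.integer(table(cv$assignments)), rep(8L, 5))
  # folds are stratified: 4 of each class per fold
  for (i in 1:5) expect_identical(sum(y[cv$assignments == i]), 4L)
  expect_length(cv$folds, 5L)
  expect_equal(unname(cv$mean["accuracy"]),
               mean(vapply(cv$folds, `[[`, 0, "accuracy")))

  cv2 <- crossvalidate(x, y, ids, tiny_config(), tc, k = 5L)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$mean, cv2$mean)

  expect_error(crossvalidate(x, y, rep("r1", n), tiny_config(), tc, k = 5L),
               "at least k records")
})
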