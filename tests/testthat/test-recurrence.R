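test_that("delay embedding lays out lagged coordinates exactly", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  traj <- embed_trajectory(x, m = 3, tau = 3)
  expect_identical(dim(traj), c(4L, 3L))
  expect_equal(traj[1, ], c(x[1], x[4], x[7]))
  expect_equal(traj[4, ], c(x[4], x[7], x[10]))

  expect_identical(nrow(embed_trajectory(runif(5000), 3, 3)), 4994L)

  one <- embed_trajectory(x, m = 1, tau = 1)
  expect_equal(as.vector(one), x)

  expect_error(embed_trajectory(1:6, m = 4, tau = 2), "too short")
})

test_that("recurrence matrix honours the strict threshold and unit diagonal", {
  R <- recurrence_matrix(embed_trajectory(c(0, 1, 10), 1, 1), 0.2)
  expect_identical(matrix(as.integer(R), 3),
                   matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L), 3))
  expect_equal(attr(R, "eps"), 2)

  # strict inequality: at fraction 1 the extreme pair is non-recurrent
  set.seed(6)
  traj <- embed_trajectory(rnorm(50), 2, 2)
  R1 <- recurrence_matrix(traj, 1.0)
  d <- as.matrix(dist(traj))
  extreme <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_identical(R1[extreme[1], extreme[2]], 0L)
  expect_true(all(diag(R1) == 1L))

  expect_error(recurrence_matrix(embed_trajectory(rep(2, 10), 2, 1)),
               "degenerate")
  expect_error(recurrence_matrix(traj, 0), "eps_frac")
})

test_that("line histograms enumerate diagonal and vertical runs", {
  h <- line_histograms(as_rp(diag(5)))
  expect_identical(h$diag, 5L)               # one line: the LOI
  expect_identical(sort(h$vert), rep(1L, 5)) # five singleton columns

  ones <- line_histograms(as_rp(matrix(1, 4, 4)))
  expect_identical(sort(ones$diag), c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_identical(sort(ones$vert), rep(4L, 4))

  # checkerboard: parity is constant along a main-direction diagonal, so
  # even-offset diagonals are solid, odd-offset ones empty; columns
  # alternate and never reach a run of 2
  cb <- matrix(0L, 4, 4)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 1L
  hc <- line_histograms(as_rp(cb))
  expect_identical(sort(hc$diag), c(2L, 2L, 4L))
  expect_true(all(hc$vert == 1L))

  # Theiler window 1 drops the line of identity
  ht <- line_histograms(as_rp(diag(5)), theiler = 1L)
  expect_length(ht$diag, 0L)
})

test_that("run conservation: line lengths sum to the recurrent point count", {
  for (seed in 1:10) {
    set.seed(seed)
    R <- recurrence_matrix(embed_trajectory(rnorm(80), 2, 3), 0.3)
    h <- line_histograms(R)
    expect_identical(sum(h$diag), sum(R))
    expect_identical(sum(h$vert), sum(R))
  }
})

test_that("recurrence statistics match analytic cases", {
  M <- 6
  ones <- rqa_features(as_rp(matrix(1, M, M)))
  expect_equal(ones$REC, 1)
  expect_equal(ones$LAM, 1)
  expect_equal(ones$Lmax_norm, 1)
  # the two corner diagonals are single cells below lmin
  expect_equal(ones$DET, (M^2 - 2) / M^2)

  ident <- rqa_features(as_rp(diag(10)))
  expect_equal(ident$REC, 0.1)
  expect_equal(ident$DET, 1)  # all points on the length-10 diagonal
  expect_equal(ident$Lmax_norm, 1)

  # entropy: single line length -> 0; two lengths with equal counts -> ln 2
  h1 <- structure(list(diag = c(3L, 3L, 3L), vert = c(2L, 2L),
                       lmin = 2L, vmin = 2L, theiler = 0L, M = 10L,
                       n_recurrent = 13L), class = "line_histograms")
  expect_equal(rqa_features(h1)$ENTR, 0)
  h2 <- structure(list(diag = c(2L, 3L), vert = c(3L, 3L),
                       lmin = 2L, vmin = 2L, theiler = 0L, M = 10L,
                       n_recurrent = 11L), class = "line_histograms")
  expect_equal(rqa_features(h2)$ENTR, log(2))
  expect_equal(rqa_features(h2)$TT, 3)

  expect_equal(rqa_features(recurrence_matrix(
    embed_trajectory(c(0, 1, 10), 1, 1), 0.2))$REC, 5 / 9)
})

test_that("degenerate histograms flag and zero the line statistics", {
  f <- rqa_features(as_rp(diag(3)), vmin = 2L)
  expect_true(f$degenerate)   # no vertical line reaches vmin
  expect_equal(f$TT, 0)
  expect_equal(f$LAM, 0)
  expect_equal(f$REC, 1 / 3)  # REC always defined
})

test_that("recurrence matrices are invariant under affine amplitude rescaling", {
  set.seed(12)
  x <- rnorm(300)
  R0 <- recurrence_matrix(embed_trajectory(x, 3, 3), 0.1)
  for (i in 1:20) {
    a <- runif(1, -5, 5)
    if (abs(a) < 0.1) a <- a + 0.5
    b <- runif(1, -10, 10)
    R1 <- recurrence_matrix(embed_trajectory(a * x + b, 3, 3), 0.1)
    expect_identical(unclass(R1)[, ], unclass(R0)[, ])
  }
})

test_that("recurrence rate is monotone in the threshold fraction", {
  set.seed(13)
  traj <- embed_trajectory(rnorm(150), 3, 2)
  recs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.0), function(f) {
    rqa_features(recurrence_matrix(traj, f))$REC
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("vectorised implementation equals the naive oracle on random signals", {
  set.seed(14)
  for (trial in 1:25) {
    n <- sample(20:150, 1)
    m <- sample(1:3, 1)
    tau <- sample(1:3, 1)
    frac <- sample(c(0.05, 0.1, 0.3), 1)
    x <- rnorm(n)
    o <- naive_rqa(x, m, tau, frac)
    R <- recurrence_matrix(embed_trajectory(x, m, tau), frac)
    h <- line_histograms(R)
    f <- rqa_features(h)
    expect_identical(unclass(R)[, ], o$R)
    expect_identical(sort(h$diag), o$dl)
    expect_identical(sort(h$vert), o$vl)
    expect_equal(f$REC, o$REC)
    expect_equal(f$DET, o$DET)
    expect_equal(f$ENTR, o$ENTR)
    expect_equal(f$TT, o$TT)
    expect_equal(f$LAM, o$LAM)
    expect_equal(f$Lmean, o$Lmean)
    expect_equal(f$Lmax_norm, o$Lmax_norm)
  }
})

test_that("image pooling preserves density structure and the matrix mean", {
  expect_true(all(rp_to_image(as_rp(matrix(1, 50, 50)), 10) == 1))

  img <- rp_to_image(as_rp(diag(100)), 10)
  expect_equal(diag(img), rep(0.1, 10))
  expect_equal(sum(img) - sum(diag(img)), 0)
  expect_equal(mean(img), rqa_features(as_rp(diag(100)))$REC)

  # small matrices are zero-padded, not pooled
  small <- rp_to_image(as_rp(diag(5)), 8)
  expect_identical(dim(small), c(8L, 8L))
  expect_equal(small[1:5, 1:5], diag(5))
  expect_true(all(small[6:8, ] == 0))
})

test_that("feature tables carry metadata and one row per segment", {
  segs <- generate_dataset(3, duration = 2, fs = 250, seed = 2L)
  ft <- rqa_feature_table(segs, m = 3, tau = 3)
  expect_identical(nrow(ft), 6L)
  expect_true(all(rqa_feature_names() %in% names(ft)))
  expect_setequal(unique(ft$label), c(0L, 1L))
})
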