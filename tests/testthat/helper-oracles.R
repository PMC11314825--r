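# Independent oracles and fixture builders shared by the tests. Everything
# here is deliberately naive (double loops, explicit run scans) so it cannot
# share a bug with the vectorised implementation under test.

# Full naive recurrence analysis: explicit double-loop distances, explicit
# run-length scans along every diagonal and column, features from the
# defining formulas.
naive_rqa <- function(x, m, tau, frac, lmin = 2L, vmin = 2L) {
  N <- length(x)
  M <- N - (m - 1L) * tau
  U <- matrix(0, M, m)
  for (i in 1:M) for (k in 1:m) U[i, k] <- x[i + (k - 1L) * tau]
  D <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M) D[i, j] <- sqrt(sum((U[i, ] - U[j, ])^2))
  eps <- frac * max(D)
  R <- matrix(0L, M, M)
  for (i in 1:M) for (j in 1:M) if (D[i, j] < eps) R[i, j] <- 1L
  scan_runs <- function(v) {
    out <- integer(0); run <- 0L
    for (b in c(v, 0L)) {
      if (b == 1L) run <- run + 1L
      else { if (run > 0L) out <- c(out, run); run <- 0L }
    }
    out
  }
  dl <- integer(0)
  for (o in -(M - 1L):(M - 1L)) {
    idx <- which(row(R) - col(R) == o)
    dl <- c(dl, scan_runs(R[idx[order(idx)]]))
  }
  vl <- integer(0)
  for (j in 1:M) vl <- c(vl, scan_runs(R[, j]))
  nr <- sum(R)
  dmin <- dl[dl >= lmin]; vmin_l <- vl[vl >= vmin]
  entr <- if (length(dmin) > 0) {
    tab <- table(dmin); p <- as.numeric(tab) / sum(tab)
    -sum(p * log(p))
  } else 0
  list(R = R, dl = sort(dl), vl = sort(vl),
       REC = nr / M^2,
       DET = if (nr > 0 && length(dmin) > 0) sum(dmin) / nr else 0,
       ENTR = entr,
       TT = if (length(vmin_l) > 0) sum(vmin_l) / length(vmin_l) else 0,
       LAM = if (nr > 0 && length(vmin_l) > 0) sum(vmin_l) / nr else 0,
       Lmean = if (length(dmin) > 0) sum(dmin) / length(dmin) else 0,
       Lmax_norm = if (length(dl) > 0) max(dl) / M else 0)
}

# AUC by brute force over every positive-negative pair, ties counting 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Write a WFDB record (text header + binary signal file) into `dir`.
# `channels` is a list of integer ADC vectors of equal length.
write_wfdb_fixture <- function(dir, name, channels, fs, fmt = "16",
                               gain = 200, adc_zero = 0) {
  nsig <- length(channels)
  nsamp <- length(channels[[1]])
  hea <- file.path(dir, paste0(name, ".hea"))
  datname <- paste0(name, ".dat")
  sig_lines <- vapply(seq_len(nsig), function(i) {
    sprintf("%s %s %g 12 %d 0 0 0 ECG%d", datname, fmt, gain, adc_zero, i)
  }, character(1))
  writeLines(c(sprintf("%s %d %g %d", name, nsig, fs, nsamp), sig_lines), hea)
  interleaved <- as.integer(do.call(rbind, channels))  # sample-major
  dat <- file.path(dir, datname)
  if (fmt == "16") {
    writeBin(interleaved, dat, size = 2L, endian = "little")
  } else if (fmt == "212") {
    if (length(interleaved) %% 2L == 1L) interleaved <- c(interleaved, 0L)
    u <- bitwAnd(interleaved, 4095L)  # 12-bit two's complement
    s1 <- u[seq(1, length(u), 2)]
    s2 <- u[seq(2, length(u), 2)]
    bytes <- as.raw(rbind(bitwAnd(s1, 255L),
                          bitwOr(bitwShiftL(bitwAnd(bitwShiftR(s2, 8L), 15L), 4L),
                                 bitwAnd(bitwShiftR(s1, 8L), 15L)),
                          bitwAnd(s2, 255L)))
    writeBin(as.vector(bytes), dat)
  } else stop("unsupported fixture format")
  file.path(dir, name)
}

# A clean strictly periodic beat train.
clean_train <- function(hr = 60, duration = 10, fs = 500, seed = 5) {
  generate_ecg(rhythm_spec(hr, 0, "non_af_like"), noise = noise_none(),
               duration = duration, fs = fs, seed = seed)
}

# Wrap a plain 0/1 matrix as a recurrence_matrix for feature computation.
as_rp <- function(R) {
  structure(matrix(as.integer(R), nrow(R)),
            class = c("recurrence_matrix", "matrix", "array"))
}
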