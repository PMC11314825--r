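# Daubechies-5 filter bank and a Mallat-cascade discrete wavelet transform
# with half-point symmetric boundary extension. The decomposition filter is
# the standard published db5 scaling filter; the highpass is its quadrature
# mirror, and reconstruction filters are the time-reversed pair.

DB5_LO <- c(0.003335725285473771, -0.012580751999081999,
            -0.006241490212798274, 0.07757149384004572,
            -0.032244869584638375, -0.24229488706638203,
            0.13842814590132074, 0.7243085284377729,
            0.6038292697971896, 0.16010239797419293)
DB5_HI <- rev(DB5_LO) * rep(c(-1, 1), length.out = length(DB5_LO))

# Single-level analysis step. Returns list(ca, cd), each of length
# floor((n + L - 1) / 2).
dwt_step <- function(x, lo = DB5_LO, hi = DB5_HI) {
  n <- length(x)
  L <- length(lo)
  if (n < 2L) stop("signal too short for one decomposition level", call. = FALSE)
  # symmetric (half-point) extension by L-1 samples each side
  left <- rev(x[seq_len(min(L - 1L, n))])
  right <- rev(x[seq.int(max(1L, n - L + 2L), n)])
  while (length(left) < L - 1L) left <- c(left, rev(left))[seq_len(L - 1L)]
  while (length(right) < L - 1L) right <- c(right, rev(right))[seq_len(L - 1L)]
  ext <- c(left, x, right)
  E <- stats::embed(ext, L)
  keep <- seq(2L, n + L - 1L, by = 2L)
  list(ca = as.vector(E %*% lo)[keep], cd = as.vector(E %*% hi)[keep])
}

# Single-level synthesis step; `n` is the length of the signal that produced
# the coefficient pair.
idwt_step <- function(ca, cd, n, lo = DB5_LO, hi = DB5_HI) {
  L <- length(lo)
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq(1L, length(u), by = 2L)] <- c
    u
  }
  conv_full <- function(s, f) {
    sp <- c(numeric(L - 1L), s, numeric(L - 1L))
    as.vector(stats::embed(sp, L) %*% f)
  }
  rec <- conv_full(up(ca), rev(lo)) + conv_full(up(cd), rev(hi))
  rec[(L - 1L):(L - 2L + n)]
}

# Multi-level decomposition. Returns list(approx, details, lengths) where
# details[[1]] is the finest level (d1) and lengths tracks the input length
# of every analysis step for exact reconstruction.
wavedec <- function(x, level) {
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(a)
    st <- dwt_step(a)
    details[[j]] <- st$cd
    a <- st$ca
  }
  list(approx = a, details = details, lengths = lengths)
}

# Inverse of wavedec.
waverec <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], dec$lengths[j])
  }
  a
}
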