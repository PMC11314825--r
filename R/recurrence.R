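#' Time-delay phase-space embedding
#'
#' Reconstructs an m-dimensional trajectory from a scalar series using lagged
#' copies: point i is `(x(i), x(i + tau), ..., x(i + (m-1) tau))`. The
#' trajectory has `M = N - (m-1) * tau` points.
#'
#' @param x Numeric vector (or `ecg_signal`) of length N with
#'   `N > (m-1) * tau`.
#' @param m Embedding dimension (>= 1), default 3.
#' @param tau Time delay in samples (>= 1), default 3.
#' @return An M x m matrix of class `phase_trajectory` with attributes `m`
#'   and `tau`.
#' @export
#' @examples
#' embed_trajectory(1:10, m = 3, tau = 3)  # 4 points: (1,4,7) ... (4,7,10)
embed_trajectory <- function(x, m = 3L, tau = 3L) {
  if (inherits(x, "ecg_signal")) x <- x$samples
  x <- as.numeric(x)
  if (m < 1L || tau < 1L) stop("need m >= 1 and tau >= 1", call. = FALSE)
  N <- length(x)
  M <- N - (m - 1L) * tau
  if (M < 1L) stop("signal too short for this embedding", call. = FALSE)
  traj <- matrix(0, nrow = M, ncol = m)
  for (k in seq_len(m)) {
    traj[, k] <- x[seq.int((k - 1L) * tau + 1L, length.out = M)]
  }
  structure(traj, class = c("phase_trajectory", "matrix", "array"),
            m = as.integer(m), tau = as.integer(tau))
}

#' Thresholded recurrence matrix
#'
#' Marks pairs of trajectory points closer than `eps` in Euclidean distance,
#' with `eps` a fraction of the maximum pairwise distance. The comparison is
#' strict (`distance < eps`), so a pair exactly at the threshold is
#' non-recurrent; the main diagonal is always recurrent.
#'
#' @param traj A [embed_trajectory()] result (or any numeric matrix of
#'   points in rows).
#' @param eps_frac Threshold as a fraction of the maximum pairwise distance,
#'   in (0, 1\]; default 0.10.
#' @return An M x M binary integer matrix of class `recurrence_matrix` with
#'   attributes `eps` (absolute threshold actually used), `eps_frac`, `m`,
#'   `tau`.
#' @export
recurrence_matrix <- function(traj, eps_frac = 0.10) {
  if (!is.matrix(traj)) traj <- matrix(as.numeric(traj), ncol = 1L)
  if (eps_frac <= 0 || eps_frac > 1) {
    stop("`eps_frac` must lie in (0, 1]", call. = FALSE)
  }
  d <- as.matrix(stats::dist(traj))
  dmax <- max(d)
  if (dmax == 0) {
    stop("degenerate trajectory: all points identical (max distance 0)",
         call. = FALSE)
  }
  eps <- eps_frac * dmax
  R <- matrix(0L, nrow(d), ncol(d))
  R[d < eps] <- 1L
  structure(R, class = c("recurrence_matrix", "matrix", "array"),
            eps = eps, eps_frac = eps_frac,
            m = attr(traj, "m"), tau = attr(traj, "tau"))
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  M <- nrow(x)
  cat(sprintf("<recurrence_matrix> %d x %d, eps = %.4g (%.0f%% of max distance), density %.3f\n",
              M, M, attr(x, "eps"), 100 * attr(x, "eps_frac"),
              sum(x) / M^2))
  invisible(x)
}

# Lengths of maximal runs of 1s across a list of 0/1 vectors, via a single
# rle over the vectors concatenated with 0 separators.
run_lengths <- function(vecs) {
  if (length(vecs) == 0L) return(integer(0))
  v <- unlist(lapply(vecs, function(d) c(d, 0L)), use.names = FALSE)
  r <- rle(v)
  r$lengths[r$values == 1L]
}

#' Diagonal and vertical line-length histograms of a recurrence matrix
#'
#' Counts maximal runs of recurrent points along every diagonal (the main
#' diagonal included unless a Theiler window excludes it) and down every
#' column. These histograms are the raw material of all line-based
#' recurrence statistics.
#'
#' @param R A `recurrence_matrix` (any square 0/1 matrix is accepted).
#' @param lmin,vmin Minimum diagonal / vertical line lengths recorded in the
#'   `lmin`/`vmin` fields (counting itself keeps all lengths >= 1).
#' @param theiler Theiler window: diagonals with |i - j| < `theiler` are
#'   skipped. Default 0 keeps the main diagonal, matching the defining
#'   equations; 1 excludes only the line of identity.
#' @return A list of class `line_histograms`: `diag` and `vert` are integer
#'   vectors of run lengths (one entry per maximal line), plus `lmin`,
#'   `vmin`, `theiler`, `M`, `n_recurrent`.
#' @export
line_histograms <- function(R, lmin = 2L, vmin = 2L, theiler = 0L) {
  M <- nrow(R)
  stopifnot(ncol(R) == M)
  off <- row(R) - col(R)
  keep <- abs(off) >= theiler
  diags <- split(R[keep], off[keep])
  vert <- split(R, col(R))
  structure(list(diag = run_lengths(diags), vert = run_lengths(vert),
                 lmin = as.integer(lmin), vmin = as.integer(vmin),
                 theiler = as.integer(theiler), M = M,
                 n_recurrent = sum(R)),
            class = "line_histograms")
}

#' Recurrence quantification statistics
#'
#' Computes the standard scalar summaries of recurrence-plot structure:
#' \describe{
#'   \item{REC}{recurrence rate, the fraction of recurrent pairs among all
#'     M^2 pairs.}
#'   \item{DET}{determinism, the fraction of recurrent points lying on
#'     diagonal lines of length >= `lmin`.}
#'   \item{ENTR}{Shannon entropy (natural log) of the distribution of
#'     diagonal line lengths >= `lmin`.}
#'   \item{TT}{trapping time, the mean vertical line length over lines
#'     >= `vmin`.}
#'   \item{LAM}{laminarity, the fraction of recurrent points lying on
#'     vertical lines of length >= `vmin`.}
#'   \item{Lmean}{mean diagonal line length over lines >= `lmin`.}
#'   \item{Lmax_norm}{longest diagonal line divided by M.}
#' }
#' When no line reaches the minimum length the affected statistics are 0 and
#' the `degenerate` flag is set; REC is always defined.
#'
#' @param R A `recurrence_matrix`, or a `line_histograms` object.
#' @param lmin,vmin Minimum diagonal / vertical line lengths (default 2).
#' @param theiler Theiler window passed to [line_histograms()] (default 0:
#'   the line of identity is included, as the defining equations read).
#' @return An object of class `rqa_features`: a list with the seven
#'   statistics above plus `Lmax_raw`, `TT_norm`, `Lmean_norm` (lengths
#'   divided by M), `M` and `degenerate`.
#' @export
rqa_features <- function(R, lmin = 2L, vmin = 2L, theiler = 0L) {
  h <- if (inherits(R, "line_histograms")) R
       else line_histograms(R, lmin = lmin, vmin = vmin, theiler = theiler)
  M <- h$M
  nr <- h$n_recurrent
  dl <- h$diag
  vl <- h$vert
  dl_min <- dl[dl >= lmin]
  vl_min <- vl[vl >= vmin]
  degenerate <- length(dl_min) == 0L || length(vl_min) == 0L

  REC <- nr / M^2
  DET <- if (nr > 0 && length(dl_min) > 0) sum(dl_min) / nr else 0
  ENTR <- if (length(dl_min) > 0) {
    p <- tabulate(dl_min)
    p <- p[p > 0] / length(dl_min)
    -sum(p * log(p))
  } else 0
  TT <- if (length(vl_min) > 0) mean(vl_min) else 0
  LAM <- if (nr > 0 && length(vl_min) > 0) sum(vl_min) / nr else 0
  Lmean <- if (length(dl_min) > 0) mean(dl_min) else 0
  Lmax_raw <- if (length(dl) > 0) max(dl) else 0L
  structure(list(REC = REC, DET = DET, ENTR = ENTR, TT = TT, LAM = LAM,
                 Lmean = Lmean, Lmax_norm = Lmax_raw / M,
                 Lmax_raw = as.integer(Lmax_raw),
                 TT_norm = TT / M, Lmean_norm = Lmean / M,
                 M = M, degenerate = degenerate),
            class = "rqa_features")
}

#' @export
print.rqa_features <- function(x, ...) {
  cat(sprintf(paste0("<rqa_features> M = %d\n",
                     "  REC %.4f  DET %.4f  ENTR %.4f  TT %.3f  LAM %.4f\n",
                     "  Lmean %.3f  Lmax %d (Lmax/M %.4f)%s\n"),
              x$M, x$REC, x$DET, x$ENTR, x$TT, x$LAM,
              x$Lmean, x$Lmax_raw, x$Lmax_norm,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Names of the seven recurrence statistics in canonical order
#' @return Character vector.
#' @export
rqa_feature_names <- function() {
  c("REC", "DET", "ENTR", "TT", "LAM", "Lmean", "Lmax_norm")
}

#' Recurrence statistics as a one-row data frame
#' @param x An `rqa_features` object.
#' @param ... Unused.
#' @return A one-row data frame with the seven canonical statistics.
#' @export
as.data.frame.rqa_features <- function(x, ...) {
  as.data.frame(x[rqa_feature_names()])
}

#' Pool a recurrence matrix to a fixed-size grayscale image
#'
#' Block-average pooling: each output pixel is the local recurrence density
#' of the block of matrix entries it covers, so values lie in \[0, 1\] and,
#' when the matrix size is a multiple of the image size, the image mean
#' equals the recurrence rate. A matrix no larger than the target is
#' zero-padded (top-left) instead of pooled.
#'
#' @param R A `recurrence_matrix` (any square 0/1 matrix).
#' @param size Output side length S (>= 8), default 224.
#' @return An S x S numeric matrix in \[0, 1\].
#' @export
rp_to_image <- function(R, size = 224L) {
  if (size < 8L) stop("`size` must be >= 8", call. = FALSE)
  M <- nrow(R)
  R <- unclass(R)
  if (M <= size) {
    img <- matrix(0, size, size)
    img[seq_len(M), seq_len(M)] <- R
    return(img)
  }
  bin <- floor((seq_len(M) - 1L) * size / M) + 1L
  sums <- rowsum(t(rowsum(R + 0, bin)), bin)  # size x size block sums
  counts <- as.numeric(table(bin))
  out <- t(sums) / outer(counts, counts)
  dimnames(out) <- NULL
  out
}

#' Recurrence statistics for a collection of segments
#'
#' Convenience wrapper running embedding, recurrence matrix and
#' quantification over a list of segments and returning a tidy table.
#'
#' @param segments List of `ecg_signal` objects.
#' @param m,tau,eps_frac,lmin,vmin,theiler Passed to the underlying
#'   functions.
#' @return A data frame with `record`, `segment`, `label` and the seven
#'   canonical statistics, one row per segment.
#' @export
rqa_feature_table <- function(segments, m = 3L, tau = 3L, eps_frac = 0.10,
                              lmin = 2L, vmin = 2L, theiler = 0L) {
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    f <- rqa_features(
      recurrence_matrix(embed_trajectory(s, m = m, tau = tau),
                        eps_frac = eps_frac),
      lmin = lmin, vmin = vmin, theiler = theiler)
    cbind(data.frame(record = s$record_id,
                     segment = attr(s, "segment") %||% 1L,
                     label = s$label),
          as.data.frame(f))
  })
  do.call(rbind, rows)
}
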