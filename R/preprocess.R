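#' Min-max normalisation
#'
#' Maps a sample vector affinely onto \[0, 1\]: the minimum goes to 0 and the
#' maximum to 1. A constant vector (max equals min) maps to all zeros.
#'
#' @param x Numeric vector with at least 2 samples, or an `ecg_signal`.
#' @return Same type as the input, normalised.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))  # 0.0 0.5 1.0
minmax_normalize <- function(x) {
  if (inherits(x, "ecg_signal")) {
    x$samples <- minmax_normalize(x$samples)
    return(x)
  }
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(numeric(length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Wavelet decomposition depth from the frequency band of interest
#'
#' The number of dyadic levels needed so the deepest approximation band sits
#' below the lower frequency bound of the signal of interest:
#' `ceiling(log2(fs / fL))`. For a 500 Hz ECG with a 0.5 Hz lower bound this
#' gives 10 levels. The result is clamped to the maximum depth the signal
#' length permits when `n` is supplied.
#'
#' @param fs Sampling rate in Hz.
#' @param fL Lower frequency bound in Hz (default 0.5); must satisfy
#'   `fs > fL > 0`.
#' @param n Optional signal length used to clamp the depth to
#'   `floor(log2(n))`.
#' @return Integer number of levels.
#' @export
decomposition_level <- function(fs, fL = 0.5, n = NULL) {
  if (fL <= 0 || fs <= fL) stop("need fs > fL > 0", call. = FALSE)
  N <- as.integer(ceiling(log2(fs / fL) - 1e-9))
  if (!is.null(n)) N <- min(N, as.integer(floor(log2(n))))
  max(N, 1L)
}

#' Robust noise-scale estimate from detail coefficients
#'
#' The median-absolute-deviation estimator `median(|d|) / 0.6745`, where `d`
#' are the finest-level detail coefficients. For Gaussian noise this is a
#' consistent estimate of the noise standard deviation.
#'
#' @param d Numeric vector of detail coefficients (non-empty).
#' @return Non-negative noise scale.
#' @export
noise_sigma <- function(d) {
  if (length(d) == 0L) stop("empty coefficient sequence", call. = FALSE)
  stats::median(abs(d)) / 0.6745
}

#' Universal soft threshold
#'
#' Donoho's noise-adaptive threshold `T = delta * sqrt(2 * ln(n))` with
#' `delta` the noise scale and `n` the effective sample count.
#'
#' @param delta Noise scale (>= 0).
#' @param n Effective sample count (>= 2).
#' @return Threshold value.
#' @export
universal_threshold <- function(delta, n) {
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  delta * sqrt(2 * log(n))
}

#' Soft thresholding
#'
#' Shrinks a coefficient toward zero: values with magnitude below the
#' threshold become 0, larger values keep their sign and lose `threshold`
#' in magnitude.
#'
#' @param w Numeric coefficient(s).
#' @param threshold Threshold (>= 0).
#' @return Thresholded coefficient(s).
#' @export
#' @examples
#' soft_threshold(c(5, -5, 1.5), 2)  # 3 -3 0
soft_threshold <- function(w, threshold) {
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  sign(w) * pmax(abs(w) - threshold, 0)
}

#' Wavelet denoising configuration
#'
#' @param wavelet Wavelet family; only `"db5"` is provided.
#' @param level Decomposition depth; `NULL` derives it from the sampling rate
#'   via [decomposition_level()].
#' @param fL Lower frequency bound (Hz) used when deriving the depth.
#' @param remove_baseline Zero the deepest approximation band (removes slow
#'   baseline drift). Default `TRUE`.
#' @param threshold Numeric override of the threshold; `NULL` (default) uses
#'   the universal threshold with the noise scale estimated from the finest
#'   detail level and `n` = signal length.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(wavelet = "db5", level = NULL, fL = 0.5,
                           remove_baseline = TRUE, threshold = NULL) {
  if (wavelet != "db5") stop("only the db5 wavelet is provided", call. = FALSE)
  if (!is.null(level) && level < 1) stop("`level` must be >= 1", call. = FALSE)
  if (fL <= 0) stop("`fL` must be > 0", call. = FALSE)
  structure(list(wavelet = wavelet, level = level, fL = fL,
                 remove_baseline = remove_baseline, threshold = threshold),
            class = "wavelet_config")
}

#' Adaptive wavelet denoising of an ECG segment
#'
#' Decomposes the signal with the db5 filter bank, estimates the noise scale
#' from the finest detail level, soft-thresholds every detail level with the
#' universal threshold, optionally zeroes the deepest approximation band to
#' remove baseline drift, and reconstructs. Output length equals input
#' length; with the threshold forced to 0 and baseline retention the
#' round-trip is a perfect reconstruction.
#'
#' @param signal An `ecg_signal` or a plain numeric vector (then `fs` must be
#'   given).
#' @param config A [wavelet_config()].
#' @param fs Sampling rate, required only for plain numeric input.
#' @return Denoised signal of the same type as the input.
#' @export
denoise_ecg <- function(signal, config = wavelet_config(), fs = NULL) {
  if (inherits(signal, "ecg_signal")) {
    out <- signal
    out$samples <- denoise_ecg(signal$samples, config, fs = signal$fs)
    return(out)
  }
  x <- as.numeric(signal)
  if (is.null(fs)) stop("`fs` is required for numeric input", call. = FALSE)
  n <- length(x)
  level <- config$level %||% decomposition_level(fs, config$fL, n = n)
  if (n < 2^level) {
    stop(sprintf("signal of length %d too short for %d levels", n, level),
         call. = FALSE)
  }
  dec <- wavedec(x, level)
  threshold <- config$threshold %||%
    universal_threshold(noise_sigma(dec$details[[1]]), n)
  dec$details <- lapply(dec$details, soft_threshold, threshold = threshold)
  if (config$remove_baseline) {
    # Baseline = everything below fL: the deepest approximation band plus
    # any detail band lying wholly below fL (band of detail j is
    # [fs/2^(j+1), fs/2^j]).
    dec$approx[] <- 0
    for (j in seq_len(level)) {
      if (fs / 2^j <= config$fL) dec$details[[j]][] <- 0
    }
  }
  waverec(dec)
}
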