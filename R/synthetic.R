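#' Beat morphology template
#'
#' Describes one heartbeat as a sum of five Gaussian deflections (P, Q, R, S,
#' T). Each deflection has an amplitude in millivolt, a centre offset in
#' seconds relative to the R peak, and a width (Gaussian standard deviation)
#' in seconds. The defaults give a plausible lead-I beat with a dominant R
#' wave and a low, wide T wave.
#'
#' @param amplitudes Named numeric vector of deflection amplitudes (mV) for
#'   `p`, `q`, `r`, `s`, `t`.
#' @param centers Named numeric vector of centre offsets (s) relative to the
#'   R peak.
#' @param widths Named numeric vector of Gaussian widths (s), all positive.
#'
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(amplitudes = c(p = 0.15, q = -0.10, r = 1.00,
                                         s = -0.25, t = 0.35),
                          centers = c(p = -0.20, q = -0.035, r = 0.00,
                                      s = 0.035, t = 0.30),
                          widths = c(p = 0.025, q = 0.010, r = 0.012,
                                     s = 0.012, t = 0.060)) {
  nm <- c("p", "q", "r", "s", "t")
  stopifnot(setequal(names(amplitudes), nm), setequal(names(centers), nm),
            setequal(names(widths), nm))
  amplitudes <- amplitudes[nm]; centers <- centers[nm]; widths <- widths[nm]
  if (amplitudes[["r"]] <= 0) {
    stop("R-wave amplitude must be positive", call. = FALSE)
  }
  if (any(widths <= 0)) stop("all widths must be positive", call. = FALSE)
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths),
            class = "beat_template")
}

#' Rhythm specification for the synthetic ECG generator
#'
#' The two generated classes differ in rhythm irregularity (coefficient of
#' variation of the RR interval) and in P-wave visibility: the
#' pre-fibrillation-like class is built with strictly larger RR variability
#' and attenuated P waves, qualitatively mirroring the physiology of atria
#' prone to fibrillation. No clinical fidelity is claimed.
#'
#' @param heart_rate Mean heart rate in beats per minute, in \[30, 220\].
#' @param rr_cv Coefficient of variation of the RR interval (>= 0).
#' @param class_label `"pre_af_like"` or `"non_af_like"`.
#' @param p_wave_factor Multiplier applied to the template P-wave amplitude
#'   (1 keeps it, 0 removes it).
#'
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(heart_rate = 75, rr_cv = 0.04,
                        class_label = c("non_af_like", "pre_af_like"),
                        p_wave_factor = NULL) {
  class_label <- match.arg(class_label)
  if (!is.finite(heart_rate) || heart_rate < 30 || heart_rate > 220) {
    stop("`heart_rate` must lie in [30, 220] bpm", call. = FALSE)
  }
  if (!is.finite(rr_cv) || rr_cv < 0) {
    stop("`rr_cv` must be >= 0", call. = FALSE)
  }
  if (is.null(p_wave_factor)) {
    p_wave_factor <- if (class_label == "pre_af_like") 0.35 else 1.0
  }
  if (p_wave_factor < 0) stop("`p_wave_factor` must be >= 0", call. = FALSE)
  structure(list(heart_rate = heart_rate, rr_cv = rr_cv,
                 class_label = class_label, p_wave_factor = p_wave_factor),
            class = "rhythm_spec")
}

#' Default rhythm specification for a generated class
#'
#' The package-wide study conditions: both classes beat at 75 bpm, so rhythm
#' irregularity alone discriminates them. The non-AF-like class has RR
#' coefficient of variation 0.04 and full P waves; the pre-AF-like class has
#' coefficient of variation 0.18 and P waves attenuated to 35%. The long RR
#' pauses of the irregular class lengthen its laminar diastolic segments,
#' giving it the higher trapping time expected before fibrillation onset.
#'
#' @param class_label `"non_af_like"` or `"pre_af_like"`.
#' @return A `rhythm_spec`.
#' @export
default_rhythm <- function(class_label = c("non_af_like", "pre_af_like")) {
  class_label <- match.arg(class_label)
  if (class_label == "pre_af_like") {
    rhythm_spec(heart_rate = 75, rr_cv = 0.18, class_label = "pre_af_like")
  } else {
    rhythm_spec(heart_rate = 75, rr_cv = 0.04, class_label = "non_af_like")
  }
}

#' Noise specification for the synthetic ECG generator
#'
#' Models the three contaminants the denoiser targets: slow sinusoidal
#' baseline drift, mains powerline interference, and broadband muscle
#' artifact restricted to high frequencies.
#'
#' @param drift_amp Baseline drift amplitude (mV, >= 0).
#' @param drift_freq Baseline drift frequency (Hz, must be < 0.5).
#' @param powerline_amp Powerline amplitude (mV, >= 0).
#' @param powerline_freq Mains frequency, 50 or 60 Hz.
#' @param muscle_sd Muscle-artifact standard deviation (mV, >= 0).
#' @param muscle_corner High-pass corner of the muscle band (Hz, > 40).
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(drift_amp = 0.2, drift_freq = 0.25,
                       powerline_amp = 0.05, powerline_freq = 50,
                       muscle_sd = 0.05, muscle_corner = 45) {
  if (drift_amp < 0 || powerline_amp < 0 || muscle_sd < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  if (drift_freq >= 0.5 || drift_freq <= 0) {
    stop("`drift_freq` must lie in (0, 0.5) Hz", call. = FALSE)
  }
  if (!powerline_freq %in% c(50, 60)) {
    stop("`powerline_freq` must be 50 or 60 Hz", call. = FALSE)
  }
  if (muscle_corner <= 40) {
    stop("`muscle_corner` must exceed 40 Hz", call. = FALSE)
  }
  structure(list(drift_amp = drift_amp, drift_freq = drift_freq,
                 powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 muscle_sd = muscle_sd, muscle_corner = muscle_corner),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return A `noise_spec` with all amplitudes zero.
#' @export
noise_none <- function() {
  noise_spec(drift_amp = 0, powerline_amp = 0, muscle_sd = 0)
}

# White noise restricted to (corner, Nyquist) by zeroing FFT bins below the
# corner. Deterministic given the RNG state.
highpassed_noise <- function(n, sd, corner, fs) {
  x <- stats::rnorm(n, mean = 0, sd = sd)
  if (sd == 0) return(x)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs > corner & freqs < fs - corner  # symmetric bins
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Generate one synthetic single-lead ECG
#'
#' Lays down a beat train whose RR intervals are drawn from a lognormal
#' distribution with the requested mean rate and coefficient of variation,
#' renders each beat from the Gaussian-bump template, and adds the three
#' noise components. Identical arguments and seed reproduce the output
#' bit-for-bit; with all noise amplitudes zero the output is the clean beat
#' train.
#'
#' @param rhythm A [rhythm_spec()].
#' @param template A [beat_template()].
#' @param noise A [noise_spec()] (use [noise_none()] for a clean signal).
#' @param duration Signal duration in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed controlling RR draws, noise phases and noise.
#'
#' @return An `ecg_signal` labelled 1 for `pre_af_like`, 0 for `non_af_like`.
#' @export
#' @examples
#' s <- generate_ecg(default_rhythm("non_af_like"), seed = 1)
#' length(s$samples)  # 10 s at 500 Hz -> 5000
generate_ecg <- function(rhythm = default_rhythm(),
                         template = beat_template(),
                         noise = noise_spec(),
                         duration = 10, fs = 500, seed = 1L) {
  stopifnot(inherits(rhythm, "rhythm_spec"), inherits(template, "beat_template"),
            inherits(noise, "noise_spec"))
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  mean_rr <- 60 / rhythm$heart_rate

  with_seed(seed, {
    # RR intervals: lognormal with the requested mean and CV; CV = 0
    # degenerates to a strictly periodic train.
    n_beats <- ceiling(duration / mean_rr) + 8L
    if (rhythm$rr_cv > 0) {
      sdlog <- sqrt(log(1 + rhythm$rr_cv^2))
      meanlog <- log(mean_rr) - sdlog^2 / 2
      rr <- stats::rlnorm(n_beats, meanlog = meanlog, sdlog = sdlog)
    } else {
      rr <- rep(mean_rr, n_beats)
    }
    # First R peak placed half a mean RR in so the initial P wave is on-screen.
    r_times <- cumsum(c(mean_rr / 2, rr))
    r_times <- r_times[r_times < duration + 2 * mean_rr]

    amp <- template$amplitudes
    amp[["p"]] <- amp[["p"]] * rhythm$p_wave_factor
    x <- numeric(n)
    for (k in seq_along(r_times)) {
      for (w in names(amp)) {
        c_w <- r_times[k] + template$centers[[w]]
        sd_w <- template$widths[[w]]
        # Only evaluate within +-5 sd of the bump centre.
        i0 <- max(1L, ceiling((c_w - 5 * sd_w) * fs) + 1L)
        i1 <- min(n, floor((c_w + 5 * sd_w) * fs) + 1L)
        if (i0 > i1) next
        idx <- i0:i1
        x[idx] <- x[idx] + amp[[w]] * exp(-0.5 * ((t[idx] - c_w) / sd_w)^2)
      }
    }

    if (noise$drift_amp > 0) {
      x <- x + noise$drift_amp *
        sin(2 * pi * noise$drift_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise$powerline_amp > 0) {
      x <- x + noise$powerline_amp *
        sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise$muscle_sd > 0) {
      x <- x + highpassed_noise(n, noise$muscle_sd, noise$muscle_corner, fs)
    }

    label <- if (rhythm$class_label == "pre_af_like") 1L else 0L
    ecg_signal(x, fs = fs,
               record_id = sprintf("sim-%s-%d", rhythm$class_label, seed),
               lead = "I", label = label)
  })
}

#' Generate a balanced labelled collection of synthetic ECGs
#'
#' Draws `n_per_class` signals from each rhythm class. Per-signal seeds are
#' derived deterministically from the master seed, so the whole collection is
#' reproducible and individual signals can be regenerated in isolation.
#'
#' @param n_per_class Number of signals per class (>= 1).
#' @param duration,fs Passed to [generate_ecg()].
#' @param seed Master seed.
#' @param rhythms Named list with elements `non_af_like` and `pre_af_like`
#'   giving the class rhythm specifications (defaults to [default_rhythm()]).
#' @param template A [beat_template()].
#' @param noise A [noise_spec()].
#'
#' @return A list of `ecg_signal` objects, `2 * n_per_class` long, classes
#'   interleaved; each carries its label and a unique record id.
#' @export
generate_dataset <- function(n_per_class, duration = 10, fs = 500, seed = 1L,
                             rhythms = list(
                               non_af_like = default_rhythm("non_af_like"),
                               pre_af_like = default_rhythm("pre_af_like")),
                             template = beat_template(),
                             noise = noise_spec()) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  stopifnot(all(c("non_af_like", "pre_af_like") %in% names(rhythms)))
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1L, 2L * n_per_class))
  out <- vector("list", 2L * n_per_class)
  for (i in seq_len(n_per_class)) {
    for (j in 1:2) {
      cls <- c("non_af_like", "pre_af_like")[j]
      k <- 2L * (i - 1L) + j
      sig <- generate_ecg(rhythms[[cls]], template, noise,
                          duration = duration, fs = fs, seed = seeds[k])
      sig$record_id <- sprintf("sim-%s-%03d", cls, i)
      out[[k]] <- sig
    }
  }
  out
}
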