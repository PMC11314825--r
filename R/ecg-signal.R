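#' Construct an ECG signal object
#'
#' A uniformly sampled single-lead voltage series together with its sampling
#' rate and provenance. This is the container every other function in the
#' package consumes and produces.
#'
#' @param samples Numeric vector of voltages in millivolt.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param record_id Character record identifier (defaults to `"anonymous"`).
#' @param lead Character lead name (defaults to `"I"`).
#' @param label Optional class label: `1` for a pre-fibrillation segment,
#'   `0` for a non-fibrillation segment, `NA` when unlabelled.
#'
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs`, `record_id`, `lead` and `label`.
#' @export
#' @examples
#' s <- ecg_signal(sin(seq(0, 2 * pi, length.out = 250)), fs = 250)
#' s
ecg_signal <- function(samples, fs, record_id = "anonymous", lead = "I",
                       label = NA_integer_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("`label`, when present, must be 0 or 1", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         record_id = as.character(record_id), lead = as.character(lead),
         label = if (is.na(label)) NA_integer_ else as.integer(label)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  lab <- if (is.na(x$label)) "unlabelled" else
    if (x$label == 1L) "pre-AF (1)" else "non-AF (0)"
  cat(sprintf("<ecg_signal> record %s, lead %s: %d samples @ %g Hz (%.3g s), %s\n",
              x$record_id, x$lead, length(x$samples), x$fs, dur, lab))
  invisible(x)
}

#' Duration of an ECG signal in seconds
#' @param signal An `ecg_signal`.
#' @return Duration in seconds.
#' @export
ecg_duration <- function(signal) {
  stopifnot(inherits(signal, "ecg_signal"))
  length(signal$samples) / signal$fs
}

# Run `expr` under a fixed RNG state, restoring the caller's state afterwards.
# Keeps generator output independent of whatever the session did before.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
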