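#' Read one lead from a WFDB record
#'
#' Minimal reader for PhysioNet WFDB records: a text `.hea` header plus a
#' binary `.dat` signal file in format 16 (16-bit little-endian, interleaved)
#' or format 212 (packed 12-bit pairs). ADC counts are converted to millivolt
#' as `(adc - baseline) / gain`.
#'
#' @param record Path to the record, with or without the `.hea` extension.
#' @param lead Lead selector: 1-based channel index or the signal description
#'   string from the header.
#'
#' @return An `ecg_signal` with the channel's native sampling rate.
#' @export
read_wfdb <- function(record, lead = 1L) {
  hea <- if (grepl("\\.hea$", record)) record else paste0(record, ".hea")
  if (!file.exists(hea)) {
    stop(errorCondition(sprintf("WFDB header not found: %s", hea),
                        class = c("rpaf_missing_record", "error")))
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(errorCondition("WFDB header has no signal lines",
                        class = c("rpaf_bad_header", "error")))
  }
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L) {
    stop(errorCondition("malformed WFDB record line",
                        class = c("rpaf_bad_header", "error")))
  }
  record_id <- sub("/.*$", "", rec[1])
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*$", "", rec[3]))  # strip counter frequency
  nsamp <- as.integer(rec[4])
  sig_lines <- lines[2:(1 + nsig)]

  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- sub("[x:+].*$", "", tok[2])
    gain_tok <- if (length(tok) >= 3) tok[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE]+).*$", "\\1", gain_tok))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else if (length(tok) >= 5) as.numeric(tok[5]) else 0  # adc zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else sprintf("ch%d", NA_integer_)
    list(file = tok[1], fmt = fmt, gain = gain,
         baseline = ifelse(is.finite(baseline), baseline, 0), desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  descs <- vapply(sigs, function(s) s$desc, character(1))

  ch <- if (is.character(lead)) match(lead, descs) else as.integer(lead)
  if (is.na(ch) || ch < 1L || ch > nsig) {
    stop(errorCondition(sprintf("lead '%s' not present (record has %d signals)",
                                as.character(lead), nsig),
                        class = c("rpaf_missing_lead", "error")))
  }

  dat <- file.path(dirname(hea), sigs[[ch]]$file)
  if (!file.exists(dat)) {
    stop(errorCondition(sprintf("WFDB signal file not found: %s", dat),
                        class = c("rpaf_missing_record", "error")))
  }
  fmt <- sigs[[ch]]$fmt
  adc <- if (fmt == "16") {
    raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                   signed = TRUE, endian = "little")
    matrix(raw, nrow = nsig)[ch, ]
  } else if (fmt == "212") {
    read_fmt212(dat, nsig, nsamp)[ch, ]
  } else {
    stop(errorCondition(sprintf("unsupported WFDB format '%s'", fmt),
                        class = c("rpaf_bad_header", "error")))
  }
  if (length(adc) < nsamp) {
    stop(errorCondition("WFDB signal file shorter than header declares",
                        class = c("rpaf_bad_header", "error")))
  }
  mv <- (adc - sigs[[ch]]$baseline) / sigs[[ch]]$gain
  ecg_signal(mv, fs = fs, record_id = record_id, lead = descs[ch])
}

# Format 212: three bytes encode two 12-bit two's-complement samples.
read_fmt212 <- function(path, nsig, nsamp) {
  total <- nsig * nsamp
  bytes <- as.integer(readBin(path, "raw", n = ceiling(total / 2) * 3))
  b1 <- bytes[seq(1, length(bytes), 3)]
  b2 <- bytes[seq(2, length(bytes), 3)]
  b3 <- bytes[seq(3, length(bytes), 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8)
  s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 15L), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))[seq_len(total)]
  matrix(flat, nrow = nsig)
}

#' Read an ECG from a two-column CSV file
#'
#' Expects columns `time_s` (strictly increasing, uniform) and `mv`. The
#' sampling rate is inferred from the median time step; time steps deviating
#' from it by more than 1% make the file non-uniform and raise an error.
#'
#' @param path CSV file path.
#' @param label Optional class label to attach.
#' @param record_id Record id (defaults to the file name).
#' @return An `ecg_signal`.
#' @export
read_ecg_csv <- function(path, label = NA_integer_, record_id = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("rpaf_missing_record", "error")))
  }
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("expected two columns (time_s, mv)", call. = FALSE)
  t <- suppressWarnings(as.numeric(df[[1]]))
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(t) || anyNA(v)) stop("non-numeric rows in CSV", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    stop("non-uniform sampling (time step deviates by more than 1%)",
         call. = FALSE)
  }
  fs <- 1 / step
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  ecg_signal(v, fs = fs,
             record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
             label = label)
}

#' Write an ECG to a two-column CSV file
#'
#' Writes `time_s, mv` at full double precision so that
#' [read_ecg_csv()] round-trips the samples within float precision.
#'
#' @param signal An `ecg_signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  t <- (seq_along(signal$samples) - 1) / signal$fs
  lines <- c("time_s,mv",
             sprintf("%.17g,%.17g", t, signal$samples))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample an ECG to a new rate
#'
#' Fourier-method resampling: the signal's spectrum is truncated or
#' zero-padded to the new length, which band-limits (anti-aliases) on
#' downsampling. Output length is `round(n * fs_out / fs_in)`; when the
#' target equals the source rate the signal is returned untouched.
#'
#' @param signal An `ecg_signal`.
#' @param fs_out Target sampling rate in Hz (> 0).
#' @return An `ecg_signal` at `fs_out`.
#' @export
resample_ecg <- function(signal, fs_out) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (fs_out <= 0) stop("`fs_out` must be > 0", call. = FALSE)
  if (fs_out == signal$fs) return(signal)
  x <- signal$samples
  n <- length(x)
  n_out <- round(n * fs_out / signal$fs)
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- min(n, n_out) %/% 2
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  # Nyquist bin handling for even lengths: split/merge keeps the result real.
  if (min(n, n_out) %% 2 == 0) {
    nyq <- half + 1
    if (n_out < n) {
      Y[nyq] <- X[nyq] + X[n - nyq + 2]
    } else if (n_out > n) {
      Y[nyq] <- X[nyq] / 2
      Y[n_out - nyq + 2] <- X[nyq] / 2
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  out <- signal
  out$samples <- y
  out$fs <- fs_out
  out
}

#' Cut an ECG into fixed-length analysis windows
#'
#' Non-overlapping consecutive windows; a trailing remainder shorter than
#' one window is discarded. Each segment inherits the record id, lead and
#' label, and carries its 1-based index in attribute `"segment"`.
#'
#' @param signal An `ecg_signal`.
#' @param window Window length in seconds (> 0), default 10.
#' @return A list of `ecg_signal` segments (possibly empty).
#' @export
segment_ecg <- function(signal, window = 10) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  w <- round(window * signal$fs)
  k <- length(signal$samples) %/% w
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) {
    seg <- signal
    seg$samples <- signal$samples[((i - 1L) * w + 1L):(i * w)]
    attr(seg, "segment") <- i
    seg
  })
}

#' Train/validation/test split specification
#'
#' @param train,validation,test Positive fractions summing to 1
#'   (default 0.7/0.2/0.1).
#' @param unit `"record"` (no record id crosses partitions) or `"segment"`.
#' @param seed Integer seed for the shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.7, validation = 0.2, test = 0.1,
                       unit = c("record", "segment"), seed = 1L) {
  unit <- match.arg(unit)
  f <- c(train, validation, test)
  if (any(f <= 0) || abs(sum(f) - 1) > 1e-8) {
    stop("fractions must be positive and sum to 1", call. = FALSE)
  }
  structure(list(train = train, validation = validation, test = test,
                 unit = unit, seed = as.integer(seed)),
            class = "split_spec")
}

# Largest-remainder apportionment of n units over fractions; ties broken
# toward earlier partitions (training first).
apportion <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Split labelled segments into train/validation/test sets
#'
#' With `unit = "record"` whole records are apportioned, so no patient's
#' segments can appear on both sides of a train/test boundary. Counts follow
#' largest-remainder apportionment of the requested fractions.
#'
#' @param segments List of `ecg_signal` segments.
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `validation`, `test`, each a list of
#'   segments; the union is the input, the parts are disjoint.
#' @export
split_dataset <- function(segments, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), length(segments) >= 1L)
  if (spec$unit == "record") {
    ids <- vapply(segments, function(s) s$record_id, character(1))
    recs <- unique(ids)
    if (length(recs) < 3L) {
      stop("need at least 3 records for a record-level 3-way split",
           call. = FALSE)
    }
    counts <- apportion(length(recs),
                        c(spec$train, spec$validation, spec$test))
    shuffled <- with_seed(spec$seed, sample(recs))
    part_of_rec <- rep(c("train", "validation", "test"), counts)
    names(part_of_rec) <- shuffled
    part <- part_of_rec[ids]
  } else {
    n <- length(segments)
    counts <- apportion(n, c(spec$train, spec$validation, spec$test))
    idx <- with_seed(spec$seed, sample.int(n))
    part <- character(n)
    part[idx] <- rep(c("train", "validation", "test"), counts)
  }
  list(train = segments[part == "train"],
       validation = segments[part == "validation"],
       test = segments[part == "test"])
}
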