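# Waveform I/O, windowing and reassembly.
#
# Supported formats: mono 16-bit PCM WAV (RIFF), raw little-endian
# two's-complement int16, and plain text (one sample per line).  Headerless
# formats carry no rate, so sample_rate is taken from the caller (default
# 2000 Hz, the usual S-EMG acquisition rate).

#' Construct a signal record
#'
#' A `signal_record` holds a single-channel integer-sampled waveform
#' together with its sampling rate and quantization word length.
#'
#' @param samples Numeric vector of integer-valued ADC counts.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param bit_depth Bits per sample R, between 8 and 32; every sample must
#'   lie in `[-2^(R-1), 2^(R-1)-1]`.
#' @return Object of class `signal_record` with fields `samples`,
#'   `sample_rate`, `bit_depth`, `length`.
#' @export
signal_record <- function(samples, sample_rate = 2000, bit_depth = 16L) {
  samples <- as.numeric(samples)
  bit_depth <- as.integer(bit_depth)
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be > 0", call. = FALSE)
  }
  if (bit_depth < 8L || bit_depth > 32L) {
    stop("bit_depth must be in 8..32", call. = FALSE)
  }
  if (length(samples) && any(samples != floor(samples))) {
    stop("samples must be integer-valued ADC counts", call. = FALSE)
  }
  lo <- -2^(bit_depth - 1)
  hi <- 2^(bit_depth - 1) - 1
  if (length(samples) && (min(samples) < lo || max(samples) > hi)) {
    stop("samples outside the ", bit_depth, "-bit range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 bit_depth = bit_depth, length = length(samples)),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record: %d samples @ %g Hz, %d-bit (%.2f s)>\n",
              x$length, x$sample_rate, x$bit_depth,
              x$length / x$sample_rate))
  invisible(x)
}

.match_format <- function(format) {
  match.arg(format, c("wav16", "raw_int16", "text"))
}

# --- minimal RIFF/WAVE PCM16 reader and writer --------------------------

.read_wav16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      audio_format <- fmt[1]
      n_channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little")  # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little")  # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (audio_format != 1L || bits != 16L) {
        stop("only 16-bit PCM WAV is supported", call. = FALSE)
      }
      if (n_channels != 1L) {
        stop("multi-channel WAV is not supported", call. = FALSE)
      }
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz %/% 2L, size = 2L,
                         signed = TRUE, endian = "little")
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(sample_rate)) stop("WAV file has no fmt chunk", call. = FALSE)
  if (is.null(samples)) samples <- integer(0)
  list(samples = samples, sample_rate = sample_rate)
}

.write_wav16 <- function(samples, sample_rate, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")   # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  if (n) writeBin(as.integer(samples), con, size = 2L, endian = "little")
}

#' Read a waveform file
#'
#' @param path File path.
#' @param format One of `"wav16"` (mono 16-bit PCM WAV), `"raw_int16"`
#'   (headerless little-endian int16 stream), `"text"` (one integer per
#'   line).
#' @param sample_rate Sampling rate in Hz for the headerless formats;
#'   ignored for WAV (taken from the header).  Default 2000 Hz.
#' @return A [signal_record()].
#' @export
read_signal <- function(path, format = c("wav16", "raw_int16", "text"),
                        sample_rate = 2000) {
  format <- .match_format(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "wav16") {
    w <- .read_wav16(path)
    signal_record(w$samples, w$sample_rate, 16L)
  } else if (format == "raw_int16") {
    n <- file.size(path) %/% 2L
    con <- file(path, "rb")
    on.exit(close(con))
    s <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                 endian = "little")
    signal_record(s, sample_rate, 16L)
  } else {
    s <- scan(path, what = numeric(), quiet = TRUE)
    if (length(s) && (min(s) < -32768 || max(s) > 32767)) {
      stop("text samples outside the int16 range", call. = FALSE)
    }
    signal_record(s, sample_rate, 16L)
  }
}

#' Write a waveform file
#'
#' Inverse of [read_signal()]: the written file reads back with identical
#' samples.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @param format See [read_signal()].
#' @export
write_signal <- function(record, path,
                         format = c("wav16", "raw_int16", "text")) {
  format <- .match_format(format)
  stopifnot(inherits(record, "signal_record"))
  s <- record$samples
  if (format %in% c("wav16", "raw_int16") &&
      length(s) && (min(s) < -32768 || max(s) > 32767)) {
    stop("samples outside the int16 range", call. = FALSE)
  }
  if (format == "wav16") {
    .write_wav16(s, record$sample_rate, path)
  } else if (format == "raw_int16") {
    con <- file(path, "wb")
    on.exit(close(con))
    if (length(s)) writeBin(as.integer(s), con, size = 2L, endian = "little")
  } else {
    writeLines(format(s, scientific = FALSE, trim = TRUE), path)
  }
  invisible(NULL)
}

#' Segment a signal into fixed-length windows
#'
#' Splits the waveform into consecutive length-N blocks; the final block is
#' zero-padded to N and the pad count recorded so the decoder can truncate
#' back to the original length.
#'
#' @param record A [signal_record()] with at least one sample.
#' @param window_length Window length N; must be a power of two.
#' @return Object of class `window_set`: list with `windows` (list of
#'   length-N numeric vectors), `window_length`, `original_length`,
#'   `pad_count`.
#' @export
segment <- function(record, window_length = 2048L) {
  stopifnot(inherits(record, "signal_record"))
  n <- as.integer(window_length)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    stop("window_length must be a power of two >= 2", call. = FALSE)
  }
  k <- record$length
  if (k < 1L) stop("cannot segment an empty signal", call. = FALSE)
  n_win <- ceiling(k / n)
  pad <- as.integer(n_win * n - k)
  padded <- c(record$samples, numeric(pad))
  windows <- split(padded, rep(seq_len(n_win), each = n))
  names(windows) <- NULL
  structure(list(windows = windows, window_length = n,
                 original_length = k, pad_count = pad),
            class = "window_set")
}

#' Reassemble decoded windows into a signal
#'
#' Concatenates the windows in order and truncates to the original length,
#' undoing the zero padding added by [segment()].
#'
#' @param windows A `window_set` (decoded windows may be real-valued or
#'   integer-valued).
#' @param sample_rate,bit_depth Metadata for the output record.
#' @return A [signal_record()] of length `original_length`.
#' @export
reassemble <- function(windows, sample_rate = 2000, bit_depth = 16L) {
  stopifnot(inherits(windows, "window_set"))
  lens <- lengths(windows$windows)
  if (length(lens) && any(lens != windows$window_length)) {
    stop("inconsistent window lengths", call. = FALSE)
  }
  flat <- unlist(windows$windows, use.names = FALSE)
  if (is.null(flat)) flat <- numeric(0)
  k <- windows$original_length
  signal_record(flat[seq_len(k)], sample_rate, bit_depth)
}
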