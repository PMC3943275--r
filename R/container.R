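# Codec orchestration and the packed .semgz container.
#
# Layout (all integers little-endian):
#   magic "SEMG" | version u8 | sample_rate u32 | bit_depth u8 | K u32 |
#   N u32 | M u16 | levels u8 | wavelet char[8] (NUL-padded) | shape u8 |
#   Q u8 | L u8 | alpha f32 | beta f32 | B[m] u8 x M | n_windows u32 |
#   pad_count u32 | CRC-32 of all preceding bytes u32
# followed by one record per window: payload length u32 | payload bytes.
# The explicit B[m] vector makes the stream fully self-describing: the
# decoder never re-evaluates the shape curve, so reconstruction cannot
# drift from the encoder's plan.  The reported stream size counts
# everything, header included.

.SEMG_MAGIC <- "SEMG"
.SEMG_VERSION <- 1L

# CRC-32 as a signed 32-bit value so it survives writeBin(size = 4)
.crc32_int <- function(bytes) {
  v <- .cpp_crc32(bytes)
  as.integer(if (v >= 2^31) v - 2^32 else v)
}

#' Codec configuration
#'
#' Bundles and validates the parameters of every codec stage.  Defaults are
#' the standard operating point: 2048-sample windows, 16 sub-bands, an
#' 8-level Daubechies-4 transform, and the rotated-hyperbolic-tangent
#' allocation at Q = 10, L = 2.
#'
#' @param N Window length (power of two, divisible by `2^levels` and by M).
#' @param M Number of sub-bands.
#' @param wavelet Wavelet name (see [wavelet_filters()]).
#' @param levels Wavelet decomposition depth.
#' @param shape Allocation shape, one of `"dla"`, `"dsr"`, `"dea"`, `"rht"`.
#' @param Q,L Longest/shortest sub-band word length in bits.
#' @param alpha,beta RHT shape parameters (see [allocate_rht()]).
#' @return A validated list of class `codec_config`.
#' @export
codec_config <- function(N = 2048L, M = 16L, wavelet = "db4", levels = 8L,
                         shape = c("rht", "dla", "dsr", "dea"),
                         Q = 10L, L = 2L, alpha = 0.4, beta = 0.5) {
  shape <- match.arg(shape)
  N <- as.integer(N); M <- as.integer(M); levels <- as.integer(levels)
  Q <- as.integer(Q); L <- as.integer(L)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L) {
    stop("N must be a power of two", call. = FALSE)
  }
  if (N %% M != 0L) stop("M (", M, ") must divide N (", N, ")", call. = FALSE)
  if (N %% 2L^levels != 0L) {
    stop("2^levels (", 2L^levels, ") must divide N (", N, ")", call. = FALSE)
  }
  if (Q < 1L || Q > 16L) stop("Q must be in 1..16", call. = FALSE)
  wavelet_filters(wavelet)  # validates the name
  # validates shape-specific preconditions (L bounds etc.)
  plan <- allocate_bits(shape, Q, L, M, alpha, beta)
  structure(list(N = N, M = M, wavelet = wavelet, levels = levels,
                 shape = shape, Q = Q, L = L, alpha = alpha, beta = beta,
                 plan = plan),
            class = "codec_config")
}

.write_header <- function(con, h) {
  writeChar(.SEMG_MAGIC, con, eos = NULL)
  writeBin(.SEMG_VERSION, con, size = 1L)
  writeBin(as.integer(h$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(h$bit_depth), con, size = 1L)
  writeBin(as.integer(h$K), con, size = 4L, endian = "little")
  writeBin(as.integer(h$N), con, size = 4L, endian = "little")
  writeBin(as.integer(h$M), con, size = 2L, endian = "little")
  writeBin(as.integer(h$levels), con, size = 1L)
  wv <- charToRaw(h$wavelet)
  writeBin(c(wv, raw(8L - length(wv))), con)
  writeBin(unname(.shape_ids[h$shape]), con, size = 1L)
  writeBin(as.integer(h$Q), con, size = 1L)
  writeBin(as.integer(h$L), con, size = 1L)
  writeBin(as.numeric(h$alpha), con, size = 4L, endian = "little")
  writeBin(as.numeric(h$beta), con, size = 4L, endian = "little")
  writeBin(as.integer(h$bits), con, size = 1L)
  writeBin(as.integer(h$n_windows), con, size = 4L, endian = "little")
  writeBin(as.integer(h$pad_count), con, size = 4L, endian = "little")
}

.build_semgz <- function(h, payloads) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  .write_header(con, h)
  head_bytes <- rawConnectionValue(con)
  writeBin(.crc32_int(head_bytes), con, size = 4L, endian = "little")
  for (p in payloads) {
    writeBin(length(p), con, size = 4L, endian = "little")
    writeBin(p, con)
  }
  rawConnectionValue(con)
}

.parse_semgz <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  u <- function(size) readBin(con, "integer", 1L, size = size,
                              signed = size == 4L, endian = "little")
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, .SEMG_MAGIC)) {
    stop("format error: bad magic, not a .semgz stream", call. = FALSE)
  }
  version <- u(1L)
  if (version != .SEMG_VERSION) {
    stop("format error: unsupported version ", version, call. = FALSE)
  }
  h <- list()
  h$sample_rate <- u(4L)
  h$bit_depth <- u(1L)
  h$K <- u(4L)
  h$N <- u(4L)
  h$M <- u(2L)
  h$levels <- u(1L)
  wv <- readBin(con, "raw", 8L)
  h$wavelet <- rawToChar(wv[wv != as.raw(0)])
  shape_id <- u(1L)
  h$shape <- names(.shape_ids)[match(shape_id, .shape_ids)]
  if (is.na(h$shape)) stop("format error: unknown shape id", call. = FALSE)
  h$Q <- u(1L)
  h$L <- u(1L)
  h$alpha <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  h$beta <- readBin(con, "numeric", 1L, size = 4L, endian = "little")
  h$bits <- readBin(con, "integer", h$M, size = 1L)
  h$n_windows <- u(4L)
  h$pad_count <- u(4L)
  head_len <- seek(con)
  stored_crc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  crc <- .crc32_int(bytes[seq_len(head_len)])
  if (!identical(crc, stored_crc)) {
    stop("format error: header checksum mismatch", call. = FALSE)
  }
  payloads <- vector("list", h$n_windows)
  for (i in seq_len(h$n_windows)) {
    plen <- u(4L)
    if (is.na(plen) || plen < 0L) {
      stop("format error: corrupt window record", call. = FALSE)
    }
    p <- readBin(con, "raw", plen)
    if (length(p) != plen) {
      stop("format error: truncated window payload", call. = FALSE)
    }
    payloads[[i]] <- p
  }
  list(header = h, payloads = payloads)
}

.plan_from_header <- function(h) {
  .new_plan(h$shape, h$bits, h$Q, h$L, h$M, alpha = h$alpha, beta = h$beta)
}

#' Compress a signal
#'
#' Runs the full encoder: windowing, orthonormal wavelet transform,
#' sub-band quantization under the configured bit-allocation shape, and
#' adaptive arithmetic coding, packed into a self-describing byte stream.
#'
#' @param record A [signal_record()].
#' @param config A [codec_config()].
#' @return Object of class `semg_compressed`: list with `bytes` (the packed
#'   raw stream), `header` (parsed field list), `payloads`,
#'   `total_size_bytes`, and `clamp_count` (coefficients clamped at the
#'   quantizer across all windows).
#' @examples
#' x <- semg_synthetic(duration_s = 2, seed = 1)
#' cs <- compress(x, codec_config(shape = "rht", Q = 10, L = 2))
#' y <- decompress(cs)
#' percent_residual_difference(x, y)
#' @export
compress <- function(record, config = codec_config()) {
  stopifnot(inherits(record, "signal_record"), inherits(config, "codec_config"))
  plan <- config$plan
  clamp_total <- 0L
  if (record$length == 0L) {
    payloads <- list()
    n_windows <- 0L
    pad <- 0L
  } else {
    ws <- segment(record, config$N)
    n_windows <- length(ws$windows)
    pad <- ws$pad_count
    payloads <- vector("list", n_windows)
    for (i in seq_len(n_windows)) {
      cw <- forward_dwt(ws$windows[[i]], config$wavelet, config$levels)
      qw <- quantize(cw, plan, record$bit_depth)
      clamp_total <- clamp_total + qw$clamp_count
      payloads[[i]] <- entropy_encode(qw)
    }
  }
  h <- list(sample_rate = record$sample_rate, bit_depth = record$bit_depth,
            K = record$length, N = config$N, M = config$M,
            levels = config$levels, wavelet = config$wavelet,
            shape = config$shape, Q = config$Q, L = config$L,
            alpha = config$alpha, beta = config$beta, bits = plan$bits,
            n_windows = n_windows, pad_count = pad)
  bytes <- .build_semgz(h, payloads)
  structure(list(bytes = bytes, header = h, payloads = payloads,
                 total_size_bytes = length(bytes),
                 clamp_count = clamp_total),
            class = "semg_compressed")
}

#' @export
print.semg_compressed <- function(x, ...) {
  h <- x$header
  cat(sprintf(
    "<semg_compressed: %d samples, %s Q=%d L=%d, %d windows, %d bytes>\n",
    h$K, toupper(h$shape), h$Q, h$L, h$n_windows, x$total_size_bytes))
  invisible(x)
}

#' Decompress a packed stream
#'
#' Inverse pipeline: entropy decoding, inverse quantization, inverse
#' wavelet transform, integer rounding, and reassembly.  All decoder
#' configuration is read from the stream header; the encoder's config
#' object is never consulted.
#'
#' @param x A `semg_compressed`, a raw vector, or a path to a `.semgz`
#'   file.
#' @return A [signal_record()] of the original length.
#' @export
decompress <- function(x) {
  bytes <- if (inherits(x, "semg_compressed")) {
    x$bytes
  } else if (is.raw(x)) {
    x
  } else if (is.character(x) && length(x) == 1L) {
    readBin(x, "raw", file.size(x))
  } else {
    stop("x must be a semg_compressed object, raw vector or file path",
         call. = FALSE)
  }
  s <- .parse_semgz(bytes)
  h <- s$header
  if (h$n_windows == 0L) {
    return(signal_record(numeric(0), h$sample_rate, h$bit_depth))
  }
  plan <- .plan_from_header(h)
  windows <- vector("list", h$n_windows)
  for (i in seq_len(h$n_windows)) {
    sym <- entropy_decode(s$payloads[[i]], plan, h$N)
    xhat <- dequantize(sym, plan, h$bit_depth)
    windows[[i]] <- round_to_integer(inverse_dwt(xhat, h$wavelet, h$levels),
                                     h$bit_depth)
  }
  ws <- structure(list(windows = windows, window_length = h$N,
                       original_length = h$K, pad_count = h$pad_count),
                  class = "window_set")
  reassemble(ws, h$sample_rate, h$bit_depth)
}

#' Write a compressed stream to disk
#'
#' @param stream A `semg_compressed` from [compress()].
#' @param path Output file path (conventionally `.semgz`).
#' @return Invisibly, the number of bytes written.
#' @export
write_semgz <- function(stream, path) {
  stopifnot(inherits(stream, "semg_compressed"))
  writeBin(stream$bytes, path)
  invisible(length(stream$bytes))
}

#' Read a compressed stream from disk
#'
#' @param path Path to a `.semgz` file.
#' @return A `semg_compressed` object.
#' @export
read_semgz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", file.size(path))
  s <- .parse_semgz(bytes)
  structure(list(bytes = bytes, header = s$header, payloads = s$payloads,
                 total_size_bytes = length(bytes), clamp_count = NA_integer_),
            class = "semg_compressed")
}
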