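# Rate-distortion evaluation: compression factor (CF), percent residual
# difference (PRD), parameter sweeps and CF-binned bank-level curves.

#' Compression factor
#'
#' `CF = (O_S - C_S) / O_S * 100`, the percentage of storage saved, where
#' O_S and C_S are the original and compressed sizes in bits.
#'
#' @param original_bits O_S, size of the original data in bits (> 0).
#' @param compressed_bits C_S, size of the compressed stream in bits.
#' @return CF in percent.
#' @export
compression_factor <- function(original_bits, compressed_bits) {
  if (any(original_bits <= 0)) stop("original size must be > 0", call. = FALSE)
  (original_bits - compressed_bits) / original_bits * 100
}

#' Percent residual difference
#'
#' `PRD = sqrt(sum((x - xhat)^2) / sum(x^2)) * 100`, computed over all K
#' samples of the raw (non-normalized) signals.
#'
#' @param x Original [signal_record()] (or numeric vector).
#' @param xhat Reconstructed signal of the same length.
#' @return PRD in percent.
#' @export
percent_residual_difference <- function(x, xhat) {
  xs <- if (inherits(x, "signal_record")) x$samples else as.numeric(x)
  ys <- if (inherits(xhat, "signal_record")) xhat$samples else as.numeric(xhat)
  if (length(xs) != length(ys)) stop("signals differ in length", call. = FALSE)
  if (length(xs) < 1L) stop("signals must be nonempty", call. = FALSE)
  den <- sum(xs^2)
  if (den == 0) stop("PRD undefined for an all-zero reference", call. = FALSE)
  sqrt(sum((xs - ys)^2) / den) * 100
}

#' Evaluate one codec operating point
#'
#' Compresses and decompresses a signal and returns its (CF, PRD) point.
#'
#' @param record A [signal_record()].
#' @param config A [codec_config()].
#' @return One-row data frame: `shape`, `Q`, `L`, `alpha`, `beta`, `cf`,
#'   `prd`, `bytes`, `clamped`.
#' @export
rd_point <- function(record, config = codec_config()) {
  cs <- compress(record, config)
  xhat <- decompress(cs)
  o_bits <- record$length * record$bit_depth
  data.frame(shape = config$shape, Q = config$Q, L = config$L,
             alpha = config$alpha, beta = config$beta,
             cf = compression_factor(o_bits, 8 * cs$total_size_bytes),
             prd = percent_residual_difference(record, xhat),
             bytes = cs$total_size_bytes, clamped = cs$clamp_count)
}

#' Rate-distortion sweep
#'
#' Runs the codec over a grid of shapes and Q values at fixed L for every
#' signal in a bank, producing one (CF, PRD) point per combination.
#' Combinations whose parameters are invalid for a shape (e.g. L < 2 for
#' the exponential shape, or Q <= L) are skipped.
#'
#' @param signals A list of [signal_record()]s (a "bank"), optionally
#'   named.
#' @param shapes Character vector of allocation shapes.
#' @param Q_grid Integer vector of Q values to sweep.
#' @param L Shortest word length, fixed across the sweep.
#' @param config Base [codec_config()] supplying N, M, wavelet, levels,
#'   alpha, beta.
#' @param csv Optional path; when given the point table is also written as
#'   CSV.
#' @return Data frame with columns `signal`, `shape`, `Q`, `L`, `cf`,
#'   `prd`.
#' @export
rd_sweep <- function(signals, shapes = c("dla", "dsr", "dea", "rht"),
                     Q_grid = 15:2, L = 2L, config = codec_config(),
                     csv = NULL) {
  if (inherits(signals, "signal_record")) signals <- list(signals)
  ids <- names(signals)
  if (is.null(ids)) ids <- sprintf("signal%02d", seq_along(signals))
  rows <- list()
  for (i in seq_along(signals)) {
    for (shape in shapes) {
      for (Q in Q_grid) {
        cfg <- tryCatch(
          codec_config(N = config$N, M = config$M, wavelet = config$wavelet,
                       levels = config$levels, shape = shape, Q = Q, L = L,
                       alpha = config$alpha, beta = config$beta),
          error = function(e) NULL)
        if (is.null(cfg)) next
        pt <- rd_point(signals[[i]], cfg)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(signal = ids[i]), pt[c("shape", "Q", "L", "cf",
                                                  "prd")])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

#' Bank-level rate-distortion curves
#'
#' Aggregates sweep points into mean PRD per CF bin and shape, the form in
#' which bank-level codec comparisons are usually plotted.
#'
#' @param points Data frame from [rd_sweep()].
#' @param bin_width CF bin width in percentage points (default 1).
#' @return Data frame with columns `shape`, `cf_bin` (bin center), `prd`
#'   (mean), `n_points`.
#' @export
rd_curves <- function(points, bin_width = 1) {
  bin <- floor(points$cf / bin_width) * bin_width + bin_width / 2
  agg <- aggregate(points$prd, by = list(shape = points$shape, cf_bin = bin),
                   FUN = mean)
  cnt <- aggregate(points$prd, by = list(shape = points$shape, cf_bin = bin),
                   FUN = length)
  out <- data.frame(shape = agg$shape, cf_bin = agg$cf_bin, prd = agg$x,
                    n_points = cnt$x)
  out[order(out$shape, out$cf_bin), ]
}
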