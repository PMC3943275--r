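# Sub-band quantization of wavelet coefficients.
#
# Each coefficient is normalized by the full-scale value 2^(R-1) and scaled
# by its sub-band's lambda_m = 2^B[m]; the integer part (truncation toward
# zero, which keeps quantization odd-symmetric and free of DC bias) is the
# transmitted symbol.  Symbols are clamped to [-lambda_m, +lambda_m]: the
# orthonormal transform makes coefficients exceeding full scale rare but not
# impossible, and clamp events are counted so they can be reported.

#' Quantize a coefficient window
#'
#' Maps each coefficient X\[k\] to the integer symbol
#' `trunc(X[k] / 2^(R-1) * lambda_m)`, clamped to `[-lambda_m, lambda_m]`,
#' where m is the coefficient's sub-band.  Sub-bands allocated zero bits are
#' discarded: their symbols are forced to 0.
#'
#' @param coeffs A `coefficient_window` from [forward_dwt()], or a plain
#'   numeric vector.
#' @param plan An `allocation_plan`; `plan$M` must divide the window length.
#' @param bit_depth Word length R of the source signal (default 16).
#' @return Object of class `quantized_window`: list with `symbols`
#'   (length-N integer vector), `plan`, `bit_depth`, and `clamp_count` (how
#'   many coefficients hit the clamp).
#' @export
quantize <- function(coeffs, plan, bit_depth = 16L) {
  stopifnot(inherits(plan, "allocation_plan"))
  x <- if (inherits(coeffs, "coefficient_window")) coeffs$coefficients
       else as.numeric(coeffs)
  n <- length(x)
  if (n %% plan$M != 0L) stop("plan M must divide window length",
                              call. = FALSE)
  lam <- rep(plan$scale_factors, each = n %/% plan$M)
  q <- trunc(x / 2^(bit_depth - 1) * lam)
  clamped <- sum(q > lam | q < -lam)
  q <- pmin(pmax(q, -lam), lam)
  q[rep(plan$bits, each = n %/% plan$M) == 0L] <- 0
  structure(list(symbols = as.integer(q), plan = plan,
                 bit_depth = as.integer(bit_depth),
                 clamp_count = as.integer(clamped)),
            class = "quantized_window")
}

#' Inverse quantization
#'
#' Reconstructs approximate coefficients `Xhat[k] = symbol * 2^(R-1) /
#' lambda_m`.  For coefficients that were not clamped the reconstruction
#' error is below one quantization step `2^(R-1) / lambda_m`.
#'
#' @param qwin A `quantized_window`, or an integer symbol vector (then
#'   `plan` and `bit_depth` must be given).
#' @param plan,bit_depth Used when `qwin` is a bare vector.
#' @return Numeric vector of reconstructed coefficients.
#' @export
dequantize <- function(qwin, plan = NULL, bit_depth = 16L) {
  if (inherits(qwin, "quantized_window")) {
    plan <- qwin$plan
    bit_depth <- qwin$bit_depth
    qwin <- qwin$symbols
  }
  stopifnot(inherits(plan, "allocation_plan"))
  n <- length(qwin)
  lam <- rep(plan$scale_factors, each = n %/% plan$M)
  as.numeric(qwin) * 2^(bit_depth - 1) / lam
}
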