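# Dynamic bit allocation from decreasing spectral-shape models.
#
# The wavelet coefficient vector is split into M equal sub-bands; sub-band m
# gets a digital word length B[m] read off a decreasing curve between Q (the
# longest word, sub-band 0) and L (the shortest, sub-band M-1).  Because the
# coefficient index grows with frequency and S-EMG energy is concentrated at
# low frequency, fewer bits are spent where the expected energy is small.
# All curves use the smallest-integer-not-below rounding (ceiling), which is
# the only rounding that preserves the exact Q/L endpoints.

.shape_ids <- c(dla = 0L, dsr = 1L, dea = 2L, rht = 3L)

# smallest integer >= x, evaluated on values that are exact integers at the
# curve endpoints up to floating-point noise: snap at 1e-9 before ceiling
# so B[0] = Q and B[M-1] = L hold exactly
.intsup <- function(x) as.integer(ceiling(round(x, 9)))

.new_plan <- function(shape, bits, Q, L, M, alpha = NA_real_, beta = NA_real_) {
  bits <- as.integer(bits)
  structure(list(shape = shape, bits = bits, scale_factors = 2^bits,
                 Q = as.integer(Q), L = as.integer(L), M = as.integer(M),
                 alpha = alpha, beta = beta),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf("<allocation_plan %s: M=%d, Q=%d, L=%d>\n", toupper(x$shape),
              x$M, x$Q, x$L))
  cat("B[m]:", x$bits, "\n")
  invisible(x)
}

.check_ql <- function(Q, L, M, L_min = 0L) {
  if (M < 2L) stop("M must be >= 2", call. = FALSE)
  if (L > Q) stop("L must not exceed Q", call. = FALSE)
  if (L < L_min) stop("L must be >= ", L_min, " for this shape", call. = FALSE)
}

#' Decreasing linear bit allocation (DLA)
#'
#' `B[m] = ceil(Q - m (Q - L)/(M - 1))`: the word length falls linearly from
#' Q in the lowest-frequency sub-band to L in the highest.
#'
#' @param Q Longest digital word length (bits), sub-band 0.
#' @param L Shortest digital word length (bits), sub-band M-1.
#' @param M Number of sub-bands.
#' @return An `allocation_plan`: list with `shape`, `bits` (integer vector
#'   B of length M), `scale_factors` (`2^B`), `Q`, `L`, `M`.
#' @export
allocate_dla <- function(Q, L, M = 16L) {
  .check_ql(Q, L, M)
  m <- seq_len(M) - 1
  b <- .intsup(Q - (Q - L) / (M - 1) * m)
  .new_plan("dla", b, Q, L, M)
}

#' Decreasing square-root bit allocation (DSR)
#'
#' The word length decays like a square root between Q and L:
#' `B[m] = ceil(xi * sqrt(C - m))` with `C = Q^2 (1 - M) / (L^2 - Q^2)` and
#' `xi = Q / sqrt(C)`, so that B\[0\] = Q and B\[M-1\] = L exactly.
#' The degenerate case L == Q yields a flat allocation.
#'
#' @inheritParams allocate_dla
#' @return An `allocation_plan`.
#' @export
allocate_dsr <- function(Q, L, M = 16L) {
  .check_ql(Q, L, M)
  if (L == Q) return(.new_plan("dsr", rep(Q, M), Q, L, M))
  m <- seq_len(M) - 1
  C <- Q^2 * (1 - M) / (L^2 - Q^2)
  xi <- Q / sqrt(C)
  b <- .intsup(xi * sqrt(C - m))
  .new_plan("dsr", b, Q, L, M)
}

#' Decreasing exponential bit allocation (DEA)
#'
#' The word length decays exponentially from Q to L:
#' `B[m] = ceil(b^(p - m))` with `p = (1 - M) / (log10(L)/log10(Q) - 1)` and
#' `b = Q^(1/p)`, giving B\[0\] = Q and B\[M-1\] = L exactly.  Both Q and L
#' must exceed 1 (the closed form uses their logarithms); L == Q yields a
#' flat allocation.
#'
#' @inheritParams allocate_dla
#' @return An `allocation_plan`.
#' @export
allocate_dea <- function(Q, L, M = 16L) {
  .check_ql(Q, L, M, L_min = 2L)
  if (Q <= 1L) stop("Q must be > 1 for the exponential shape", call. = FALSE)
  if (L == Q) return(.new_plan("dea", rep(Q, M), Q, L, M))
  m <- seq_len(M) - 1
  p <- (1 - M) / (log10(L) / log10(Q) - 1)
  b <- Q^(1 / p)
  bits <- .intsup(b^(p - m))
  .new_plan("dea", bits, Q, L, M)
}

#' Rotated hyperbolic tangent bit allocation (RHT)
#'
#' A sigmoid word-length profile,
#' `B[m] = ceil((Q/2) (1 - tanh(alpha (m - M beta))))`, clamped to
#' `[L, Q]`.  `alpha` controls the steepness of the transition and `beta`
#' the position of its midpoint as a fraction of the M sub-bands.
#'
#' @inheritParams allocate_dla
#' @param alpha Transition slope (>= 0); `alpha = 0` gives a flat
#'   allocation at `ceil(Q/2)`.
#' @param beta Midpoint position as a fraction of M, in \[0, 1\].
#' @return An `allocation_plan` (with `alpha` and `beta` recorded).
#' @export
allocate_rht <- function(Q, L, M = 16L, alpha = 0.4, beta = 0.5) {
  .check_ql(Q, L, M)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  m <- seq_len(M) - 1
  b <- .intsup(Q / 2 * (1 - tanh(alpha * (m - M * beta))))
  b <- pmin(pmax(b, L), Q)
  .new_plan("rht", b, Q, L, M, alpha = alpha, beta = beta)
}

#' Compute a bit-allocation plan by shape name
#'
#' @param shape One of `"dla"`, `"dsr"`, `"dea"`, `"rht"`.
#' @inheritParams allocate_rht
#' @return An `allocation_plan`.
#' @export
allocate_bits <- function(shape = c("dla", "dsr", "dea", "rht"),
                          Q, L, M = 16L, alpha = 0.4, beta = 0.5) {
  shape <- match.arg(shape)
  switch(shape,
         dla = allocate_dla(Q, L, M),
         dsr = allocate_dsr(Q, L, M),
         dea = allocate_dea(Q, L, M),
         rht = allocate_rht(Q, L, M, alpha, beta))
}

#' Sub-band scale factors
#'
#' The quantizer scale factor of sub-band m is `lambda_m = 2^B[m]`.
#'
#' @param plan An `allocation_plan`.
#' @return Numeric vector of length M with the exact integer powers of two.
#' @export
scale_factors <- function(plan) {
  stopifnot(inherits(plan, "allocation_plan"))
  2^plan$bits
}

#' Sub-band index of a transform coefficient
#'
#' Coefficient k (0-based) of an N-point window belongs to sub-band
#' `m = floor(k / (N/M))`; each of the M sub-bands holds N/M consecutive
#' coefficients.
#'
#' @param k 0-based coefficient index (vectorized), `0 <= k < N`.
#' @param N Window length; must be a multiple of M.
#' @param M Number of sub-bands.
#' @return Integer vector of 0-based sub-band indices.
#' @export
subband_of <- function(k, N = 2048L, M = 16L) {
  if (N %% M != 0L) stop("M must divide N", call. = FALSE)
  if (any(k < 0L | k >= N)) stop("k out of range [0, N)", call. = FALSE)
  as.integer(k %/% (N %/% M))
}
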