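# Periodized orthonormal discrete wavelet transform.
#
# Boundary handling is circular (periodized) so the analysis operator is an
# exact N x N orthogonal matrix: the coefficient vector has the same length
# and the same Euclidean norm as the input window, which is the premise the
# sub-band quantizer relies on.  Coefficients are packed coarse to fine,
# [approx_L, detail_L, detail_{L-1}, ..., detail_1], so the index grows with
# frequency.

# one analysis step: x (even length) -> list(a, d) of half length each.
# The circular wrap only reaches taps-2 samples past the end, so when the
# block is long enough the gather runs on a padded copy with plain indices.
.dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  taps <- length(h)
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  if (taps - 2L <= n) {
    xp <- c(x, x[seq_len(taps - 2L)])
    for (j in seq_along(h)) {
      xs <- xp[base + j]
      a <- a + h[j] * xs
      d <- d + g[j] * xs
    }
  } else {
    for (j in seq_along(h)) {
      xs <- x[(base + (j - 1L)) %% n + 1L]
      a <- a + h[j] * xs
      d <- d + g[j] * xs
    }
  }
  list(a = a, d = d)
}

# one synthesis step: exact adjoint (= inverse) of .dwt_step
.idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  taps <- length(h)
  base <- 2L * (seq_len(half) - 1L)
  if (taps - 2L <= n) {
    xp <- numeric(n + taps - 2L)
    for (j in seq_along(h)) {
      idx <- base + j
      xp[idx] <- xp[idx] + h[j] * a + g[j] * d
    }
    x <- xp[seq_len(n)]
    tail_idx <- seq_len(taps - 2L)
    x[tail_idx] <- x[tail_idx] + xp[n + tail_idx]
  } else {
    x <- numeric(n)
    for (j in seq_along(h)) {
      idx <- (base + (j - 1L)) %% n + 1L
      x[idx] <- x[idx] + h[j] * a + g[j] * d
    }
  }
  x
}

#' Forward orthonormal wavelet transform of one window
#'
#' Applies a `levels`-deep periodized Daubechies wavelet decomposition to a
#' length-N sample window.  The transform is orthonormal: the output has
#' length N and preserves the window's energy exactly (up to floating-point
#' rounding), so the coefficient magnitudes live on the same scale as the
#' input ADC counts.
#'
#' @param window Numeric vector of N samples; N must be divisible by
#'   `2^levels`.
#' @param wavelet Wavelet name (see [wavelet_filters()]); default `"db4"`.
#' @param levels Decomposition depth; default 8.
#' @return Object of class `coefficient_window`: a list with `coefficients`
#'   (length-N numeric, ordered coarse approximation first, then detail
#'   bands from coarsest to finest), `levels`, and `wavelet`.
#' @examples
#' w <- sin(2 * pi * 50 * (0:255) / 2000)
#' cw <- forward_dwt(w, "db4", 4)
#' all.equal(sum(cw$coefficients^2), sum(w^2))
#' @export
forward_dwt <- function(window, wavelet = "db4", levels = 8L) {
  n <- length(window)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (n %% (2L^levels) != 0L) {
    stop("window length ", n, " is not divisible by 2^levels = ", 2L^levels,
         call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  a <- as.numeric(window)
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    s <- .dwt_step(a, f$h, f$g)
    a <- s$a
    details[[lev]] <- s$d
  }
  coeffs <- c(a, unlist(rev(details), use.names = FALSE))
  structure(list(coefficients = coeffs, levels = levels, wavelet = wavelet),
            class = "coefficient_window")
}

#' Inverse orthonormal wavelet transform
#'
#' Exact inverse of [forward_dwt()] up to floating-point tolerance.
#'
#' @param coeffs A `coefficient_window`, or a plain numeric coefficient
#'   vector (then `wavelet` and `levels` must be supplied).
#' @param wavelet,levels Used only when `coeffs` is a bare numeric vector.
#' @return Numeric vector: the reconstructed real-valued window.
#' @export
inverse_dwt <- function(coeffs, wavelet = "db4", levels = 8L) {
  if (inherits(coeffs, "coefficient_window")) {
    wavelet <- coeffs$wavelet
    levels <- coeffs$levels
    coeffs <- coeffs$coefficients
  }
  n <- length(coeffs)
  levels <- as.integer(levels)
  if (n %% (2L^levels) != 0L) {
    stop("coefficient length ", n, " inconsistent with ", levels, " levels",
         call. = FALSE)
  }
  f <- wavelet_filters(wavelet)
  alen <- n %/% 2L^levels
  a <- coeffs[seq_len(alen)]
  pos <- alen
  for (lev in seq(levels, 1L)) {
    dlen <- n %/% 2L^lev
    d <- coeffs[pos + seq_len(dlen)]
    pos <- pos + dlen
    a <- .idwt_step(a, d, f$h, f$g)
  }
  a
}

#' Round a real-valued block back to integer samples
#'
#' Rounds half away from zero, then clamps to the signed range of the given
#' bit depth.  Used as the final step of signal reconstruction.
#'
#' @param window Numeric vector.
#' @param bit_depth Bits per sample R; samples are clamped to
#'   `[-2^(R-1), 2^(R-1)-1]`.
#' @return Integer-valued numeric vector.
#' @export
round_to_integer <- function(window, bit_depth = 16L) {
  r <- sign(window) * floor(abs(window) + 0.5)
  lo <- -2^(bit_depth - 1)
  hi <- 2^(bit_depth - 1) - 1
  pmin(pmax(r, lo), hi)
}
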