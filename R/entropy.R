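# Entropy coding of the quantized-symbol stream.
#
# Sub-bands sharing a word length B share one adaptive frequency model with
# alphabet {-lambda, ..., +lambda} (size 2^(B+1) + 1); zero-bit sub-bands
# carry no information (their symbols are fixed at 0) and cost no bits.
# Each window is coded independently with fresh models, so windows are
# individually decodable and no side information is transmitted.

# context layout shared by encode/decode: per-coefficient model index and
# per-model alphabet size, derived from the allocation plan alone
.entropy_contexts <- function(plan, n) {
  widths <- rep(plan$bits, each = n %/% plan$M)
  uw <- sort(unique(widths))
  ctx <- match(widths, uw) - 1L
  asize <- ifelse(uw == 0L, 1L, 2L * 2L^uw + 1L)
  list(ctx = ctx, alphabet_sizes = as.integer(asize),
       lambda = ifelse(widths == 0L, 0L, 2L^widths))
}

#' Entropy-encode a quantized window
#'
#' Losslessly compresses the symbol vector with an adaptive arithmetic
#' coder.  The payload is self-checking: a CRC-32 of the symbol stream is
#' appended, so decoding with a mismatched plan or a truncated payload
#' raises an error rather than returning garbage.
#'
#' @param qwin A `quantized_window` from [quantize()], or an integer symbol
#'   vector (then `plan` must be given).
#' @param plan Used when `qwin` is a bare vector.
#' @return Raw vector: the compressed payload.
#' @export
entropy_encode <- function(qwin, plan = NULL) {
  if (inherits(qwin, "quantized_window")) {
    plan <- qwin$plan
    qwin <- qwin$symbols
  }
  stopifnot(inherits(plan, "allocation_plan"))
  cx <- .entropy_contexts(plan, length(qwin))
  if (any(abs(qwin) > cx$lambda)) {
    stop("symbol outside its sub-band alphabet", call. = FALSE)
  }
  .cpp_arith_encode(as.integer(qwin + cx$lambda), cx$ctx, cx$alphabet_sizes)
}

#' Entropy-decode a window payload
#'
#' Exact inverse of [entropy_encode()] given the same plan and window
#' length.
#'
#' @param payload Raw vector from [entropy_encode()].
#' @param plan The `allocation_plan` the payload was encoded under.
#' @param n Window length N (number of symbols).
#' @return Integer symbol vector of length `n`.
#' @export
entropy_decode <- function(payload, plan, n) {
  stopifnot(inherits(plan, "allocation_plan"))
  cx <- .entropy_contexts(plan, n)
  sym <- .cpp_arith_decode(payload, cx$ctx, cx$alphabet_sizes)
  as.integer(sym - cx$lambda)
}
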