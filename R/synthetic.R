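# Surrogate S-EMG generator.
#
# Surface EMG at constant contraction is well approximated, for codec
# purposes, by band-limited Gaussian noise: the generator shapes white
# noise with a zero-phase Butterworth band-pass over the standard surface
# EMG bandwidth (20-450 Hz at a 2 kHz rate).  The isometric regime keeps a
# constant envelope; the dynamic (cycling) regime modulates the noise with
# periodic activation bursts separated by near-silent intervals, with
# raised-cosine ramps so the envelope has no discontinuities and a small
# noise floor (1% of full scale) standing in for baseline instrumentation
# noise.  Physiological detail (motor-unit firing statistics, fatigue
# drift) is intentionally out of scope.

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.burst_envelope <- function(n, sample_rate, burst_rate_hz, duty_cycle,
                            ramp_s = 0.05) {
  t <- (seq_len(n) - 1) / sample_rate
  phase <- (t * burst_rate_hz) %% 1   # position within the burst cycle
  on_len <- duty_cycle
  ramp <- ramp_s * burst_rate_hz      # ramp length as a cycle fraction
  ramp <- min(ramp, on_len / 2)
  env <- numeric(n)
  inside <- phase < on_len
  env[inside] <- 1
  rise <- inside & phase < ramp
  env[rise] <- 0.5 * (1 - cos(pi * phase[rise] / ramp))
  fall <- inside & phase > (on_len - ramp)
  env[fall] <- 0.5 * (1 - cos(pi * (on_len - phase[fall]) / ramp))
  env
}

#' Generate a surrogate S-EMG signal
#'
#' @param protocol `"isometric"` (stationary, constant envelope) or
#'   `"dynamic"` (cyclic activation bursts, emulating pedaling).
#' @param duration_s Duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 2000).
#' @param rms_level Target RMS amplitude as a fraction of full scale
#'   (`2^15`); default 0.125, about 4096 ADC counts.  The default leaves
#'   enough headroom that the orthonormal transform's coefficients stay
#'   within the 16-bit word, the dynamic-range regime the codec's
#'   quantizer is designed around; push it higher to study clamping.
#' @param band Pass band in Hz, default `c(20, 450)`.
#' @param burst_rate_hz Activation burst rate for the dynamic protocol
#'   (default 1 Hz, a typical pedaling cadence per leg).
#' @param duty_cycle Fraction of each burst cycle with muscle activity
#'   (default 0.5).
#' @param noise_floor Off-interval noise amplitude as a fraction of full
#'   scale (dynamic protocol; default 0.01).
#' @param seed RNG seed; the output is a deterministic function of the
#'   arguments.  The caller's RNG state is left untouched.
#' @return A 16-bit [signal_record()].
#' @examples
#' x <- semg_synthetic("isometric", duration_s = 1, seed = 7)
#' sd(x$samples) / 2^15   # close to rms_level
#' @export
semg_synthetic <- function(protocol = c("isometric", "dynamic"),
                           duration_s = 10, sample_rate = 2000,
                           rms_level = 0.125, band = c(20, 450),
                           burst_rate_hz = 1, duty_cycle = 0.5,
                           noise_floor = 0.01, seed = 1L) {
  protocol <- match.arg(protocol)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < sample_rate / 2)) {
    stop("band must satisfy 0 < low < high < sample_rate/2", call. = FALSE)
  }
  if (rms_level <= 0 || rms_level >= 1) {
    stop("rms_level must be in (0, 1)", call. = FALSE)
  }
  if (duty_cycle <= 0 || duty_cycle > 1) {
    stop("duty_cycle must be in (0, 1]", call. = FALSE)
  }
  n <- round(duration_s * sample_rate)
  full_scale <- 2^15
  .with_seed(seed, {
    white <- rnorm(n)
    bf <- signal::butter(4, band / (sample_rate / 2), type = "pass")
    shaped <- signal::filtfilt(bf, white)
    shaped <- shaped / sqrt(mean(shaped^2))      # unit RMS carrier
    if (protocol == "isometric") {
      s <- shaped * rms_level * full_scale
    } else {
      env <- .burst_envelope(n, sample_rate, burst_rate_hz, duty_cycle)
      amp <- noise_floor + (rms_level - noise_floor) * env
      s <- shaped * amp * full_scale
    }
    signal_record(round_to_integer(s, 16L), sample_rate, 16L)
  })
}

#' Generate a bank of surrogate S-EMG signals
#'
#' Stand-in for a multi-subject signal bank: `n_signals` independent
#' signals whose RMS levels are jittered by up to +/- 20% around
#' `rms_level`, with per-signal seeds derived deterministically from the
#' master seed.
#'
#' @param n_signals Number of signals (>= 1).
#' @param protocol,duration_s,sample_rate,rms_level,seed See
#'   [semg_synthetic()]; `seed` is the master seed.
#' @param rms_jitter Relative half-width of the per-signal RMS jitter
#'   (default 0.2).
#' @param ... Further arguments passed to [semg_synthetic()].
#' @return Named list of [signal_record()]s.
#' @export
semg_bank <- function(n_signals = 14L, protocol = "isometric",
                      duration_s = 10, sample_rate = 2000, rms_level = 0.125,
                      rms_jitter = 0.2, seed = 1L, ...) {
  if (n_signals < 1L) stop("n_signals must be >= 1", call. = FALSE)
  draws <- .with_seed(seed, list(
    sub_seeds = sample.int(.Machine$integer.max - 1L, n_signals),
    jitter = runif(n_signals, 1 - rms_jitter, 1 + rms_jitter)
  ))
  bank <- lapply(seq_len(n_signals), function(i) {
    semg_synthetic(protocol, duration_s = duration_s,
                   sample_rate = sample_rate,
                   rms_level = rms_level * draws$jitter[i],
                   seed = draws$sub_seeds[i], ...)
  })
  names(bank) <- sprintf("%s%02d", substr(protocol, 1, 3), seq_len(n_signals))
  bank
}

#' In-band power fraction
#'
#' Fraction of total signal power inside a frequency band, from the raw
#' periodogram.  Used to verify the generator's spectral shaping.
#'
#' @param record A [signal_record()] (or numeric vector with
#'   `sample_rate`).
#' @param band Band in Hz.
#' @param sample_rate Used when `record` is a bare vector.
#' @return Scalar in \[0, 1\].
#' @export
band_power_fraction <- function(record, band = c(20, 450),
                                sample_rate = 2000) {
  x <- if (inherits(record, "signal_record")) record$samples else record
  if (inherits(record, "signal_record")) sample_rate <- record$sample_rate
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  half <- seq_len(floor(n / 2) + 1L)
  freq <- (half - 1) * sample_rate / n
  pw <- p[half]
  sum(pw[freq >= band[1] & freq <= band[2]]) / sum(pw)
}
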