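---
title: "Sub-band wavelet compression of surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-band wavelet compression of surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgcodec)
```

## The problem

Surface electromyography (S-EMG) records muscle electrical activity from
skin electrodes, typically sampled at 2 kHz and digitized to 16 bits.
Long experimental protocols — minutes of recording per muscle, per
subject — produce signal banks whose storage and transmission costs
motivate lossy waveform compression that preserves diagnostic morphology.
`semgcodec` implements a transform codec specialized to the S-EMG
spectrum: almost all signal power lies between 20 and 450 Hz and decays
toward high frequency, so a decreasing bit-allocation profile across
frequency-ordered transform sub-bands spends words where the energy is.

## The codec

Each signal `x[n]` (ADC counts, word length `R = 16`) is segmented into
windows of `N = 2048` samples (the last window zero-padded, the true
length kept in the container header). Every window is mapped by a
periodized orthonormal Daubechies wavelet transform — `db4` (four
vanishing moments, eight taps) with 8 decomposition levels by default —
into a coefficient vector `X[k]` packed coarse-to-fine, so the index `k`
increases with frequency. Orthonormality matters twice: energy in the
coefficient domain equals energy in the sample domain (so distortion
introduced on coefficients translates directly to waveform distortion),
and the coefficient dynamic range stays comparable to the sample range.

The `N` coefficients are split into `M = 16` equal sub-bands of
`N/M = 128` coefficients. Sub-band `m` receives a digital word length
`B[m]` from one of four decreasing spectral-shape models, all evaluated
with `intsup` (smallest integer not below) and spanning a longest word
`Q` (sub-band 0) down to a shortest word `L` (sub-band `M−1`):

* **DLA**, decreasing linear: `B[m] = intsup(Q − m(Q−L)/(M−1))`;
* **DSR**, decreasing square root: `B[m] = intsup(ξ√(C−m))` with
  `C = Q²(1−M)/(L²−Q²)`, `ξ = Q/√C`;
* **DEA**, decreasing exponential: `B[m] = intsup(b^(p−m))` with
  `p = (1−M)/(log₁₀L/log₁₀Q − 1)`, `b = Q^(1/p)` (requires `Q, L > 1`);
* **RHT**, rotated hyperbolic tangent:
  `B[m] = intsup((Q/2)(1 − tanh(α(m − Mβ))))`, clamped to `[L, Q]`;
  `α` sets the transition steepness, `β` the midpoint as a fraction of
  `M` (defaults 0.4 and 0.5).

The DSR and DEA closures make `B[0] = Q` and `B[M−1] = L` exact in exact
arithmetic, but floating-point evaluation lands an epsilon above the
integer, which a naive ceiling would tip to `Q+1`. `intsup` therefore
snaps its argument to nine decimals before the ceiling; the snap is three
orders of magnitude above double-precision noise and three below any
honest curve value.

Quantization follows the scale factors `λ_m = 2^B[m]`:

```
X_q[k] = int( X[k] / 2^(R−1) · λ_m ),     m = floor(k / (N/M))
```

with `int` read as truncation toward zero (odd-symmetric, no DC bias) and
the result clamped to `[−λ_m, +λ_m]`. The decoder mirrors it as
`X̂[k] = X_q[k] · 2^(R−1) / λ_m`, so the unclamped per-coefficient error
is below one step `2^(R−1)/λ_m`. Zero-bit sub-bands (reachable by
explicitly choosing `L = 0` with DLA/DSR/RHT) discard their coefficients
outright.

The symbol stream is entropy coded by an adaptive order-0 arithmetic
coder (integer implementation, 40-bit state): one frequency model per
distinct word length `B`, each with alphabet `{−λ…+λ}`, Laplace-initial
counts, an increment of 32 per coded symbol and count halving at a 2¹⁷
total. Windows are coded independently (models reset per window) so each
window is individually decodable and damage cannot propagate. Every
payload carries a CRC-32 of its symbol stream; truncated or mismatched
payloads fail loudly. The packed `.semgz` container stores a fixed
little-endian header — including the explicit `B[m]` vector, so the
decoder never re-evaluates a shape curve — protected by its own CRC-32,
followed by length-prefixed window payloads. All reported compressed
sizes count the complete file, header included.

## Performance metrics

Fidelity and rate are measured as in the electrophysiological
compression literature:

* compression factor `CF = (O_S − C_S)/O_S × 100 %`, with `O_S = K·R`
  bits for the original and `C_S` the full container size;
* percent residual difference
  `PRD = √(Σ(x−x̂)² / Σx²) × 100 %`, over all `K` raw samples (no
  normalization or mean removal).

`rd_sweep()` traces rate-distortion curves by sweeping `Q` at fixed `L`
for each shape and signal; `rd_curves()` aggregates a signal bank into
mean PRD per 1-point CF bin, the form in which multi-subject codec
comparisons are usually plotted. Bank-level aggregation at fixed
parameters with CF binning (rather than interpolation to exact CF
targets) is this package's convention.

## The surrogate signal generator

Real multi-subject S-EMG banks are not redistributable, so the package
generates surrogates that reproduce the statistical structure the codec
exploits, at two protocols:

* **isometric** — constant-force contraction: white Gaussian noise
  shaped by an order-4 Butterworth band-pass over 20–450 Hz, applied
  forward-backward (`signal::filtfilt`) for zero phase (the magnitude
  response is consequently 8th-order), normalized to a constant RMS
  envelope;
* **dynamic** — cycling: the same carrier modulated by periodic
  activation bursts (default 1 Hz, 50 % duty cycle — a pedaling cadence
  per leg) with 50 ms raised-cosine ramps, plus a 1 %-of-full-scale
  noise floor in the silent intervals standing in for baseline
  instrumentation noise.

Samples are rounded half-away-from-zero and clamped to 16 bits.
`semg_bank()` emulates a 14-subject bank with per-signal RMS jitter
(±20 %) and seeds derived from one master seed; generation is
deterministic given the seed and leaves the caller's RNG state
untouched.

The default RMS level is 0.125 of full scale. This is a deliberate
dynamic-range choice: the codec's quantizer is built on the premise that
the orthonormal transform keeps coefficients within the 16-bit word, a
property the source recordings are expected to satisfy by acquisition
gain. Band-limited Gaussian noise concentrates energy, so its coefficient
amplitudes reach roughly 1.5× the time-domain scale; 0.125 leaves about
5.4σ of coefficient headroom, making clamping a rare event rather than
the dominant distortion. At `rms_level = 0.2` clamping becomes routine —
a regime the generator can still produce on request (clamp events are
counted and reported by `compress()`).

What the surrogate does *not* model: motor-unit firing statistics and
their recruitment-dependent spectral shifts, fatigue-related spectral
compression, movement artifact below 20 Hz, and power-line interference.
Its in-band spectrum is flat, where real S-EMG power peaks near
50–100 Hz and decays toward 450 Hz, and its out-of-band residue (~2 % of
power above 450 Hz, set by the Butterworth roll-off) is larger than a
well-conditioned acquisition chain would leave. Consequently absolute PRD
values on surrogates run higher than published values on real banks at
matched CF, and passing tests demonstrate the codec's structural
properties — losslessness of the entropy layer, monotone rate-distortion
behavior, relative shape ordering — not clinical-grade absolute
distortion figures.

## Numerical and design choices

* **Boundary handling** is periodized (circular) convolution, making the
  analysis operator an exact `N×N` orthogonal matrix; the test suite
  materializes that matrix at small `N` and checks `WᵀW = I` directly.
* **"Daubechies-4"** is read as four vanishing moments (eight taps); the
  filter is selectable (`db1`–`db6`, `db8`) for sensitivity checks.
* **Integer rounding** of reconstructed samples is half-away-from-zero
  with clamping to the signed `R`-bit range.
* **Degenerate inputs**: `L = Q` collapses DSR/DEA to a flat allocation;
  empty signals compress to a header-only stream; the final window's
  padding is removed by length, not value, so zero-valued tails of real
  signals are preserved.
* **Problem sizes** used by the automated checks: windows of `N = 2048`
  at 2 kHz, 10-second signals, and a 14-signal isometric bank swept over
  `Q = 15…2` at `L = 2` for all four shapes — large enough to show the
  monotone CF/PRD trade-off and the shape ordering (the exponential
  shape trailing the others at matched CF, most visibly at moderate CF),
  while keeping the default evaluation fast on one CPU.

## Known limitations

Single-channel only; no EDF/BDF clinical container support; no
wavelet-packet or learned bit allocation (the shape models are fixed
curves, not per-window adapted); the arithmetic coder is order-0 — no
inter-coefficient context modeling; and CF on very short signals is
dominated by the fixed ~60-byte header.
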