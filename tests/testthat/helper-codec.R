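# shared fixtures: windows and short signals built in code

# white Gaussian window at a given RMS (in ADC counts)
random_window <- function(n = 2048L, rms = 4096) {
  rnorm(n, sd = rms)
}

# one window cut from a synthetic isometric recording
emg_window <- function(seed = 1L, n = 2048L) {
  x <- semg_synthetic("isometric", duration_s = n / 2000, seed = seed)
  x$samples[seq_len(n)]
}

short_signal <- function(seed = 1L, duration_s = 2) {
  semg_synthetic("isometric", duration_s = duration_s, seed = seed)
}

# independent oracle: materialize the analysis operator column by column
# and check it against the defining property of an orthogonal matrix
dwt_matrix <- function(n, wavelet, levels) {
  vapply(seq_len(n), function(i) {
    e <- numeric(n)
    e[i] <- 1
    forward_dwt(e, wavelet, levels)$coefficients
  }, numeric(n))
}
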