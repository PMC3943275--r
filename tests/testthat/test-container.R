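test_that("compression is deterministic and self-inverting on length", {
  x <- short_signal(51)
  cfg <- codec_config(shape = "rht", Q = 10, L = 2)
  a <- compress(x, cfg)
  b <- compress(x, cfg)
  expect_identical(a$bytes, b$bytes)
  y <- decompress(a)
  expect_equal(y$length, x$length)
  expect_equal(y$sample_rate, x$sample_rate)
  expect_equal(a$total_size_bytes, length(a$bytes))
})

test_that("a K=4096 signal yields exactly two window records", {
  x <- signal_record(round_to_integer(rnorm(4096, sd = 3000)))
  cs <- compress(x, codec_config())
  expect_equal(cs$header$n_windows, 2L)
  expect_length(cs$payloads, 2L)
})

test_that("an empty signal compresses to a header-only stream", {
  x <- signal_record(numeric(0))
  cs <- compress(x, codec_config())
  expect_equal(cs$header$n_windows, 0L)
  y <- decompress(cs)
  expect_equal(y$length, 0L)
})

test_that("decoding is driven by the stream alone", {
  x <- short_signal(52)
  cs <- compress(x, codec_config(shape = "dsr", Q = 9, L = 1))
  # raw bytes with no encoder-side state
  y <- decompress(cs$bytes)
  expect_identical(y$samples, decompress(cs)$samples)
  # every shape id decodes self-consistently from its own header
  for (shape in c("dla", "dsr", "dea", "rht")) {
    cz <- compress(x, codec_config(shape = shape, Q = 8, L = 2))
    expect_equal(decompress(cz$bytes)$length, x$length)
  }
})

test_that("sample rate is metadata only: it never changes decoded samples", {
  samples <- short_signal(53)$samples
  a <- compress(signal_record(samples, 2000), codec_config())
  b <- compress(signal_record(samples, 4000), codec_config())
  ya <- decompress(a)
  yb <- decompress(b)
  expect_identical(ya$samples, yb$samples)
  expect_equal(yb$sample_rate, 4000)
})

test_that("file round trip preserves the stream bit for bit", {
  x <- short_signal(54)
  cs <- compress(x, codec_config(shape = "dla", Q = 11, L = 3))
  f <- withr::local_tempfile(fileext = ".semgz")
  write_semgz(cs, f)
  expect_equal(file.size(f), cs$total_size_bytes)  # C_S is the on-disk size
  back <- read_semgz(f)
  expect_identical(back$bytes, cs$bytes)
  expect_identical(decompress(back)$samples, decompress(cs)$samples)
})

test_that("corrupt streams are rejected loudly", {
  x <- short_signal(55)
  cs <- compress(x, codec_config())
  bad <- cs$bytes
  bad[1] <- as.raw(0x58)
  expect_error(decompress(bad), "magic")
  tampered <- cs$bytes
  tampered[8] <- xor(tampered[8], as.raw(0xFF))  # flip a header byte
  expect_error(decompress(tampered), "checksum")
  expect_error(decompress(cs$bytes[1:40]), "format error|truncated|checksum")
  truncated <- cs$bytes[seq_len(length(cs$bytes) - 3L)]
  expect_error(decompress(truncated), "truncated|checksum")
})

test_that("rate-distortion moves the right way as Q shrinks", {
  x <- short_signal(56, duration_s = 3)
  pts <- do.call(rbind, lapply(12:4, function(Q) {
    rd_point(x, codec_config(shape = "dsr", Q = Q, L = 2))
  }))
  expect_true(all(diff(pts$cf) > -0.2))
  expect_true(all(diff(pts$prd) > -0.2))
})

test_that("invalid configurations are rejected before any stage runs", {
  expect_error(codec_config(N = 2000), "power of two")
  expect_error(codec_config(N = 2048, M = 15), "divide")
  expect_error(codec_config(N = 256, levels = 9), "levels")
  expect_error(codec_config(shape = "dea", Q = 8, L = 1), "L must be")
  expect_error(codec_config(Q = 20), "Q must be")
})
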