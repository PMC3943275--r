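test_that("raw int16 is read little-endian two's-complement", {
  f <- withr::local_tempfile()
  writeBin(as.raw(c(0x00, 0x00, 0xFF, 0x7F)), f)
  rec <- read_signal(f, "raw_int16")
  expect_equal(rec$samples, c(0, 32767))
  expect_equal(rec$sample_rate, 2000)
  expect_equal(rec$bit_depth, 16L)
})

test_that("text format parses one literal value per line", {
  f <- withr::local_tempfile()
  writeLines(c("1", "-2", "3"), f)
  expect_equal(read_signal(f, "text")$samples, c(1, -2, 3))
  writeLines(c("1", "40000"), f)
  expect_error(read_signal(f, "text"), "range")
})

test_that("write then read round trips in every format", {
  rec <- signal_record(c(0, 1, -1, 32767, -32768), 2000, 16L)
  for (fmt in c("wav16", "raw_int16", "text")) {
    f <- withr::local_tempfile()
    write_signal(rec, f, fmt)
    back <- read_signal(f, fmt)
    expect_equal(back$samples, rec$samples, label = fmt)
  }
  # WAV carries its own rate
  f <- withr::local_tempfile()
  write_signal(signal_record(1:4, 4000, 16L), f, "wav16")
  expect_equal(read_signal(f, "wav16")$sample_rate, 4000)
})

test_that("empty signals round trip as length zero", {
  rec <- signal_record(numeric(0))
  for (fmt in c("wav16", "raw_int16", "text")) {
    f <- withr::local_tempfile()
    write_signal(rec, f, fmt)
    expect_equal(read_signal(f, fmt)$length, 0L, label = fmt)
  }
})

test_that("out-of-range and malformed inputs are rejected", {
  expect_error(signal_record(32768, 2000, 16L), "range")
  expect_error(signal_record(0, -1), "sample_rate")
  expect_error(read_signal("no/such/file.wav", "wav16"), "not found")
  # stereo WAV is refused
  f <- withr::local_tempfile()
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 2L), con, size = 2L, endian = "little")  # PCM, stereo
  writeBin(2000L, con, size = 4L, endian = "little")
  writeBin(8000L, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(0L, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_signal(f, "wav16"), "multi-channel")
})

test_that("segmentation covers the signal with recorded zero padding", {
  x <- signal_record(seq_len(4096) %% 100)
  ws <- segment(x, 2048L)
  expect_length(ws$windows, 2L)
  expect_equal(ws$pad_count, 0L)

  y <- signal_record(seq_len(3072) %% 100)
  ws2 <- segment(y, 2048L)
  expect_length(ws2$windows, 2L)
  expect_equal(ws2$pad_count, 1024L)   # 2 * 2048 - 3072
  expect_equal(ws2$windows[[2]][1025:2048], numeric(1024))
  expect_equal(reassemble(ws2)$length, 3072L)

  z <- segment(signal_record(7), 2048L)
  expect_equal(z$windows[[1]], c(7, numeric(2047)))
  expect_equal(z$pad_count, 2047L)
})

test_that("reassemble is the exact inverse of segment", {
  set.seed(41)
  for (k in sample(1:5000, 8)) {
    x <- signal_record(sample(-32768:32767, k, replace = TRUE))
    for (n in c(256L, 1024L, 2048L)) {
      ws <- segment(x, n)
      expect_equal(length(ws$windows) * n - ws$pad_count, k)
      expect_identical(reassemble(ws)$samples, x$samples)
    }
  }
})

test_that("segmentation rejects invalid window lengths", {
  x <- signal_record(1:10)
  expect_error(segment(x, 1000L), "power of two")
  expect_error(segment(signal_record(numeric(0)), 2048L), "empty")
  ws <- segment(x, 8L)
  ws$windows[[2]] <- 1:3
  expect_error(reassemble(ws), "inconsistent")
})
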