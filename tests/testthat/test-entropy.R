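test_that("encode/decode is bit-exact across shapes and parameter draws", {
  set.seed(31)
  for (shape in c("dla", "dsr", "dea", "rht")) {
    for (i in 1:6) {
      Q <- sample(4:15, 1)
      L <- sample(2:Q, 1)
      plan <- allocate_bits(shape, Q, L, 16L)
      lam <- rep(plan$scale_factors, each = 128)
      sym <- as.integer(round(pmin(pmax(rnorm(2048, sd = lam / 3),
                                        -lam), lam)))
      pay <- entropy_encode(sym, plan)
      expect_identical(entropy_decode(pay, plan, 2048L), sym)
    }
  }
})

test_that("an adaptive model collapses a constant stream to a few bytes", {
  plan <- allocate_dla(3, 3, 4)  # alphabet 17 per band
  sym <- rep(5L, 4096)
  pay <- entropy_encode(sym, plan)
  expect_lt(length(pay), 64L)
  expect_identical(entropy_decode(pay, plan, 4096L), sym)
})

test_that("incompressible input is not expanded beyond the source-coding bound slack", {
  set.seed(32)
  plan <- allocate_dla(7, 7, 4)   # alphabet A = 257 everywhere
  sym <- as.integer(sample(-128:128, 4096, replace = TRUE))
  pay <- entropy_encode(sym, plan)
  # uniform source: >= n log2(A) bits minus modest adaptive-model slack
  expect_gt(length(pay), (4096 * log2(257)) / 8 - 64)
  expect_identical(entropy_decode(pay, plan, 4096L), sym)
})

test_that("entropy stage does not expand typical quantized EMG windows", {
  for (shape in c("dla", "dsr", "dea", "rht")) {
    plan <- allocate_bits(shape, 12L, 2L, 16L)
    w <- emg_window(4)
    q <- quantize(forward_dwt(w, "db4", 8L), plan, 16L)
    raw_bytes <- ceiling(sum((plan$bits + 1) * 2048 / 16) / 8)
    expect_lte(length(entropy_encode(q)), raw_bytes + 16)
  }
})

test_that("empty streams round trip", {
  plan <- allocate_dla(7, 2, 16)
  pay <- entropy_encode(integer(0), plan)
  expect_identical(entropy_decode(pay, plan, 0L), integer(0))
})

test_that("corrupt or mismatched payloads raise errors, never silent garbage", {
  set.seed(33)
  plan <- allocate_dla(7, 2, 16)
  lam <- rep(plan$scale_factors, each = 128)
  sym <- as.integer(pmin(pmax(round(rnorm(2048, sd = lam / 4)), -lam), lam))
  pay <- entropy_encode(sym, plan)
  expect_error(entropy_decode(pay[-length(pay)], plan, 2048L), "checksum|corrupt")
  other <- allocate_dla(9, 3, 16)
  expect_error(entropy_decode(pay, other, 2048L), "checksum|corrupt")
  expect_error(entropy_decode(raw(2), plan, 2048L), "too short")
})

test_that("symbols outside their sub-band alphabet are rejected at encode", {
  plan <- allocate_dla(3, 3, 4)  # lambda = 8
  expect_error(entropy_encode(c(rep(0L, 7), 9L), plan), "alphabet")
})
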