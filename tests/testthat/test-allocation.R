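test_that("linear shape hits its endpoints and known interior values", {
  p <- allocate_dla(7, 1, 16)
  expect_equal(p$bits[1], 7L)
  expect_equal(p$bits[16], 1L)
  expect_equal(p$bits[9], 4L)  # ceil(7 - 0.4 * 8) = ceil(3.8)
  expect_true(all(allocate_dla(5, 5, 16)$bits == 5L))
})

test_that("square-root shape closure reproduces the derived constants", {
  # C = Q^2 (1 - M) / (L^2 - Q^2) = 49 * (-15) / (1 - 49)
  Q <- 7; L <- 1; M <- 16
  C <- Q^2 * (1 - M) / (L^2 - Q^2)
  expect_equal(C, 15.3125)
  p <- allocate_dsr(Q, L, M)
  expect_equal(p$bits[1], 7L)
  expect_equal(p$bits[16], 1L)
  expect_true(all(diff(p$bits) <= 0L))
  # frozen from a 50-digit evaluation of ceil(xi * sqrt(C - m)) with the
  # exact-integer endpoints snapped
  expect_identical(p$bits,
                   c(7L, 7L, 7L, 7L, 7L, 6L, 6L, 6L, 5L, 5L, 5L, 4L, 4L,
                     3L, 3L, 1L))
})

test_that("exponential shape closure reproduces the derived constants", {
  # p = (1 - M)/((log10 L / log10 Q) - 1); L=2, Q=8 gives 1/3 exactly
  p_exp <- (1 - 16) / (log10(2) / log10(8) - 1)
  expect_equal(p_exp, 22.5)
  plan <- allocate_dea(8, 2, 16)
  expect_equal(plan$bits[1], 8L)
  expect_equal(plan$bits[16], 2L)
  # frozen from a 50-digit evaluation of ceil(b^(p - m)), b = 8^(1/22.5)
  expect_identical(plan$bits,
                   c(8L, 8L, 7L, 7L, 6L, 6L, 5L, 5L, 4L, 4L, 4L, 3L, 3L,
                     3L, 3L, 2L))
  expect_true(all(plan$bits >= 2L & plan$bits <= 8L))
})

test_that("rotated tanh shape has the expected flat, midpoint and saturated forms", {
  # alpha = 0: tanh term vanishes, every band gets ceil(Q/2)
  expect_true(all(allocate_rht(9, 0, 16, alpha = 0)$bits == ceiling(9 / 2)))
  # integer midpoint m = M * beta sits at ceil(Q/2)
  p <- allocate_rht(10, 1, 16, alpha = 0.4, beta = 0.5)
  expect_equal(p$bits[8 + 1], ceiling(10 / 2))
  # large alpha saturates to Q below the midpoint and to the clamp above it
  s <- allocate_rht(10, 1, 16, alpha = 50, beta = 0.5)
  expect_true(all(s$bits[1:8] == 10L))
  expect_true(all(s$bits[10:16] == 1L))
})

test_that("endpoint identities hold across the full parameter grid", {
  for (M in c(4L, 8L, 16L, 32L)) {
    for (Q in 4:15) {
      for (L in 1:(Q - 1)) {
        dla <- allocate_dla(Q, L, M)
        dsr <- allocate_dsr(Q, L, M)
        expect_identical(c(dla$bits[1], dla$bits[M]), c(Q, L))
        expect_identical(c(dsr$bits[1], dsr$bits[M]), c(Q, L))
        expect_true(all(diff(dla$bits) <= 0L))
        expect_true(all(diff(dsr$bits) <= 0L))
        if (L >= 2L) {
          dea <- allocate_dea(Q, L, M)
          expect_identical(c(dea$bits[1], dea$bits[M]), c(Q, L))
          expect_true(all(diff(dea$bits) <= 0L))
        }
        rht <- allocate_rht(Q, L, M)
        expect_true(all(diff(rht$bits) <= 0L))
        expect_true(all(rht$bits >= L & rht$bits <= Q))
      }
    }
  }
})

test_that("total bit budget grows strictly with Q at fixed L and M", {
  for (shape in c("dla", "dsr", "dea", "rht")) {
    budgets <- vapply(4:15, function(Q) {
      sum(allocate_bits(shape, Q, 2L, 16L)$bits) * 2048 / 16
    }, numeric(1))
    expect_true(all(diff(budgets) > 0), label = paste(shape, "budget"))
  }
})

test_that("scale factors are exact powers of two", {
  p <- allocate_dla(15, 0, 16)
  expect_identical(scale_factors(p), 2^p$bits)
  expect_equal(scale_factors(allocate_dla(7, 7, 4))[1], 128)
  expect_equal(2^allocate_dla(15, 0, 16)$bits[16], 1)
  expect_equal(2^15, 32768)
})

test_that("coefficient-to-sub-band mapping follows floor(k / (N/M))", {
  expect_equal(subband_of(0, 2048, 16), 0L)
  expect_equal(subband_of(c(127, 128), 2048, 16), c(0L, 1L))
  expect_equal(subband_of(2047, 2048, 16), 15L)
  expect_error(subband_of(0, 2048, 15), "divide")
  expect_error(subband_of(2048, 2048, 16), "out of range")
})

test_that("invalid shape parameters are rejected", {
  expect_error(allocate_dla(3, 5, 16), "exceed")
  expect_error(allocate_dla(5, 2, 1), "M must be")
  expect_error(allocate_dea(8, 1, 16), "L must be")
  expect_error(allocate_rht(8, 2, 16, alpha = -1), "alpha")
  expect_error(allocate_rht(8, 2, 16, beta = 2), "beta")
  # flat fallback at L == Q
  expect_true(all(allocate_dsr(6, 6, 16)$bits == 6L))
  expect_true(all(allocate_dea(6, 6, 16)$bits == 6L))
})
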