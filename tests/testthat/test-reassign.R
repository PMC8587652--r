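test_that("modified kernels have the stated structure and symmetry", {
  g <- make_window("hamming", 6); h <- make_window("hamming", 4)
  mk <- modified_kernels(g, h)
  # time-weighted kernel vanishes on the m = 0 row
  expect_equal(mk$T[5, ], rep(0, ncol(mk$T)))
  expect_equal(mk$T, outer((-4:4) * h$coef, g$coef))
  # discrete symmetries that enable the one-sided lag evaluation:
  # T is odd in m and even in l, D is even in m and odd in l
  expect_equal(mk$T, -mk$T[rev(seq_len(nrow(mk$T))), ])
  expect_equal(mk$T, mk$T[, rev(seq_len(ncol(mk$T)))])
  expect_equal(mk$D, mk$D[rev(seq_len(nrow(mk$D))), ])
  expect_equal(mk$D, -mk$D[, rev(seq_len(ncol(mk$D)))])
  # derivative ingredient is odd in the lag
  expect_equal(mk$g_D, -rev(mk$g_D))
  expect_error(modified_kernels(make_window("exponential", 4), h), "Hermitian")
})

test_that("an impulse reassigns exactly onto its time sample", {
  N <- 64; n0 <- 30
  imp <- eeg_signal(as.complex(replace(numeric(N), n0 + 1, 1)), 1, TRUE)
  g <- make_window("hamming", 8); h <- make_window("hanning", 6)
  C <- smoothed_pwvd(imp, g, h, 32)
  f <- reassignment_operators(C, smoothed_pwvd(imp, g, h, 32, "T"),
                              smoothed_pwvd(imp, g, h, 32, "D"))
  expect_gt(sum(f$valid), 0)
  expect_lt(max(abs(f$n_hat - n0)[f$valid]), 1)
})

test_that("a tone reassigns onto its frequency bin (calibration oracle)", {
  Nf <- 64; v0 <- 16 / (2 * Nf); N <- 256
  tone <- eeg_signal(exp(2i * pi * v0 * (0:(N - 1))), 1, TRUE)
  g <- make_window("hamming", 16); h <- make_window("hanning", 8)
  C <- smoothed_pwvd(tone, g, h, Nf)
  f <- reassignment_operators(C, smoothed_pwvd(tone, g, h, Nf, "T"),
                              smoothed_pwvd(tone, g, h, Nf, "D"))
  interior <- 27:(N - 26)  # rows with full autocorrelation support
  energetic <- abs(C$values[interior, ]) >= 1e-2 * max(abs(C$values))
  err_bins <- abs(f$v_hat[interior, ] - v0) * 2 * Nf
  expect_lt(max(err_bins[energetic & f$valid[interior, ]]), 0.5)
})

test_that("zero modified streams give the identity field", {
  x <- rand_analytic(48, 3)
  g <- make_window("hamming", 6); h <- make_window("hanning", 4)
  C <- smoothed_pwvd(x, g, h, 32)
  zero <- C; zero$values <- C$values * 0
  f <- reassignment_operators(C, zero, zero)
  expect_equal(f$n_hat, matrix(C$time_axis, 48, 32))
  expect_equal(f$v_hat, matrix(C$freq_axis, 48, 32, byrow = TRUE))
})

test_that("apply_reassign conserves the signed total and honours identity", {
  x <- rand_analytic(64, 8)
  g <- make_window("hamming", 8); h <- make_window("hanning", 6)
  C <- smoothed_pwvd(x, g, h, 32)
  zero <- C; zero$values <- C$values * 0
  ident <- reassignment_operators(C, zero, zero)
  expect_equal(apply_reassign(C, ident)$values, C$values)

  f <- reassignment_operators(C, smoothed_pwvd(x, g, h, 32, "T"),
                              smoothed_pwvd(x, g, h, 32, "D"))
  out <- apply_reassign(C, f)
  expect_lt(abs(sum(out$values) - sum(C$values)) / abs(sum(C$values)), 1e-9)
  # discard policy drops off-grid mass instead
  out2 <- apply_reassign(C, f, clip = FALSE)
  expect_lte(sum(abs(out2$values)), sum(abs(out$values)) + 1e-9)
})

test_that("reassignment concentrates a pure tone into one frequency row", {
  Nf <- 64; k0 <- 16; v0 <- k0 / (2 * Nf)
  tone <- eeg_signal(exp(2i * pi * v0 * (0:511)), 1, TRUE)
  out <- reassigned_spwvd(tone, make_window("hamming", 16),
                          make_window("hanning", 8), Nf)
  share <- sum(out$values[, k0 + 1]) / sum(out$values)
  expect_gte(share, 0.95)
})

test_that("fast Hermitian evaluation matches the direct double sum", {
  x <- rand_analytic(64, 23)
  g <- make_window("hamming", 8); h <- make_window("hanning", 6)
  fh <- fast_hermitian_eval(x, g, h, 64)
  expect_lt(rel_err(fh$T$values, smoothed_pwvd(x, g, h, 64, "T")$values),
            1e-10)
  expect_lt(rel_err(fh$D$values, smoothed_pwvd(x, g, h, 64, "D")$values),
            1e-10)
  oc <- attr(fh, "op_counts")
  # one-sided lag sum halves the lag-loop multiplication count
  expect_lt(oc$onesided_mults, 0.62 * oc$full_mults)
  expect_error(fast_hermitian_eval(x, make_window("exponential", 8), h, 64),
               "Hermitian")
})

test_that("single-sample signal: T stream closed form, D stream zero", {
  N <- 32; n0 <- 15
  x <- eeg_signal(as.complex(replace(numeric(N), n0 + 1, 2)), 1, TRUE)
  g <- make_window("hamming", 4); h <- make_window("hanning", 3)
  fh <- fast_hermitian_eval(x, g, h, 16)
  M <- h$half_length
  expected_T <- matrix(0, N, 16)
  for (n in 0:(N - 1)) {
    m <- n0 - n
    if (abs(m) <= M) expected_T[n + 1, ] <- m * h$coef[m + M + 1] * g$coef[5] * 4
  }
  expect_equal(fh$T$values, expected_T, tolerance = 1e-12)
  expect_lt(max(abs(fh$D$values)), 1e-12)
})

test_that("reallocation-function evaluation stays within 3N adds / 2N mults", {
  set.seed(1)
  for (Nf in c(1L, 16L, 64L, 256L)) {
    oc <- count_reassign_ops(Nf)
    expect_lte(oc[["additions"]], 3 * Nf)
    expect_lte(oc[["multiplications"]], 2 * Nf)
  }
})

test_that("reassigned chirp ridge tracks the linear law within one bin", {
  ch <- analytic(make_chirp(512, 0.1, 0.3))
  out <- reassigned_spwvd(ch, make_window("hamming", 32),
                          make_window("hamming", 32), 256)
  ridge <- out$freq_axis[apply(out$values, 1, which.max)]
  law <- chirp_frequency_law(512, 0.1, 0.3)
  central <- 52:461  # central 80 percent
  expect_lte(stats::median(abs(ridge - law)[central]), 1 / 512)
})

test_that("direct and recursive reassignment agree; zero in, zero out", {
  x <- rand_analytic(128, 77)
  g <- make_window("hamming", 12); h <- make_window("hanning", 6)
  a <- reassigned_spwvd(x, g, h, 64, mode = "direct")
  b <- reassigned_spwvd(x, g, h, 64, mode = "recursive")
  expect_lt(rel_err(b$values, a$values), 1e-8)

  z <- eeg_signal(as.complex(numeric(64)), 1, TRUE)
  expect_equal(max(abs(reassigned_spwvd(z, g, h, 64)$values)), 0)
})
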