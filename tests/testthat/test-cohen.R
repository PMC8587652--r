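test_that("instantaneous autocorrelation identities", {
  x <- rand_analytic(16, 2)
  # l = 0 gives |x[n]|^2
  expect_equal(Re(inst_autocorr(x, 5, 0)), Mod(x$samples[6])^2)
  # conjugate symmetry in the lag
  for (l in 1:5) {
    expect_equal(inst_autocorr(x, 8, -l), Conj(inst_autocorr(x, 8, l)))
  }
  # printed toy sequence: direct elementwise product
  toy <- eeg_signal(complex(real = 1:8, imaginary = 8:1), 1,
                    is_analytic = FALSE)
  expect_equal(inst_autocorr(toy, 4, 2),
               toy$samples[7] * Conj(toy$samples[3]))
  expect_equal(inst_autocorr(toy, 6, 3), 0 + 0i)  # n + l beyond support
})

test_that("pseudo-WVD of a tone peaks at the tone bin with value sum(g)", {
  Nf <- 64
  v0 <- 10 / (2 * Nf)
  x <- eeg_signal(exp(2i * pi * v0 * (0:99)), 1, is_analytic = TRUE)
  g <- make_window("hamming", 8)
  W <- pseudo_wvd(x, g, Nf)
  interior <- 10:90
  for (n in interior) {
    expect_equal(which.max(W$values[n + 1, ]), 11L)
  }
  # at the tone bin every rotation cancels: value = sum of g
  expect_equal(W$values[interior + 1, 11], rep(sum(g$coef), length(interior)),
               tolerance = 1e-9)
})

test_that("smoothed-pseudo WVD equals the brute-force triple loop", {
  x <- rand_analytic(20, 7)
  g <- make_window("hamming", 3)
  h <- make_window("hanning", 2)
  Nf <- 16
  for (mod in c("none", "T", "D")) {
    direct <- smoothed_pwvd(x, g, h, Nf, modified = mod)$values
    bf <- brute_spwvd(x, g, h, Nf, mod)
    if (mod != "D") bf <- Re(bf)
    expect_lt(max(abs(direct - bf)), 1e-12, label = paste("kernel", mod))
  }
})

test_that("time-impulse h reduces the smoothed to the pseudo WVD", {
  x <- rand_analytic(32, 9)
  g <- make_window("hamming", 6)
  a <- smoothed_pwvd(x, g, make_window("rectangular", 0), 32)$values
  b <- pseudo_wvd(x, g, 32)$values
  expect_identical(a, b)
})

test_that("unmodified distributions of analytic signals are real", {
  x <- rand_analytic(48, 12)
  g <- make_window("hamming", 6); h <- make_window("hanning", 4)
  # recompute keeping the complex transform: imaginary residue must vanish
  L <- g$half_length
  R <- kcdetect:::lag_autocorr_matrix(x$samples, L)
  A <- matrix(0 + 0i, nrow(R), ncol(R))
  for (m in -4:4) A <- A + h$coef[m + 5] * kcdetect:::shift_cols(R, m)
  W <- t(kcdetect:::lag_dft(A * g$coef, L, 48))
  expect_lt(max(abs(Im(W))) / max(abs(W)), 1e-10)
})

test_that("distributions are covariant under time shifts", {
  set.seed(21)
  base <- stats::rnorm(40)
  d <- 7
  x1 <- eeg_signal(c(base, numeric(d)), 1)
  x2 <- eeg_signal(c(numeric(d), base), 1)  # delayed copy, same length
  g <- make_window("hamming", 4); h <- make_window("hanning", 3)
  # real input: the aliasing warning is irrelevant to the exact covariance
  W1 <- suppressWarnings(smoothed_pwvd(x1, g, h, 16)$values)
  W2 <- suppressWarnings(smoothed_pwvd(x2, g, h, 16)$values)
  # rows far enough from the edges translate exactly
  inner <- 12:32
  expect_equal(W2[inner + d, ], W1[inner, ], tolerance = 1e-12)
})

test_that("full-lag WVD time marginal is proportional to |x[n]|^2", {
  x <- rand_analytic(24, 5)
  N <- length(x)
  g <- make_window("rectangular", N - 1)
  Nf <- 2 * N - 1
  W <- pseudo_wvd(x, g, Nf)
  marg <- rowSums(W$values)
  expect_equal(marg, Nf * Mod(x$samples)^2, tolerance = 1e-9)
})

test_that("Cohen kernels: identity, spectrogram oracle, validation", {
  x <- rand_analytic(24, 31)
  g <- make_window("hamming", 4)
  wv <- cohen_distribution(x, kernel_spec("wigner_ville", g = g), 16)
  expect_equal(wv$values, pseudo_wvd(x, g, 16)$values)

  h <- make_window("hanning", 4)
  sp <- cohen_distribution(x, kernel_spec("spectrogram", h = h), 16)
  expect_lt(max(abs(sp$values - brute_stft_spectrogram(x, h, 16))), 1e-10)
  expect_true(all(sp$values >= 0))

  expect_error(kernel_spec("choi_williams", g = g, sigma = -1), "sigma")
  expect_error(kernel_spec("spectrogram"), "window h")
  expect_error(kernel_spec("nonsense"))
  expect_error(kernel_spec("born_jordan", g = g, modified = "T"),
               "pseudo-Wigner-Ville")
})

test_that("Born-Jordan trades resolution for suppressed secondary lobes", {
  ch <- analytic(make_chirp(256, 0.1, 0.3))
  g <- make_window("hamming", 24)
  Nf <- 128
  pw <- pseudo_wvd(ch, g, Nf)$values
  bj <- cohen_distribution(ch, kernel_spec("born_jordan", g = g), Nf)$values
  law <- chirp_frequency_law(256, 0.1, 0.3)
  # worst off-ridge magnitude relative to the ridge peak, excluding the
  # (possibly broadened) main lobe of +- 12 bins
  sidelobe_ratio <- function(W) {
    worst <- 0; ridge <- 0
    for (n in seq.int(40, 216)) {
      k <- round(law[n] * 2 * Nf)
      cols <- setdiff(seq_len(Nf), (k - 12):(k + 12))
      worst <- max(worst, max(abs(W[n, cols])))
      ridge <- max(ridge, abs(W[n, k + 1]))
    }
    worst / ridge
  }
  # secondary lobes almost unnoticed: distinctly below the pseudo-WVD ones
  expect_lt(sidelobe_ratio(bj), sidelobe_ratio(pw))
  # ... at the price of a thicker "knife blade" (lower ridge concentration)
  expect_lt(max(abs(bj)), max(abs(pw)))
})

test_that("Choi-Williams and ZAM produce real grids that localize the chirp", {
  ch <- analytic(make_chirp(128, 0.1, 0.3))
  g <- make_window("hamming", 12)
  for (id in c("choi_williams", "zam")) {
    W <- cohen_distribution(ch, kernel_spec(id, g = g, sigma = 1), 64)
    expect_true(is.numeric(W$values))
    law <- chirp_frequency_law(128, 0.1, 0.3)
    ridge <- apply(W$values[30:98, ], 1, which.max) - 1
    expect_lt(stats::median(abs(ridge / 128 - law[30:98])), 2 / 128)
  }
})

test_that("spectrogram Parseval relation holds at hop 1", {
  # the stated factor is exact when the signal is supported at least a
  # window half-length away from both edges
  h <- make_window("hanning", 6)
  core <- rand_analytic(28, 17)$samples
  x <- eeg_signal(c(rep(0 + 0i, 6), core, rep(0 + 0i, 6)), 1, TRUE)
  Nf <- 32
  S <- stft_spectrogram(x, h, Nf, hop = 1, onesided = FALSE)
  lhs <- sum(S$values)
  rhs <- 2 * Nf * sum(h$coef^2) * sum(Mod(x$samples)^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("rectangular-64 spectrogram configuration runs on the test chirp", {
  ch <- make_chirp(512, 0.1, 0.3)
  S <- stft_spectrogram(ch, make_window("rectangular", 32), 256, hop = 4)
  expect_true(all(S$values >= 0))
  law <- chirp_frequency_law(512, 0.1, 0.3)
  ridge <- S$freq_axis[apply(S$values, 1, which.max)]
  centre <- seq.int(20, nrow(S$values) - 20)
  expect_lt(stats::median(abs(ridge[centre] - law[S$time_axis[centre] + 1])),
            4 / 512)
})
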