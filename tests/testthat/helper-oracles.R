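# Shared fixtures and independent oracles, built in code at test time.

rand_analytic <- function(n, seed) {
  set.seed(seed)
  analytic(eeg_signal(stats::rnorm(n), fs = 1))
}

# Brute-force triple-loop evaluation of the (modified) smoothed-pseudo WVD:
# independent of the package's vectorized/convolutional path (only the
# window coefficient definitions are shared).
brute_spwvd <- function(x, g, h, Nf, modified = "none") {
  xs <- as.complex(x$samples)
  N <- length(xs)
  M <- h$half_length
  L <- g$half_length + (modified == "D")
  gd <- window_derivative(g)
  at <- function(i) ifelse(i >= 0 & i < N, xs[pmax(i, 0) + 1], 0 + 0i)
  W <- matrix(0 + 0i, N, Nf)
  for (n in 0:(N - 1)) for (k in 0:(Nf - 1)) {
    acc <- 0 + 0i
    for (l in -L:L) for (m in -M:M) {
      gl <- if (modified == "D") gd[l + L + 1] else g$coef[l + L + 1]
      hm <- if (modified == "T") m * h$coef[m + M + 1] else h$coef[m + M + 1]
      acc <- acc + gl * hm * at(n + m + l) * Conj(at(n + m - l)) *
        exp(-2i * pi * k * l / Nf)
    }
    W[n + 1, k + 1] <- acc
  }
  W
}

# Direct short-time transform magnitude: explicit per-frame DFT sums.
brute_stft_spectrogram <- function(x, h, Nf) {
  xs <- as.complex(x$samples)
  N <- length(xs)
  M <- h$half_length
  S <- matrix(0, N, Nf)
  for (n in 0:(N - 1)) for (k in 0:(Nf - 1)) {
    acc <- 0 + 0i
    for (m in -M:M) {
      i <- n + m
      if (i >= 0 && i < N) {
        acc <- acc + h$coef[m + M + 1] * xs[i + 1] *
          exp(-2i * pi * k * m / (2 * Nf))
      }
    }
    S[n + 1, k + 1] <- Mod(acc)^2
  }
  S
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

# a small shared feature dataset for classifier tests: two well-separated
# Gaussian blobs in 2-D
toy_blobs <- function(n_per_class = 30, seed = 11) {
  set.seed(seed)
  X <- rbind(cbind(stats::rnorm(n_per_class, -2, 0.5),
                   stats::rnorm(n_per_class, -2, 0.5)),
             cbind(stats::rnorm(n_per_class, 2, 0.5),
                   stats::rnorm(n_per_class, 2, 0.5)))
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}
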