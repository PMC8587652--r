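#' Time-frequency grid container
#'
#' Holds a discrete Cohen-class distribution `C[n, k]` on a time x frequency
#' grid. The frequency convention follows the `e^{-j 4 pi v l}` discretization
#' of the lag transform: an `Nf`-point transform over the lag index spans
#' normalized frequency `[0, 0.5)` with bins `v_k = k / (2 Nf)`,
#' `k = 0..Nf-1`. Values are real for unmodified Hermitian kernels and for
#' the time-weighted (T) kernel, complex (purely imaginary up to rounding)
#' for the lag-derivative (D) kernel.
#'
#' @param values time x frequency matrix.
#' @param time_axis 0-based sample indices (length `nrow(values)`).
#' @param freq_axis normalized frequencies in `[0, 0.5)` (length
#'   `ncol(values)`).
#' @param kernel list describing the kernel (id, params, modified).
#' @param fs sampling rate in Hz (optional; `NA` for normalized time).
#' @return object of class `tfr_grid`.
#' @export
tfr_grid <- function(values, time_axis, freq_axis, kernel = list(id = "custom"),
                     fs = NA_real_) {
  stopifnot(nrow(values) == length(time_axis),
            ncol(values) == length(freq_axis))
  if (length(freq_axis) > 1L && any(diff(freq_axis) <= 0)) {
    stop("freq_axis must be strictly increasing")
  }
  if (any(freq_axis < 0 | freq_axis >= 0.5)) {
    stop("freq_axis must lie in [0, 0.5)")
  }
  structure(list(values = values, time_axis = time_axis,
                 freq_axis = freq_axis, kernel = kernel, fs = fs),
            class = "tfr_grid")
}

#' @export
print.tfr_grid <- function(x, ...) {
  cat(sprintf("<tfr_grid> %d x %d (time x freq), kernel '%s'%s\n",
              nrow(x$values), ncol(x$values), x$kernel$id,
              if (!is.null(x$kernel$modified) && x$kernel$modified != "none")
                paste0(" [", x$kernel$modified, "-modified]") else ""))
  invisible(x)
}

#' Instantaneous autocorrelation
#'
#' `R_x[n, l] = x[n + l] * Conj(x[n - l])` with zero padding outside the
#' signal support; the quantity whose lag transform yields the Wigner-Ville
#' distribution. Satisfies `R_x[n, -l] = Conj(R_x[n, l])`.
#'
#' @param x an [eeg_signal()].
#' @param n 0-based time index (scalar).
#' @param l lag index (vectorized).
#' @return complex value(s).
#' @export
inst_autocorr <- function(x, n, l) {
  xs <- as.complex(as_signal(x)$samples)
  N <- length(xs)
  at <- function(i) ifelse(i >= 0 & i < N, xs[pmax(i, 0) + 1L], 0 + 0i)
  at(n + l) * Conj(at(n - l))
}

# (2L+1) x N matrix of R_x[n, l], rows l = -L..L, columns n = 0..N-1.
lag_autocorr_matrix <- function(xs, L) {
  xs <- as.complex(xs)
  N <- length(xs)
  out <- matrix(0 + 0i, 2L * L + 1L, N)
  n <- seq.int(0L, N - 1L)
  for (l in seq.int(-L, L)) {
    ip <- n + l; im <- n - l
    ok <- ip >= 0L & ip < N & im >= 0L & im < N
    row <- rep(0 + 0i, N)
    row[ok] <- xs[ip[ok] + 1L] * Conj(xs[im[ok] + 1L])
    out[l + L + 1L, ] <- row
  }
  out
}

# columns shifted by d samples with zero fill: out[, j] = M[, j + d]
shift_cols <- function(M, d) {
  N <- ncol(M)
  out <- matrix(0 + 0i, nrow(M), N)
  if (d >= 0L) {
    if (d < N) out[, seq_len(N - d)] <- M[, seq.int(d + 1L, N)]
  } else {
    if (-d < N) out[, seq.int(-d + 1L, N)] <- M[, seq_len(N + d)]
  }
  out
}

# DFT over the lag dimension: fold rows l = -L..L into Nf bins (mod Nf) and
# transform; input lagmat is (2L+1) x N with row weights already applied.
lag_dft <- function(lagmat, L, Nf) {
  if (2L * L + 1L > Nf) stop("Nf must be at least the lag support 2L+1")
  Z <- matrix(0 + 0i, Nf, ncol(lagmat))
  for (l in seq.int(-L, L)) {
    bin <- ((l %% Nf) + Nf) %% Nf
    Z[bin + 1L, ] <- Z[bin + 1L, ] + lagmat[l + L + 1L, ]
  }
  stats::mvfft(Z)  # Nf x N, rows = frequency bins
}

check_analytic_input <- function(x) {
  if (!x$is_analytic && !is.complex(x$samples)) {
    warning("real (non-analytic) input: the discrete Wigner-Ville family ",
            "aliases; consider analytic() first")
  }
}

freq_axis_of <- function(Nf) seq.int(0L, Nf - 1L) / (2 * Nf)

#' Pseudo Wigner-Ville distribution
#'
#' Lag-windowed discrete WVD:
#' `W[n, k] = sum_l g[l] R_x[n, l] e^{-j 2 pi k l / Nf}` with frequency bin
#' `k` at normalized frequency `k / (2 Nf)`. Real-valued for Hermitian
#' (real, even) lag windows `g`.
#'
#' @param x [eeg_signal()], preferably analytic.
#' @param g lag window from [make_window()].
#' @param Nf number of frequency bins (>= lag support `2*g$half_length + 1`).
#' @return [tfr_grid()] (real values).
#' @export
pseudo_wvd <- function(x, g, Nf) {
  smoothed_pwvd(x, g, make_window("rectangular", 0L), Nf)
}

#' Smoothed-pseudo Wigner-Ville distribution (direct evaluation)
#'
#' Separable time and lag smoothing of the WVD:
#' `W[n, k] = sum_l sum_m g[l] h[m] R_x[n + m, l] e^{-j 2 pi k l / Nf}`.
#' This direct double-sum evaluation is the reference ("oracle") that the
#' recursive streaming implementation must reproduce. `modified` selects the
#' plain kernel, the time-weighted kernel `T: m g[l] h[m]` or the
#' lag-derivative kernel `D: g'[l] h[m]`, the two ingredients of the
#' reassignment operators.
#'
#' @param x [eeg_signal()], preferably analytic.
#' @param g lag window; `h` time window (both [make_window()]).
#' @param Nf number of frequency bins.
#' @param modified `"none"`, `"T"` or `"D"`.
#' @return [tfr_grid()]; real values for `"none"`/`"T"`, complex for `"D"`.
#' @export
smoothed_pwvd <- function(x, g, h, Nf, modified = c("none", "T", "D")) {
  modified <- match.arg(modified)
  x <- as_signal(x)
  check_analytic_input(x)
  M <- h$half_length
  # the derivative lag window overhangs the plain support by one sample
  L <- g$half_length + (modified == "D")
  R <- lag_autocorr_matrix(x$samples, L)
  hcoef <- h$coef
  if (modified == "T") hcoef <- seq.int(-M, M) * hcoef
  A <- matrix(0 + 0i, nrow(R), ncol(R))
  for (m in seq.int(-M, M)) {
    w <- hcoef[m + M + 1L]
    if (w != 0) A <- A + w * shift_cols(R, m)
  }
  gcoef <- if (modified == "D") window_derivative(g) else g$coef
  W <- lag_dft(A * gcoef, L, Nf)
  vals <- t(W)
  if (modified != "D") vals <- Re(vals)
  tfr_grid(vals, seq.int(0L, ncol(R) - 1L), freq_axis_of(Nf),
           kernel = list(id = "wigner_ville", modified = modified,
                         g = g$name, h = h$name, L = L, M = M),
           fs = x$fs)
}

#' Kernel specification for [cohen_distribution()]
#'
#' @param id one of `"wigner_ville"`, `"born_jordan"`, `"choi_williams"`,
#'   `"zam"`, `"spectrogram"`.
#' @param g lag window ([make_window()]); used by all but the spectrogram.
#' @param h analysis/time window; required for the spectrogram.
#' @param sigma Choi-Williams spread parameter (> 0); larger `sigma` means
#'   less time-direction smoothing.
#' @param modified `"none"`, `"T"` or `"D"` (separable kernels only).
#' @return list of class `kernel_spec`.
#' @export
kernel_spec <- function(id = c("wigner_ville", "born_jordan", "choi_williams",
                               "zam", "spectrogram"),
                        g = NULL, h = NULL, sigma = 1,
                        modified = c("none", "T", "D")) {
  id <- match.arg(id)
  modified <- match.arg(modified)
  if (id == "choi_williams" && sigma <= 0) stop("sigma must be positive")
  if (id == "spectrogram" && is.null(h)) stop("spectrogram needs window h")
  if (modified != "none" && id != "wigner_ville") {
    stop("modified kernels are implemented for the separable ",
         "pseudo-Wigner-Ville family only")
  }
  structure(list(id = id, g = g, h = h, sigma = sigma, modified = modified),
            class = "kernel_spec")
}

#' Cohen-class energy distributions
#'
#' Discrete time-lag smoothing implementation
#' `D[n, k] = sum_l sum_m G[m, l] R_x[n + m, l] e^{-j 2 pi k l / Nf}` where
#' `G` realizes the kernel: Born-Jordan smooths uniformly over `|m| <= |l|`
#' with weight `1/(2|l|+1)`; Choi-Williams applies a per-lag unit-mass
#' Gaussian in `m` with spread `|l| / sigma`; Zhao-Atlas-Marks is the cone
#' kernel (`|m| <= |l|`, no normalization); the spectrogram is computed as a
#' squared short-time transform magnitude; `wigner_ville` reduces to
#' [pseudo_wvd()].
#'
#' @param x [eeg_signal()], preferably analytic.
#' @param kernel a [kernel_spec()].
#' @param Nf number of frequency bins.
#' @return [tfr_grid()].
#' @export
cohen_distribution <- function(x, kernel, Nf) {
  stopifnot(inherits(kernel, "kernel_spec"))
  x <- as_signal(x)
  if (kernel$id == "spectrogram") {
    return(stft_spectrogram(x, kernel$h, Nf, hop = 1L))
  }
  g <- kernel$g
  if (is.null(g)) stop("kernel needs a lag window g")
  if (kernel$id == "wigner_ville") {
    grid <- smoothed_pwvd(x, g, make_window("rectangular", 0L), Nf,
                          modified = kernel$modified)
    grid$kernel$id <- "wigner_ville"
    return(grid)
  }
  check_analytic_input(x)
  L <- g$half_length
  R <- lag_autocorr_matrix(x$samples, L)
  sm <- matrix(0 + 0i, nrow(R), ncol(R))
  for (l in seq.int(-L, L)) {
    row <- R[l + L + 1L, , drop = FALSE]
    al <- abs(l)
    acc <- switch(kernel$id,
      born_jordan = {
        s <- rep(0 + 0i, ncol(R))
        for (m in seq.int(-al, al)) s <- s + shift_cols(row, m)
        s / (2 * al + 1)
      },
      zam = {
        s <- rep(0 + 0i, ncol(R))
        for (m in seq.int(-al, al)) s <- s + shift_cols(row, m)
        s
      },
      choi_williams = {
        if (al == 0L) {
          as.vector(row)
        } else {
          sl <- al / kernel$sigma
          ms <- seq.int(-ceiling(3 * sl), ceiling(3 * sl))
          w <- exp(-0.5 * (ms / sl)^2)
          w <- w / sum(w)
          s <- rep(0 + 0i, ncol(R))
          for (i in seq_along(ms)) s <- s + w[i] * shift_cols(row, ms[i])
          s
        }
      })
    sm[l + L + 1L, ] <- acc
  }
  W <- lag_dft(sm * g$coef, L, Nf)
  tfr_grid(Re(t(W)), seq.int(0L, ncol(R) - 1L), freq_axis_of(Nf),
           kernel = list(id = kernel$id, modified = "none", g = g$name,
                         sigma = kernel$sigma, L = L),
           fs = x$fs)
}

#' Short-time Fourier transform spectrogram
#'
#' `S[n, k] = |sum_m h[m] x[n + m] e^{-j 2 pi k m / (2 Nf)}|^2` over centred
#' frames, evaluated with a `2*Nf`-point transform so that the retained bins
#' `k = 0..Nf-1` sit at the same normalized frequencies `k / (2 Nf)` as the
#' Wigner-Ville family. Nonnegative everywhere. For `hop = 1` and the full
#' two-sided spectrum (`onesided = FALSE`) the total obeys
#' `sum S = 2 Nf * sum(h^2) * sum(|x|^2)` exactly whenever the signal is
#' supported at least a window half-length away from both record edges
#' (edge frames are zero-padded, so boundary samples otherwise see only part
#' of the window energy).
#'
#' @param x [eeg_signal()].
#' @param h analysis window ([make_window()]).
#' @param Nf retained frequency bins (transform length is `2*Nf`).
#' @param hop frame hop in samples (>= 1).
#' @param onesided keep bins `0..Nf-1` (default) or all `2*Nf`.
#' @return [tfr_grid()]; for `onesided = FALSE` the frequency axis is still
#'   `[0, 0.5)` scaled but contains all `2*Nf` bins as attribute-free columns.
#' @export
stft_spectrogram <- function(x, h, Nf, hop = 1L, onesided = TRUE) {
  x <- as_signal(x)
  hop <- as.integer(hop)
  if (hop < 1L) stop("hop must be >= 1")
  M <- h$half_length
  if (2L * M + 1L > 2L * Nf) stop("window exceeds transform length 2*Nf")
  xs <- as.complex(x$samples)
  N <- length(xs)
  centres <- seq.int(0L, N - 1L, by = hop)
  nfft <- 2L * Nf
  Z <- matrix(0 + 0i, nfft, length(centres))
  m <- seq.int(-M, M)
  for (j in seq_along(centres)) {
    idx <- centres[j] + m
    ok <- idx >= 0L & idx < N
    frame <- rep(0 + 0i, length(m))
    frame[ok] <- xs[idx[ok] + 1L] * h$coef[ok]
    Z[((m %% nfft) + nfft) %% nfft + 1L, j] <- frame
  }
  S <- Mod(stats::mvfft(Z))^2  # nfft x frames
  if (onesided) {
    vals <- t(S[seq_len(Nf), , drop = FALSE])
    fax <- freq_axis_of(Nf)
  } else {
    vals <- t(S)
    fax <- seq.int(0L, nfft - 1L) / (2 * nfft)  # placeholder monotone axis
  }
  tfr_grid(vals, centres, fax,
           kernel = list(id = "spectrogram", modified = "none", h = h$name,
                         M = M, hop = hop, onesided = onesided),
           fs = x$fs)
}
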