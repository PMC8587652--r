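#' Single-channel EEG signal container
#'
#' Light S3 container for a uniformly sampled amplitude sequence. Amplitudes
#' are in microvolts for EEG recordings and dimensionless for test signals.
#' An *analytic* signal is complex-valued with (numerically) no
#' negative-frequency spectral mass; it is the preferred input to the
#' Wigner-Ville family because it suppresses discrete-WVD aliasing.
#'
#' @param samples numeric or complex vector of amplitudes.
#' @param fs sampling rate in Hz (> 0).
#' @param is_analytic logical; `TRUE` only for complex signals produced by
#'   [analytic()] (or equivalent).
#' @return An object of class `eeg_signal` with fields `samples`, `fs`,
#'   `is_analytic`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 5 * (0:199) / 100), fs = 100)
#' length(s$samples)
#' @export
eeg_signal <- function(samples, fs, is_analytic = FALSE) {
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (is_analytic && !is.complex(samples)) {
    stop("an analytic signal must be complex-valued")
  }
  structure(list(samples = as.vector(samples), fs = fs,
                 is_analytic = isTRUE(is_analytic)),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (x$is_analytic) ", analytic" else ""))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

as_signal <- function(x, fs = NULL) {
  if (inherits(x, "eeg_signal")) return(x)
  if (is.null(fs)) stop("fs required when passing a bare vector")
  eeg_signal(x, fs)
}

#' Analytic signal via the FFT Hilbert transform
#'
#' Converts a real signal into its analytic (complex) form: the real part
#' equals the input and the spectrum carries no negative-frequency mass.
#' Interior positive-frequency bins are doubled, DC (and Nyquist for even
#' lengths) kept, negative bins zeroed.
#'
#' @param signal an [eeg_signal()] with real samples. Passing an
#'   already-analytic signal is a no-op with a warning.
#' @return analytic `eeg_signal`.
#' @export
analytic <- function(signal) {
  signal <- as_signal(signal)
  if (signal$is_analytic || is.complex(signal$samples)) {
    warning("signal is already analytic; returning unchanged")
    return(signal)
  }
  x <- signal$samples
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    if (n > 1L) w[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * w, inverse = TRUE) / n
  eeg_signal(z, signal$fs, is_analytic = TRUE)
}

#' Fraction of spectral energy at negative frequencies
#'
#' Diagnostic used by the analytic-signal invariant: for a proper analytic
#' signal the returned fraction is below 1e-8.
#'
#' @param signal an [eeg_signal()].
#' @return scalar in [0, 1].
#' @export
negative_freq_fraction <- function(signal) {
  x <- as_signal(signal)$samples
  n <- length(x)
  if (n < 2L) return(0)
  X <- Mod(stats::fft(x))^2
  neg <- if (n %% 2L == 0L) {
    if (n / 2L + 2L <= n) sum(X[(n / 2L + 2L):n]) else 0
  } else {
    sum(X[((n + 3L) / 2L):n])
  }
  tot <- sum(X)
  if (tot == 0) 0 else neg / tot
}
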