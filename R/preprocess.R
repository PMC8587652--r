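#' Second-order IIR notch filter for mains interference
#'
#' Classic constrained biquad notch: zeros on the unit circle at the notch
#' frequency, poles just inside at the same angle. The -3 dB rejection
#' bandwidth defaults to 2 Hz. An IIR design is used (rather than FIR) for
#' its short response time; the phase response is nonlinear, which is
#' acceptable because the discriminative information lives in the frequency
#' content. Causal single-pass application is the default; set
#' `zero_phase = TRUE` for a forward-backward (zero-phase) pass.
#'
#' @param signal real [eeg_signal()].
#' @param f0 notch frequency in Hz (default 50, the European mains).
#' @param bandwidth -3 dB bandwidth in Hz.
#' @param zero_phase apply forward and backward for zero phase lag.
#' @return filtered [eeg_signal()] of the same length.
#' @export
notch50 <- function(signal, f0 = 50, bandwidth = 2, zero_phase = FALSE) {
  signal <- as_signal(signal)
  fs <- signal$fs
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist")
  ba <- notch_coefficients(f0, fs, bandwidth)
  y <- iir_filter(ba$b, ba$a, signal$samples)
  if (zero_phase) y <- rev(iir_filter(ba$b, ba$a, rev(y)))
  eeg_signal(y, fs, is_analytic = FALSE)
}

# RBJ-cookbook biquad notch; Q = f0 / bandwidth.
notch_coefficients <- function(f0, fs, bandwidth) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * (f0 / bandwidth))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Direct-form IIR via two C-level passes of stats::filter: FIR part by
# convolution (front-padded so early samples see a zero past), then the AR
# recursion y[i] = v[i] - a[2] y[i-1] - a[3] y[i-2].
iir_filter <- function(b, a, x) {
  p <- length(b) - 1L
  v <- stats::filter(c(numeric(p), x), b, method = "convolution", sides = 1L)
  v <- as.numeric(v)[(p + 1L):(p + length(x))]
  if (length(a) > 1L) {
    as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  } else {
    v
  }
}

#' Complex frequency response of the default notch design
#'
#' Evaluates `H(e^{i 2 pi f / fs})` for the biquad returned by the notch
#' design; the independent check that the filter attenuates the mains line
#' while leaving the EEG bands untouched.
#'
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param f0,bandwidth notch design parameters.
#' @return complex vector of gains.
#' @export
notch_response <- function(f, fs, f0 = 50, bandwidth = 2) {
  ba <- notch_coefficients(f0, fs, bandwidth)
  z <- exp(-1i * 2 * pi * f / fs)
  (ba$b[1] + ba$b[2] * z + ba$b[3] * z^2) /
    (ba$a[1] + ba$a[2] * z + ba$a[3] * z^2)
}

# event-overlap labeling rule shared by segment() and make_dataset():
# a window [s, s+win) is positive iff some kcomplex event overlaps it by at
# least min_overlap of the *event* duration.
label_windows <- function(starts, win_s, events, min_overlap = 0.5) {
  kc <- events[events$label == "kcomplex", , drop = FALSE]
  if (nrow(kc) == 0L) return(integer(length(starts)))
  vapply(starts, function(s) {
    ov <- pmin(s + win_s, kc$onset_s + kc$duration_s) - pmax(s, kc$onset_s)
    as.integer(any(ov >= min_overlap * kc$duration_s))
  }, integer(1))
}

#' Cut a recording into labeled sliding windows
#'
#' Sliding fixed-length windows with hop `hop_s`; a window is labeled
#' positive iff a K-complex event overlaps it by at least `min_overlap` of
#' the event's duration. A 2 s window covers the ~900 ms K-complex plus
#' context.
#'
#' @param signal real [eeg_signal()].
#' @param events an [event_list()] (may be empty).
#' @param win_s,hop_s window length and hop in seconds.
#' @param min_overlap fraction of the event duration required for a positive
#'   label.
#' @return `segment_dataset` (see [make_dataset()]); empty with a warning if
#'   the window is longer than the record.
#' @export
segment_record <- function(signal, events = event_list(), win_s = 2.0,
                           hop_s = 0.5, min_overlap = 0.5) {
  signal <- as_signal(signal)
  fs <- signal$fs
  wlen <- as.integer(round(win_s * fs))
  if (wlen < 2L) stop("window must contain at least 2 samples")
  n <- length(signal$samples)
  if (wlen > n) {
    warning("window longer than record; returning empty dataset")
    return(structure(list(X = matrix(numeric(0), 0L, wlen), y = integer(0),
                          meta = data.frame(record = integer(0),
                                            start_s = numeric(0),
                                            fs = numeric(0)),
                          fs = fs, win_s = win_s),
                     class = "segment_dataset"))
  }
  hop <- max(1L, as.integer(round(hop_s * fs)))
  i0 <- seq.int(1L, n - wlen + 1L, by = hop)
  starts <- (i0 - 1L) / fs
  X <- t(vapply(i0, function(i) signal$samples[i:(i + wlen - 1L)],
                numeric(wlen)))
  structure(list(X = X, y = label_windows(starts, win_s, events, min_overlap),
                 meta = data.frame(record = 1L, start_s = starts, fs = fs),
                 fs = fs, win_s = win_s),
            class = "segment_dataset")
}
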