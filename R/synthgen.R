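#' Linear-FM chirp test signal
#'
#' Unit-amplitude linear chirp in normalized frequency. The instantaneous
#' normalized frequency at sample `k` (0-based) is
#' `f0 + (f1 - f0) * k / (n_samples - 1)` and the phase is the cumulative sum
#' of the instantaneous frequency. The 512-sample 0.1 -> 0.3 configuration is
#' the canonical test signal for comparing Cohen-class distributions.
#'
#' @param n_samples number of samples (>= 2).
#' @param f0,f1 start/end normalized frequency in `[0, 0.5)`.
#' @param amplitude peak amplitude (default 1).
#' @return real [eeg_signal()] with `fs = 1` (normalized time).
#' @examples
#' ch <- make_chirp(512, 0.1, 0.3)
#' @export
make_chirp <- function(n_samples, f0, f1, amplitude = 1) {
  n <- as.integer(n_samples)
  if (n < 2L) stop("n_samples must be >= 2")
  if (f0 < 0 || f0 >= 0.5 || f1 < 0 || f1 >= 0.5) {
    stop("normalized frequencies must lie in [0, 0.5)")
  }
  k <- seq_len(n) - 1L
  finst <- f0 + (f1 - f0) * k / (n - 1L)
  phase <- 2 * pi * cumsum(finst)
  eeg_signal(amplitude * cos(phase), fs = 1)
}

#' Instantaneous normalized frequency law of [make_chirp()]
#' @param n_samples,f0,f1 as in [make_chirp()].
#' @return numeric vector of per-sample normalized frequencies.
#' @export
chirp_frequency_law <- function(n_samples, f0, f1) {
  k <- seq_len(n_samples) - 1L
  f0 + (f1 - f0) * k / (n_samples - 1L)
}

#' K-complex waveform template
#'
#' Smooth biphasic stage-2 K-complex morphology: a sharp negative peak
#' (deeper than -100 uV in healthy adults) early in the event, a positive
#' lobe peaking at 350-550 ms, and a return to baseline by ~900 ms. The
#' waveform is a clamped monotone Hermite spline through the landmarks
#' (0, 0), (80 ms, -neg_peak), (pos_latency, +0.6 neg_peak), (total, 0);
#' the literature gives amplitudes and latencies but no analytic waveform.
#'
#' @param fs sampling rate (Hz).
#' @param neg_peak_uV magnitude of the negative peak in microvolts.
#' @param pos_latency_ms latency of the positive lobe peak (ms), strictly
#'   inside `(0, total_ms)`.
#' @param total_ms total event duration (ms).
#' @return real [eeg_signal()] of `round(total_ms * fs / 1000)` samples.
#' @export
kcomplex_template <- function(fs, neg_peak_uV = 120, pos_latency_ms = 450,
                              total_ms = 900) {
  if (total_ms <= 0 || pos_latency_ms <= 0 || pos_latency_ms >= total_ms) {
    stop("need 0 < pos_latency_ms < total_ms and positive durations")
  }
  n <- max(2L, as.integer(round(total_ms * fs / 1000)))
  t_ms <- (seq_len(n) - 1L) * 1000 / fs
  A <- neg_peak_uV
  lm_t <- c(0, min(80, pos_latency_ms / 2), pos_latency_ms, total_ms)
  lm_v <- c(0, -A, 0.6 * A, 0)
  f <- stats::splinefun(lm_t, lm_v, method = "monoH.FC")
  y <- f(t_ms)
  # the sampled grid may miss the landmark extremum at coarse fs; rescale so
  # the sampled minimum honours the requested peak
  if (A > 0 && min(y) > -A) y <- y * (A / -min(y))
  eeg_signal(y, fs)
}

#' Sleep-spindle waveform template
#'
#' Gaussian-enveloped sinusoid in the sigma band (11-16 Hz, default 13 Hz),
#' the burst that frequently follows a K-complex in stage-2 sleep.
#'
#' @param fs sampling rate (Hz).
#' @param freq spindle frequency (Hz), below Nyquist.
#' @param dur_s duration in seconds.
#' @param amplitude peak envelope amplitude (default 1).
#' @return real [eeg_signal()].
#' @export
spindle_template <- function(fs, freq = 13, dur_s = 1, amplitude = 1) {
  if (freq <= 0 || freq >= fs / 2) stop("freq must lie in (0, fs/2)")
  if (dur_s <= 0) stop("dur_s must be positive")
  n <- max(2L, as.integer(round(dur_s * fs)))
  t <- (seq_len(n) - 1L) / fs
  centre <- (n - 1L) / (2 * fs)
  env <- exp(-0.5 * ((t - centre) / (dur_s / 6))^2)
  eeg_signal(amplitude * env * sin(2 * pi * freq * t), fs)
}

#' Synthetic recording configuration
#'
#' Defaults encode the stated stage-2 sleep-EEG structure: K-complex negative
#' peaks above 100 uV recurring roughly every 1.0-1.7 min, often followed by
#' sleep spindles, on a background of delta oscillations (1.6-4.0 Hz), a
#' 0.8 Hz slow wave, broadband noise, and 50 Hz mains interference.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz); 200 Hz accommodates the 50 Hz notch and the
#'   spindle band.
#' @param kc_interval_range_s uniform inter-onset range for K-complexes (s).
#' @param kc_neg_peak_uV minimum negative-peak magnitude (uV); instances draw
#'   amplitudes in `[1, 1.25] *` this value.
#' @param kc_pos_latency_ms_range positive-lobe latency range (ms).
#' @param kc_total_ms nominal K-complex duration (ms); instances jitter
#'   within +-4 percent.
#' @param spindle_freq_Hz,spindle_follow_prob spindle frequency and the
#'   probability that a spindle follows a K-complex.
#' @param delta_band_Hz,slow_wave_Hz,mains_Hz background component bands.
#' @param noise_band_Hz broadband background band (Hz).
#' @param noise_rms_uV,delta_rms_uV,slow_amp_uV,mains_amp_uV,spindle_amp_uV
#'   component amplitudes (uV; `*_rms` are root-mean-square, `*_amp` peak).
#' @param seed integer RNG seed or `NULL`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600, fs = 200,
                         kc_interval_range_s = c(60, 102),
                         kc_neg_peak_uV = 120,
                         kc_pos_latency_ms_range = c(350, 550),
                         kc_total_ms = 900,
                         spindle_freq_Hz = 13, spindle_follow_prob = 0.5,
                         delta_band_Hz = c(1.6, 4.0), slow_wave_Hz = 0.8,
                         mains_Hz = 50, noise_band_Hz = c(0.5, 30),
                         noise_rms_uV = 10, delta_rms_uV = 8,
                         slow_amp_uV = 15, mains_amp_uV = 10,
                         spindle_amp_uV = 25, seed = NULL) {
  cfg <- list(duration_s = duration_s, fs = fs,
              kc_interval_range_s = kc_interval_range_s,
              kc_neg_peak_uV = kc_neg_peak_uV,
              kc_pos_latency_ms_range = kc_pos_latency_ms_range,
              kc_total_ms = kc_total_ms,
              spindle_freq_Hz = spindle_freq_Hz,
              spindle_follow_prob = spindle_follow_prob,
              delta_band_Hz = delta_band_Hz, slow_wave_Hz = slow_wave_Hz,
              mains_Hz = mains_Hz, noise_band_Hz = noise_band_Hz,
              noise_rms_uV = noise_rms_uV, delta_rms_uV = delta_rms_uV,
              slow_amp_uV = slow_amp_uV, mains_amp_uV = mains_amp_uV,
              spindle_amp_uV = spindle_amp_uV, seed = seed)
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(duration_s > 0, fs > 0,
              length(kc_interval_range_s) == 2L,
              kc_interval_range_s[1] > 0,
              kc_interval_range_s[1] <= kc_interval_range_s[2],
              kc_neg_peak_uV >= 0, kc_total_ms > 0,
              all(kc_pos_latency_ms_range > 0),
              kc_pos_latency_ms_range[2] < kc_total_ms,
              spindle_freq_Hz > 0, spindle_freq_Hz < fs / 2,
              spindle_follow_prob >= 0, spindle_follow_prob <= 1,
              mains_Hz > 0, mains_Hz < fs / 2,
              delta_band_Hz[1] > 0, delta_band_Hz[1] < delta_band_Hz[2])
  })
  invisible(cfg)
}

#' Event annotation table
#'
#' @param onset_s,duration_s,label parallel vectors: onsets (s, nondecreasing),
#'   durations (s, > 0), labels in `{"kcomplex", "spindle"}`.
#' @return `data.frame` of class `event_list`.
#' @export
event_list <- function(onset_s = numeric(), duration_s = numeric(),
                       label = character()) {
  stopifnot(length(onset_s) == length(duration_s),
            length(onset_s) == length(label))
  if (length(onset_s) > 1L && any(diff(onset_s) < 0)) {
    stop("event onsets must be nondecreasing")
  }
  if (any(duration_s <= 0)) stop("event durations must be positive")
  if (!all(label %in% c("kcomplex", "spindle"))) {
    stop("labels must be 'kcomplex' or 'spindle'")
  }
  structure(data.frame(onset_s = as.numeric(onset_s),
                       duration_s = as.numeric(duration_s),
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

# FFT bandpass with raised-cosine edges; adequate (and exactly reproducible)
# for background synthesis, not meant as a general filtering tool.
fft_bandpass <- function(x, fs, lo, hi, taper_Hz = 0.5) {
  n <- length(x)
  f <- abs(seq(0, n - 1) * fs / n)
  f <- pmin(f, fs - f)
  mask <- rep(0, n)
  ramp <- function(d) 0.5 * (1 - cos(pi * pmin(pmax(d, 0), 1)))
  mask <- ramp((f - (lo - taper_Hz)) / taper_Hz) *
          ramp(((hi + taper_Hz) - f) / taper_Hz)
  mask[f >= lo & f <= hi] <- 1
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE) / n)
}

#' Generate an annotated synthetic stage-2 sleep-EEG recording
#'
#' Background = band-limited broadband noise + delta-band (1.6-4 Hz)
#' component + 0.8 Hz slow wave + 50 Hz mains sinusoid. K-complex onsets are a
#' renewal process with uniform inter-onset intervals on
#' `kc_interval_range_s`; each K-complex is followed by a sleep spindle with
#' probability `spindle_follow_prob`. Every inserted event is annotated.
#' Output is bit-identical for identical configurations (including `seed`).
#'
#' @param cfg a [synth_config()].
#' @return list with `signal` ([eeg_signal()], uV) and `events`
#'   ([event_list()]).
#' @examples
#' rec <- synth_record(synth_config(duration_s = 300, seed = 1))
#' nrow(rec$events)
#' @export
synth_record <- function(cfg) {
  validate_synth_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs

  noise <- fft_bandpass(stats::rnorm(n), fs, cfg$noise_band_Hz[1],
                        cfg$noise_band_Hz[2])
  noise <- noise * cfg$noise_rms_uV / stats::sd(noise)
  delta <- fft_bandpass(stats::rnorm(n), fs, cfg$delta_band_Hz[1],
                        cfg$delta_band_Hz[2])
  delta <- delta * cfg$delta_rms_uV / stats::sd(delta)
  slow <- cfg$slow_amp_uV * sin(2 * pi * cfg$slow_wave_Hz * t +
                                  stats::runif(1, 0, 2 * pi))
  mains <- cfg$mains_amp_uV * sin(2 * pi * cfg$mains_Hz * t +
                                    stats::runif(1, 0, 2 * pi))
  x <- noise + delta + slow + mains

  onset <- numeric(); dur <- numeric(); lab <- character()
  tcur <- stats::runif(1, cfg$kc_interval_range_s[1],
                       cfg$kc_interval_range_s[2])
  while (TRUE) {
    total_ms <- cfg$kc_total_ms * stats::runif(1, 0.96, 1.04)
    if (tcur + total_ms / 1000 >= cfg$duration_s) break
    amp <- cfg$kc_neg_peak_uV * stats::runif(1, 1.0, 1.25)
    lat <- stats::runif(1, cfg$kc_pos_latency_ms_range[1],
                        cfg$kc_pos_latency_ms_range[2])
    tmpl <- kcomplex_template(fs, amp, lat, total_ms)$samples
    i0 <- as.integer(round(tcur * fs)) + 1L
    idx <- i0:min(n, i0 + length(tmpl) - 1L)
    x[idx] <- x[idx] + tmpl[seq_along(idx)]
    onset <- c(onset, tcur); dur <- c(dur, total_ms / 1000)
    lab <- c(lab, "kcomplex")

    if (stats::runif(1) < cfg$spindle_follow_prob) {
      sp_on <- tcur + total_ms / 1000 + stats::runif(1, 0.05, 0.3)
      sp_dur <- stats::runif(1, 0.5, 1.0)
      if (sp_on + sp_dur < cfg$duration_s) {
        sp <- spindle_template(fs, cfg$spindle_freq_Hz, sp_dur,
                               cfg$spindle_amp_uV * stats::runif(1, 0.8, 1.2))
        j0 <- as.integer(round(sp_on * fs)) + 1L
        jdx <- j0:min(n, j0 + length(sp$samples) - 1L)
        x[jdx] <- x[jdx] + sp$samples[seq_along(jdx)]
        onset <- c(onset, sp_on); dur <- c(dur, sp_dur)
        lab <- c(lab, "spindle")
      }
    }
    tcur <- tcur + stats::runif(1, cfg$kc_interval_range_s[1],
                                cfg$kc_interval_range_s[2])
  }
  list(signal = eeg_signal(x, fs),
       events = event_list(onset, dur, lab))
}

#' Build a labeled fixed-length segment dataset from synthetic recordings
#'
#' Cuts `win_s`-long waveform segments from a generated recording: positives
#' are centred (with jitter) on K-complex events, negatives are drawn from
#' K-complex-free stretches (spindles and background remain, keeping the
#' negative class non-trivial). Rows are shuffled so a head/tail split is a
#' random split. With 389 segments a 90/10 split mirrors a 350/39 protocol.
#'
#' @param cfg [synth_config()]; its `duration_s` must supply enough K-complex
#'   events for the requested positives, otherwise an error is raised.
#' @param n_segments total number of segments.
#' @param pos_fraction fraction of positive (K-complex) segments in `(0, 1)`.
#' @param seed integer seed controlling record generation and sampling.
#' @param win_s segment length in seconds.
#' @param notch apply the 50 Hz notch to the record before cutting, matching
#'   the preprocessing that [run_detection()] applies at inference time.
#' @return `segment_dataset`: list with `X` (`n_segments x win_s*fs` waveform
#'   matrix), `y` (0/1 labels), `meta` (per-segment start time), `fs`,
#'   `win_s`, and the source `events`.
#' @export
make_dataset <- function(cfg, n_segments, pos_fraction, seed = 1,
                         win_s = 2.0, notch = TRUE) {
  if (pos_fraction <= 0 || pos_fraction >= 1) {
    stop("pos_fraction must lie in (0, 1)")
  }
  cfg$seed <- seed
  rec <- synth_record(cfg)
  if (notch) rec$signal <- notch50(rec$signal)
  fs <- cfg$fs
  x <- rec$signal$samples
  n <- length(x)
  wlen <- as.integer(round(win_s * fs))
  kc <- rec$events[rec$events$label == "kcomplex", , drop = FALSE]
  n_pos <- as.integer(round(pos_fraction * n_segments))
  n_neg <- n_segments - n_pos
  if (nrow(kc) < n_pos) {
    stop(sprintf(
      "requested %d positive segments but only %d K-complex events available; increase cfg$duration_s",
      n_pos, nrow(kc)))
  }
  pick <- sample.int(nrow(kc), n_pos)
  centre <- kc$onset_s[pick] + kc$duration_s[pick] / 2
  # the labeling rule admits any event-centre phase inside the window, and
  # sliding-window detection hits events at every phase: draw the centre
  # uniformly across the window (small margin) so training matches deployment
  starts_pos <- centre - stats::runif(n_pos, 0.05, win_s - 0.05)
  starts_pos <- pmin(pmax(starts_pos, 0), n / fs - win_s)

  # rejection-sample negative starts with zero K-complex overlap
  starts_neg <- numeric(0)
  guard <- 0L
  while (length(starts_neg) < n_neg) {
    cand <- stats::runif(n_neg, 0, n / fs - win_s)
    ov <- vapply(cand, function(s) {
      any(pmin(s + win_s, kc$onset_s + kc$duration_s) -
            pmax(s, kc$onset_s) > 0)
    }, logical(1))
    starts_neg <- c(starts_neg, cand[!ov])
    guard <- guard + 1L
    if (guard > 200L) stop("could not place negative segments")
  }
  starts_neg <- starts_neg[seq_len(n_neg)]

  starts <- c(starts_pos, starts_neg)
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  ord <- sample.int(n_segments)
  starts <- starts[ord]; y <- y[ord]
  X <- t(vapply(starts, function(s) {
    i0 <- as.integer(round(s * fs)) + 1L
    x[i0:(i0 + wlen - 1L)]
  }, numeric(wlen)))
  structure(list(X = X, y = y,
                 meta = data.frame(record = 1L, start_s = starts, fs = fs),
                 fs = fs, win_s = win_s, events = rec$events),
            class = "segment_dataset")
}

#' Head/tail split of a (shuffled) segment dataset
#' @param dataset a `segment_dataset`.
#' @param train_frac fraction of rows used for training (default 0.9).
#' @return list with `train` and `test` segment datasets.
#' @export
split_dataset <- function(dataset, train_frac = 0.9) {
  n <- length(dataset$y)
  k <- as.integer(round(train_frac * n))
  take <- function(idx) {
    structure(list(X = dataset$X[idx, , drop = FALSE], y = dataset$y[idx],
                   meta = dataset$meta[idx, , drop = FALSE],
                   fs = dataset$fs, win_s = dataset$win_s),
              class = "segment_dataset")
  }
  list(train = take(seq_len(k)), test = take(seq.int(k + 1L, n)))
}
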