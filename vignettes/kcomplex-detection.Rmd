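---
title: "Detecting K-complexes with recursive reassigned Cohen-class distributions"
author: "kcdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting K-complexes with recursive reassigned Cohen-class distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcdetect)
```

## The problem

The K-complex is the largest transient waveform of stage-2 sleep EEG: a
sharp negative deflection, usually deeper than -100 uV, followed by a
slower positive lobe peaking around 350-550 ms, with the event essentially
over by ~900 ms. K-complexes recur roughly every 1.0-1.7 minutes and are
often followed by a sleep-spindle burst (11-16 Hz). They matter clinically
(sleep quality, sleep-disorder screening, candidate biomarkers for
neurodegenerative disease), but they are hard to detect automatically:
delta-band background activity (1.6-4 Hz) looks similar, the events are
aperiodic, and recordings carry 50 Hz mains interference.

`kcdetect` implements a detection pipeline that works in the
time-frequency plane: an IIR notch removes the mains line, the recording
is cut into short segments, each segment is mapped to a *reassigned
smoothed-pseudo Wigner-Ville distribution* whose evaluation admits a
streaming recursion, fixed-length features are extracted from the
distribution, and a small from-scratch multilayer perceptron (MLP)
classifies each segment. A synthetic stage-2 sleep-EEG generator makes
every stage testable without clinical data.

## Cohen-class distributions and their discrete conventions

All quadratic time-frequency energy distributions of the Cohen class can
be written as smoothed transforms of the instantaneous autocorrelation
`R_x[n, l] = x[n + l] Conj(x[n - l])`. The package evaluates

    C[n, k] = sum_l sum_m  G[m, l] R_x[n + m, l] e^{-j 2 pi k l / Nf}

with the kernel `G` selecting the member: `g[l] h[m]` (separable lag/time
windows) gives the smoothed-pseudo Wigner-Ville distribution (SPWVD),
uniform weights over `|m| <= |l|` give Born-Jordan, a per-lag Gaussian
gives Choi-Williams, the bare cone gives Zhao-Atlas-Marks, and the squared
short-time transform magnitude gives the spectrogram.

Because the lag enters the autocorrelation twice (`n + l` and `n - l`),
the discrete transform advances phase at twice the usual rate; an
`Nf`-point transform therefore spans normalized frequency `[0, 0.5)` with
bins `v_k = k / (2 Nf)`. All grids in the package carry this axis
(`tfr_grid`). Analytic-signal input (`analytic()`, an FFT Hilbert step) is
the default path for the Wigner-Ville family: a real input would fold
spectral images into the band and the functions warn about it.

Windows are symmetric on `m = -M..M` (`make_window()`): rectangular,
Hamming, Hanning, Blackman, Bartlett, half-sine, and the one-pole
exponential `alpha^(-m)` with forgetting factor `alpha` (default 0.94, a
conventional value for recursions of this kind; the method itself fixes no
value).

## Reassignment

Bilinear smoothing trades interference suppression against smearing.
Reassignment (reallocation) moves each cell's value to a locally estimated
centre of gravity, computed from two companion distributions: the
time-weighted kernel `T: m g[l] h[m]` and the lag-derivative kernel
`D: g'[l] h[m]`. The operators are

    n_hat = n + Re(C_T / C)
    v_hat = v + asin(clamp(-Im(C_D / C))) / (4 pi)

and `apply_reassign()` accumulates each valid cell's value at the nearest
grid cell of `(n_hat, v_hat)`, clipping off-grid targets to the edge so
the signed total is conserved exactly.

Two numerical choices here deserve justification because they differ from
the textbook presentation:

* **The derivative window is a central difference, not a sampled analytic
  derivative.** By the shift theorem, central differences of the
  zero-padded window satisfy `sum_l g'[l] z^l = (z^{-1} - z)/2 sum_l g[l] z^l`
  *exactly*, so the ratio `C_D / C` stays finite where the smoothing
  kernel has zeros (the two transforms share every zero). A sampled
  analytic derivative does not have this property and produces
  thousands-of-bins excursions at low-magnitude sidelobe cells. The
  derivative support is one sample wider than the window, which carries
  the boundary mass of windows that do not vanish at their endpoints; all
  streams run on this extended support.
* **The arcsine in the frequency operator.** For a pure tone at offset
  `delta` from a bin, the central-difference construction makes
  `Im(C_D / C) = -sin(4 pi delta)` identically. Inverting that
  characteristic with `asin` localizes tones exactly (to ~1e-13 bins on
  the energetic region of the grid) for offsets up to 1/8 cycle; the
  linear textbook operator is its small-ratio limit and leaves an
  `O(delta^3)` bias. The clamp to `[-1, 1]` keeps arbitrary signals
  defined.

The operator signs and scales are frozen constants pinned by calibration
tests: an impulse reassigns onto its time sample (exactly), a tone onto
its frequency bin. Cells with `|C|` below a validity floor (default
`1e-12 * max |C|`) keep the identity mapping; near signal edges the
autocorrelation support is truncated and localization degrades there,
which is why the calibration tests assert on interior rows.

## Recursive (streaming) evaluation

The time-smoothing sum `S[n, l] = sum_m h[m] R[n + m, l]` normally costs
`O(M)` per step. If `h` is a sum of exponentials `h[m] = sum_k c_k a_k^(-m)`
-- exactly true for the rectangular, exponential, half-sine, Hamming,
Hanning and Blackman windows -- each component obeys a first-order
recursion that touches only the entering and leaving autocorrelation
columns:

    S[n] = a S[n-1] + c a^(-M)  R[n + M] - c a^(M + 1) R[n - M - 1]

and the time-weighted stream needed for reassignment obeys the coupled
recursion

    T[n] = a T[n-1] - S[n] + (M+1) c a^(-M) R[n + M] + M c a^(M+1) R[n - M - 1].

These update equations were derived from scratch for this package and are
validated against the direct double-sum evaluation to 1e-8 relative error
over all admissible window families (they agree to machine precision in
practice). The lag-derivative stream needs no extra recursion at all: it
reuses the plain per-lag accumulators under the derivative lag window. The
per-step cost is independent of `M` -- the instrumented operation counters
in `recursive_spwvd_stream(count_ops = TRUE)` return identical per-step
counts for `M` in {4, 8, 16, 32} -- and the reallocation operators
themselves cost two divisions and two additions per frequency bin
(`count_reassign_ops()`), within the advertised bounds of `3N` additions
and `2N` multiplications per step. Streams warm up from silence
(accumulators start at zero `M + 1` steps before the first emitted sample),
so the recursion is exact from the first output row, not just
asymptotically.

Hermitian product kernels additionally admit a one-sided lag evaluation
(`fast_hermitian_eval()`): the `l` and `-l` summands are conjugate (plain
and T kernels) or anti-conjugate (D kernel), so `2 Re` / `2i Im` of the
one-sided sum, with an `l = 0` correction for the real case, halves the
lag-loop multiplications.

## The synthetic stage-2 generator

`synth_record()` emulates the stated structure of stage-2 sleep EEG:

| component | default | why |
|---|---|---|
| sampling rate | 200 Hz | accommodates the 50 Hz notch and the spindle band; the method fixes no rate |
| K-complex template | -120 uV peak, +0.6 peak positive lobe at 350-550 ms, 900 ms total | monotone spline through the landmark amplitudes/latencies reported for the waveform; no analytic form exists |
| inter-onset intervals | uniform on [60, 102] s | "approximately every 1.0-1.7 min" is the only constraint; uniform is the least-informative choice on that range |
| spindles | 13 Hz, 0.5-1 s, follow a K-complex with p = 0.5 | spindles frequently follow K-complexes |
| background | broadband 0.5-30 Hz noise (10 uV RMS) + delta 1.6-4 Hz (8 uV RMS) + 0.8 Hz slow wave (15 uV) + 50 Hz mains (10 uV) | the stated background components at amplitudes typical of adult stage-2 recordings |

Instance amplitudes draw from `[1, 1.25] x` the 120 uV floor and durations
jitter within 4 percent, so every generated event honours the morphology
invariants. `make_dataset()` cuts labeled 2 s segments: positives place
the event centre uniformly across the window (matching both the >= 50
percent-overlap labeling rule and the phase distribution that sliding-window
detection encounters), negatives contain no K-complex but keep spindles and
background. The record is notch-filtered before cutting, matching the
inference-time preprocessing.

What the generator does *not* emulate: real EEG nonstationarity across the
night, movement/EMG/eye artifacts, electrode drift, inter-subject
morphology differences, or multi-channel structure. A green detection test
therefore establishes that the pipeline recovers the stated morphology
from the stated background -- not clinical performance.

## Features and classifier

The feature map (`tfr_features()`) resamples the magnitude of the
segment's reassigned SPWVD to a 16 x 16 patch, applies `log1p` and a
per-segment z-score, and appends three band-energy fractions (delta
0.5-4 Hz, theta 4-8 Hz, sigma 11-16 Hz): 259 features. The patch keeps the
time-frequency signature; the fractions summarize exactly the contrast
that separates K-complexes (delta-dominant) from spindles
(sigma-dominant). Compression and normalization are deliberate: the
classifier's S-shaped activations saturate on raw uV^2-scale distribution
values.

The MLP (`init_mlp()`, `mlp_train()`) is written from scratch -- softmax
head, binary cross-entropy, exact backpropagation (finite-difference
checked to 1e-6), single-example SGD -- chiefly because the arctan
activation, with derivative `1/(1 + x^2)`, is absent from mainstream
frameworks. The reference protocol is batch size 1, learning rate 1e-5,
100 epochs, model selection by lowest test-lot cost. Selecting on the test
lot leaks information; `mlp_train()` reproduces it because it is the
stated protocol, and the clean alternative (pass a validation set as the
evaluation lot and keep a held-out test set) is a one-argument change.

### What the protocol achieves on the synthetic benchmark

The acceptance suite trains the best-reported architecture (six hidden
layers of eight arctan units) on the default benchmark (389 segments,
350/39 split). Two facts, both computed by the tests:

* At learning rate 1e-2 (or 1e-3) the network reaches >= 0.90 test
  accuracy within 100 epochs -- the features are linearly separable to
  near-perfection.
* At the protocol's 1e-5 with 100 epochs it stays at the class base rate
  (~0.52 over 5 seeds). The cause is arithmetic, not statistical: bounded
  activations cap the hidden outputs at pi/2, so 35,000 batch-1 updates at
  1e-5 move the output-layer weights by at most ~0.3 coherent units, an
  order of magnitude short of the required logit swing -- for any feature
  scaling (raw-scale features saturate the first layer instead). The same
  run does reach 100 percent accuracy if left for ~1400 epochs. The
  corresponding acceptance criterion is therefore left failing by design
  rather than silently retuned; the companion separability test documents
  where the shortfall lives.

## Numerical choices and degenerate inputs

* Frequency bins: `Nf` must cover the lag support (`2L + 3` with the
  derivative overhang); bin `k` maps to `k / (2 Nf)`.
* Reassignment targets round to the nearest cell; off-grid targets clip to
  the edge (conservation) unless `clip = FALSE` discards them.
* Validity floor `1e-12 * max |C|`; invalid cells stay in place.
* Signed values are reassigned as-is (no magnitude trick); the
  distribution total is conserved to machine precision.
* Zero signals produce zero grids, zero feature vectors, and no
  detections; windows with literally no signal are assigned probability 0
  before thresholding.
* `bce_loss()` clips probabilities to `[1e-12, 1 - 1e-12]`.
* The EDF writer quantizes to 16 bits over the recording's physical range
  and pads the tail record with zeros, storing the true sample count so
  the reader restores the original length.

## Limitations

Single-channel only; no artifact model; the feature map is fixed rather
than learned; detection merges adjacent positive windows with a 0.25 s gap
and reports window-resolution (0.5 s) onsets; the false-positive rate on
background-plus-spindle stretches is not part of the acceptance contract
and varies with training set size. The comparative kernel study
(Born-Jordan, Choi-Williams, ZAM, spectrogram) is provided for analysis;
reassignment and recursion are implemented for the separable
Wigner-Ville family, which is the configuration the detector uses.
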