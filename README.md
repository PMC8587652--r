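# kcdetect

Detection of **K-complexes** in single-channel sleep EEG via reassigned
Cohen-class time-frequency analysis and a small from-scratch neural
classifier.

The K-complex is the hallmark transient of stage-2 sleep: a sharp negative
deflection below -100 uV, a slower positive lobe at 350-550 ms, the whole
event over in about 900 ms, recurring every 1.0-1.7 minutes and often
trailed by a sleep spindle. Detecting them automatically matters for sleep
staging, sleep-disorder screening and biomarker research, and is hard
because delta-band background (1.6-4 Hz) mimics the waveform. This package
is for signal-processing and sleep-EEG researchers who want a fully
testable, dependency-light implementation of the time-frequency route to
that problem.

## What is inside

* **Cohen-class distributions** (`pseudo_wvd`, `smoothed_pwvd`,
  `cohen_distribution`, `stft_spectrogram`): discrete
  `C[n,k] = sum_{l,m} G[m,l] R_x[n+m,l] e^{-j 2 pi k l / Nf}` over the
  instantaneous autocorrelation `R_x[n,l] = x[n+l] x*[n-l]`, with
  Wigner-Ville, Born-Jordan, Choi-Williams, Zhao-Atlas-Marks and
  spectrogram kernels, frequency bins `v_k = k/(2 Nf)` on `[0, 0.5)`.
* **Reassignment** (`reassigned_spwvd`): each cell moves to its local
  centre of gravity, computed from the time-weighted kernel `m g[l] h[m]`
  and the lag-derivative kernel `g'[l] h[m]`:
  `n_hat = n + Re(C_T/C)`, `v_hat = v + asin(-Im(C_D/C))/(4 pi)`.
  Conserves the signed total exactly; concentrates a tone into a single
  frequency row.
* **Streaming recursion** (`recursive_spwvd_stream`,
  `recursive_modified_stream`): for time windows decomposable into
  exponentials (rectangular, exponential with forgetting factor `alpha`,
  half-sine, Hamming, Hanning, Blackman), the smoothed distribution
  updates per time step from two autocorrelation columns only --
  `S[n] = a S[n-1] + c a^{-M} R[n+M] - c a^{M+1} R[n-M-1]` -- so the cost
  per step is independent of the smoothing half-length `M`. Instrumented
  counters verify the claim, and the reallocation operators cost two
  divisions and two additions per frequency bin.
* **Synthetic stage-2 EEG** (`synth_record`, `make_dataset`): annotated
  K-complexes, spindles, delta background, 0.8 Hz slow wave, 50 Hz mains;
  bit-reproducible under a seed. EDF and CSV I/O included.
* **Preprocessing** (`notch50`, `analytic`, `segment_record`): biquad IIR
  notch (>= 40 dB at 50 Hz, <= 0.5 dB at 10 Hz), FFT Hilbert analytic
  signal, overlap-labeled sliding windows.
* **Classifier** (`init_mlp`, `mlp_train`, `mlp_evaluate`): from-scratch
  MLP with arctan/tanh/sigmoid activations, softmax head, binary
  cross-entropy, batch-1 SGD, architecture sweep helpers
  (`sweep_architectures`).
* **Pipeline** (`run_detection`, `score_events`): record in, scored
  K-complex events out, with event-level precision/recall/F1.

A thin command-line front end lives at `inst/cli/kcdetect.R`
(`synth`, `tfr`, `train`, `detect`, `eval` subcommands).

## Worked example

Train a detector on synthetic stage-2 sleep and run it on a fresh
recording:

```r
library(kcdetect)

cfg <- synth_config(duration_s = 6500)
ds  <- make_dataset(cfg, n_segments = 120, pos_fraction = 0.5, seed = 19)
dcfg <- detect_config()
X <- segment_features(ds, dcfg)                  # 120 x 259 features
model <- init_mlp(c(ncol(X), 8, 8, 2), "arctan", seed = 1)
fit <- mlp_train(model, X, ds$y, X, ds$y,
                 train_config(lr = 1e-2, epochs = 60, batch = 1, seed = 1))

rec <- synth_record(synth_config(duration_s = 240, seed = 31))  # 3 K-complexes
res <- run_detection(rec$signal, fit$model, detect_config(threshold = 0.99))
res$events
#>   onset_s duration_s     score
#> 1    89.5        3.5 0.9996958
#> 2   154.5        3.0 0.9996280
#> 3   237.5        2.0 0.9986524

s <- score_events(res$events, rec$events, tol_s = 1.0)
sprintf("recall %.2f, precision %.2f", s$recall, s$precision)
#> [1] "recall 1.00, precision 1.00"
```

The three detected spans cover the three planted K-complexes (true onsets
91.2 s, 155.7 s, 239.0 s; detections are reported at window resolution, so
each true event centre falls inside a detected span). At the default
threshold 0.5 the same model still recovers all three events but admits
background false positives (precision 0.25 on this record); the score
separation (true events > 0.998) is what the higher threshold exploits.

## Acceptance script

`scripts/acceptance.R` recomputes the package's measurable claims from a
fresh run of the installed package: the instrumented per-bin operation
counts of the reallocation-operator evaluation (maximum over N = 16, 64,
256 frequency bins) and the mean K-complex inter-onset interval of a
2-hour default synthetic recording. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/kcomplex-detection.Rmd`) documents the
discrete conventions, the derivation and validation of the streaming
recursions, the reassignment calibration, what the synthetic generator
does and does not emulate, and the training-protocol analysis on the
synthetic benchmark.
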