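#' Detection pipeline configuration
#'
#' Bundles the stages of the end-to-end detector: notch filtering,
#' segmentation, the reassigned smoothed-pseudo Wigner-Ville transform of
#' each segment, feature extraction, and probability thresholding with
#' merging of adjacent detections.
#'
#' @param win_s,hop_s segmentation window and hop (s).
#' @param lag_half,time_half half-lengths of the Hamming lag and time
#'   smoothing windows.
#' @param Nf frequency bins of the segment transform.
#' @param threshold detection threshold on the positive-class probability.
#' @param merge_gap_s adjacent above-threshold windows closer than this gap
#'   are merged into one event.
#' @param notch apply the 50 Hz notch before analysis.
#' @param fspec a [feature_spec()].
#' @return list of class `detect_config`.
#' @export
detect_config <- function(win_s = 2.0, hop_s = 0.5, lag_half = 24L,
                          time_half = 12L, Nf = 64L, threshold = 0.5,
                          merge_gap_s = 0.25, notch = TRUE,
                          fspec = feature_spec()) {
  structure(list(win_s = win_s, hop_s = hop_s, lag_half = as.integer(lag_half),
                 time_half = as.integer(time_half), Nf = as.integer(Nf),
                 threshold = threshold, merge_gap_s = merge_gap_s,
                 notch = isTRUE(notch), fspec = fspec),
            class = "detect_config")
}

#' Features for every segment of a dataset
#'
#' For each waveform row: analytic signal, reassigned smoothed-pseudo
#' Wigner-Ville distribution (Hamming lag/time windows per `cfg`), then
#' [tfr_features()].
#'
#' @param dataset a `segment_dataset` (waveform rows).
#' @param cfg a [detect_config()].
#' @return numeric matrix, one feature row per segment.
#' @export
segment_features <- function(dataset, cfg = detect_config()) {
  g <- make_window("hamming", cfg$lag_half)
  h <- make_window("hamming", cfg$time_half)
  n <- nrow(dataset$X)
  out <- matrix(NA_real_, n, n_features(cfg$fspec))
  for (i in seq_len(n)) {
    s <- analytic(eeg_signal(dataset$X[i, ], dataset$fs))
    grid <- reassigned_spwvd(s, g, h, cfg$Nf)
    out[i, ] <- tfr_features(grid, cfg$fspec, fs = dataset$fs)
  }
  out
}

#' Run K-complex detection on a recording
#'
#' Notch-filters (optionally), segments the record, transforms and
#' featurizes every window, applies the classifier, and merges adjacent
#' above-threshold windows into detected events. Deterministic given its
#' inputs.
#'
#' @param record real [eeg_signal()].
#' @param model trained [init_mlp()] model.
#' @param cfg a [detect_config()]; feature length must match the model input.
#' @return `detection_result`: list with `windows` (start_s, prob), `events`
#'   (onset_s, duration_s, score), `threshold`.
#' @export
run_detection <- function(record, model, cfg = detect_config()) {
  record <- as_signal(record)
  if (cfg$notch) record <- notch50(record)
  ds <- segment_record(record, event_list(), win_s = cfg$win_s,
                       hop_s = cfg$hop_s)
  if (nrow(ds$X) == 0L) {
    return(structure(list(windows = data.frame(start_s = numeric(0),
                                               prob = numeric(0)),
                          events = data.frame(onset_s = numeric(0),
                                              duration_s = numeric(0),
                                              score = numeric(0)),
                          threshold = cfg$threshold),
                     class = "detection_result"))
  }
  X <- segment_features(ds, cfg)
  if (ncol(X) != model$layer_sizes[1]) {
    stop("feature length does not match the model input size; ",
         "was the model trained with a different configuration?")
  }
  prob <- mlp_forward(model, X)[, 2L]
  # windows with no signal at all cannot contain an event
  flat <- apply(ds$X, 1L, function(w) max(abs(w)) == 0)
  prob[flat] <- 0
  starts <- ds$meta$start_s
  hit <- prob > cfg$threshold
  events <- merge_detections(starts, prob, hit, cfg$win_s, cfg$merge_gap_s)
  structure(list(windows = data.frame(start_s = starts, prob = prob),
                 events = events, threshold = cfg$threshold),
            class = "detection_result")
}

# merge runs of adjacent positive windows into non-overlapping events
merge_detections <- function(starts, prob, hit, win_s, merge_gap_s) {
  if (!any(hit)) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      score = numeric(0)))
  }
  s <- starts[hit]; p <- prob[hit]
  brk <- c(TRUE, diff(s) > win_s + merge_gap_s)
  grp <- cumsum(brk)
  onset <- tapply(s, grp, min)
  end <- tapply(s, grp, max) + win_s
  score <- tapply(p, grp, max)
  data.frame(onset_s = as.numeric(onset),
             duration_s = as.numeric(end - onset),
             score = as.numeric(score))
}

#' Event-level scoring
#'
#' Greedy one-to-one matching of predicted to true events by event-centre
#' distance (closest pairs first) within a tolerance. Centres are
#' `onset_s + duration_s / 2` when a duration column is present and the bare
#' onset otherwise; centre matching is robust to the onset bias that merged
#' multi-window detections carry. Precision is reported as 0 with the
#' `precision_undefined` flag when there are no predictions.
#'
#' @param pred,truth event tables with `onset_s` (and optionally
#'   `duration_s`); `truth` is filtered to `kcomplex` rows when a `label`
#'   column is present.
#' @param tol_s centre matching tolerance in seconds.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `precision_undefined`.
#' @export
score_events <- function(pred, truth, tol_s = 0.5) {
  if (!is.null(truth$label)) {
    truth <- truth[truth$label == "kcomplex", , drop = FALSE]
  }
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nt, precision = 0, recall = 0,
                f1 = 0, precision_undefined = TRUE))
  }
  if (nt == 0L) {
    return(list(tp = 0L, fp = np, fn = 0L, precision = 0, recall = 0,
                f1 = 0, precision_undefined = FALSE))
  }
  centre <- function(df) {
    if (!is.null(df$duration_s)) df$onset_s + df$duration_s / 2 else df$onset_s
  }
  d <- abs(outer(centre(pred), centre(truth), "-"))
  used_p <- logical(np); used_t <- logical(nt); tp <- 0L
  repeat {
    d_open <- d
    d_open[used_p, ] <- Inf; d_open[, used_t] <- Inf
    best <- which.min(d_open)
    if (!length(best) || d_open[best] > tol_s) break
    i <- (best - 1L) %% np + 1L
    j <- (best - 1L) %/% np + 1L
    used_p[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
  }
  fp <- np - tp; fn <- nt - tp
  prec <- tp / np; rec <- tp / nt
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1,
       precision_undefined = FALSE)
}

#' Architecture sweep
#'
#' Trains one model per (hidden-layer count, neurons-per-layer, activation)
#' combination and reports per-configuration train/test cost and accuracy,
#' mirroring a layers x neurons x activation grid protocol.
#'
#' @param X_train,y_train,X_test,y_test feature matrices and labels.
#' @param layers integer vector of hidden-layer counts.
#' @param neurons integer vector of neurons per hidden layer.
#' @param activations character vector of activations.
#' @param cfg a [train_config()] applied to every run.
#' @param seed model-initialization seed.
#' @return data frame with one row per configuration: activation, layers,
#'   neurons, train/test cost and accuracy at the selected epoch.
#' @export
sweep_architectures <- function(X_train, y_train, X_test, y_test,
                                layers = 1:7,
                                neurons = c(8L, 16L, 32L, 64L, 128L, 256L),
                                activations = c("tanh", "sigmoid", "arctan"),
                                cfg = train_config(), seed = 1L) {
  grid <- expand.grid(activation = activations, layers = layers,
                      neurons = neurons, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    gi <- grid[i, ]
    sizes <- c(ncol(X_train), rep(gi$neurons, gi$layers), 2L)
    model <- init_mlp(sizes, gi$activation, seed = seed)
    tr <- mlp_train(model, X_train, y_train, X_test, y_test, cfg)
    sel <- if (tr$selected_epoch > 0) tr$selected_epoch else nrow(tr$history)
    data.frame(activation = gi$activation, layers = gi$layers,
               neurons = gi$neurons,
               train_cost = tr$history$train_cost[sel],
               train_acc = tr$history$train_acc[sel],
               test_cost = tr$history$test_cost[sel],
               test_acc = tr$history$test_acc[sel])
  })
  do.call(rbind, res)
}

#' Best sweep configuration
#' @param sweep_table output of [sweep_architectures()].
#' @return the row with the minimal test cost.
#' @export
best_of_sweep <- function(sweep_table) {
  sweep_table[which.min(sweep_table$test_cost), , drop = FALSE]
}
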