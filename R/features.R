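#' Feature extraction specification
#'
#' Maps a segment's time-frequency distribution to a fixed-length vector:
#' the magnitude grid is bilinearly resampled to a small patch (so the MLP
#' input stays compact while the time-frequency signature of the event is
#' preserved), optionally log-compressed and z-scored, and concatenated with
#' per-band energy fractions. Defaults: 16 x 16 patch, log1p compression and
#' per-segment z-score ON (the bounded S-shaped activations downstream
#' saturate on raw microvolt-squared magnitudes), and the three bands that
#' discriminate K-complexes from spindles and background: delta 0.5-4 Hz,
#' theta 4-8 Hz, sigma (spindle) 11-16 Hz.
#'
#' @param patch_shape integer length-2: patch rows (time) and columns
#'   (frequency), each >= 2.
#' @param compression apply `log1p` to the magnitude patch.
#' @param normalize z-score the patch per segment.
#' @param band_edges_Hz named list of `c(lo, hi)` band edges in Hz.
#' @return list of class `feature_spec`.
#' @export
feature_spec <- function(patch_shape = c(16L, 16L), compression = TRUE,
                         normalize = TRUE,
                         band_edges_Hz = list(delta = c(0.5, 4),
                                              theta = c(4, 8),
                                              sigma = c(11, 16))) {
  stopifnot(length(patch_shape) == 2L, all(patch_shape >= 2L))
  structure(list(patch_shape = as.integer(patch_shape),
                 compression = isTRUE(compression),
                 normalize = isTRUE(normalize),
                 band_edges_Hz = band_edges_Hz),
            class = "feature_spec")
}

#' Number of features produced by a [feature_spec()]
#' @param spec a [feature_spec()].
#' @return integer: patch area + number of bands.
#' @export
n_features <- function(spec) {
  prod(spec$patch_shape) + length(spec$band_edges_Hz)
}

# separable bilinear resample of a matrix to (p, q)
bilinear_resample <- function(m, p, q) {
  interp_axis <- function(mat, nout) {
    nin <- nrow(mat)
    if (nin == nout) return(mat)
    xi <- seq(1, nin, length.out = nout)
    apply(mat, 2L, function(col) {
      stats::approx(seq_len(nin), col, xout = xi, rule = 2)$y
    })
  }
  m <- interp_axis(m, p)
  t(interp_axis(t(m), q))
}

#' Time-frequency features for the classifier
#'
#' @param grid a [tfr_grid()] (any kernel; magnitudes are used).
#' @param spec a [feature_spec()].
#' @param fs sampling rate in Hz; defaults to the grid's `fs` and is needed
#'   to map the normalized frequency axis to the band edges.
#' @return numeric feature vector of length [n_features()]: the flattened
#'   (column-major) patch followed by the band energy fractions. All values
#'   finite; an all-zero grid yields the zero vector.
#' @export
tfr_features <- function(grid, spec = feature_spec(), fs = grid$fs) {
  stopifnot(inherits(grid, "tfr_grid"), inherits(spec, "feature_spec"))
  if (is.na(fs)) stop("fs needed to place the band edges")
  P <- abs(grid$values)
  patch <- bilinear_resample(P, spec$patch_shape[1], spec$patch_shape[2])
  if (spec$compression) patch <- log1p(patch)
  if (spec$normalize) {
    s <- stats::sd(patch)
    patch <- if (s > 0) (patch - mean(patch)) / s else patch * 0
  }
  f_Hz <- grid$freq_axis * fs
  total <- sum(P)
  bands <- vapply(spec$band_edges_Hz, function(be) {
    sel <- f_Hz >= be[1] & f_Hz < be[2]
    if (total > 0) sum(P[, sel, drop = FALSE]) / total else 0
  }, numeric(1))
  out <- unname(c(as.vector(patch), bands))
  stopifnot(all(is.finite(out)))
  out
}
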