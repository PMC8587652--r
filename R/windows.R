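#' Analysis windows for time-frequency distributions
#'
#' Builds the symmetric window families used as lag windows `g` and time
#' (smoothing) windows `h`. Coefficients are indexed on `m = -M..M` where `M`
#' is the half-length ("semilength"), so the full length is `2*M + 1`.
#' Closed forms (for `M > 0`):
#' \describe{
#'   \item{rectangular}{1}
#'   \item{hamming}{0.54 + 0.46 cos(pi m / M)}
#'   \item{hanning}{0.5 + 0.5 cos(pi m / M)}
#'   \item{blackman}{0.42 + 0.5 cos(pi m / M) + 0.08 cos(2 pi m / M)}
#'   \item{bartlett}{1 - |m| / M}
#'   \item{half_sine}{cos(pi m / (2 M))}
#'   \item{exponential}{alpha^(-m), the one-pole "forgetting" window}
#' }
#' Cosine-family and exponential windows decompose exactly into complex
#' exponential terms `h[m] = sum_k c_k * a_k^(-m)`; the decomposition (stored
#' in `$exp_terms`) is what makes first-order recursive streaming possible.
#'
#' @param name one of `"rectangular"`, `"hamming"`, `"hanning"`,
#'   `"blackman"`, `"bartlett"`, `"half_sine"`, `"exponential"`.
#' @param half_length half-length `M >= 0`.
#' @param alpha forgetting factor for the exponential window (default 0.94).
#' @return object of class `tfr_window`: list with `name`, `half_length`,
#'   `coef` (length `2*half_length + 1`), `alpha`, and `exp_terms` (`NULL`
#'   for families with no exact exponential decomposition).
#' @examples
#' w <- make_window("hamming", 32)
#' w$coef[1]  # endpoint: 0.54 - 0.46
#' @export
make_window <- function(name, half_length, alpha = 0.94) {
  name <- match.arg(name, c("rectangular", "hamming", "hanning", "blackman",
                            "bartlett", "half_sine", "exponential"))
  M <- as.integer(half_length)
  if (M < 0L) stop("half_length must be >= 0")
  m <- seq.int(-M, M)
  if (M == 0L) {
    coef <- 1
    terms <- list(list(c = 1 + 0i, a = 1 + 0i))
  } else {
    coef <- switch(name,
      rectangular = rep(1, 2L * M + 1L),
      hamming     = 0.54 + 0.46 * cos(pi * m / M),
      hanning     = 0.50 + 0.50 * cos(pi * m / M),
      blackman    = 0.42 + 0.50 * cos(pi * m / M) + 0.08 * cos(2 * pi * m / M),
      bartlett    = 1 - abs(m) / M,
      half_sine   = cos(pi * m / (2 * M)),
      exponential = alpha^(-m))
    terms <- window_exp_terms(name, M, alpha)
  }
  structure(list(name = name, half_length = M, coef = coef,
                 alpha = if (name == "exponential") alpha else NA_real_,
                 exp_terms = terms),
            class = "tfr_window")
}

# Exact decomposition h[m] = sum_k c_k a_k^(-m) on [-M, M].
# cos(j pi m / M) = 0.5 (e^{i j pi/M})^m + 0.5 (e^{-i j pi/M})^m and
# (e^{i t})^m = (e^{-i t})^(-m), so a cosine of index j contributes the
# conjugate pair a = e^{-+ i j pi / M}.
window_exp_terms <- function(name, M, alpha) {
  pair <- function(amp, j, per = M) {
    list(list(c = amp + 0i, a = exp(-1i * j * pi / per)),
         list(c = amp + 0i, a = exp(+1i * j * pi / per)))
  }
  switch(name,
    rectangular = list(list(c = 1 + 0i, a = 1 + 0i)),
    exponential = list(list(c = 1 + 0i, a = alpha + 0i)),
    hanning     = c(list(list(c = 0.50 + 0i, a = 1 + 0i)), pair(0.25, 1)),
    hamming     = c(list(list(c = 0.54 + 0i, a = 1 + 0i)), pair(0.23, 1)),
    blackman    = c(list(list(c = 0.42 + 0i, a = 1 + 0i)), pair(0.25, 1),
                    pair(0.04, 2)),
    half_sine   = pair(0.5, 1, per = 2 * M),
    bartlett    = NULL)
}

#' @export
print.tfr_window <- function(x, ...) {
  cat(sprintf("<tfr_window> %s, half-length %d (%d coefficients)%s\n",
              x$name, x$half_length, length(x$coef),
              if (!is.null(x$exp_terms))
                sprintf(", %d exponential term(s)", length(x$exp_terms))
              else ""))
  invisible(x)
}

#' Derivative window
#'
#' Discrete per-sample derivative of a window, used to build the
#' lag-derivative kernel that feeds the frequency reassignment operator.
#' Central differences of the zero-padded coefficients are used for every
#' family: by the shift theorem they satisfy the *exact* discrete
#' integration-by-parts identity
#' `sum_l w'[l] z^l = (z^{-1} - z)/2 * sum_l w[l] z^l`, i.e. the derivative
#' window's transform is `-j sin(4 pi v) ` times the window's transform under
#' the `e^{-j 4 pi v l}` convention. Ratios of the two transforms are
#' therefore finite everywhere (kernel zeros cancel), which is what makes the
#' frequency reassignment operator well behaved; a sampled analytic
#' derivative does not have this property. For the rectangular window this
#' leaves zeros in the interior with boundary impulses of height -+1/2.
#'
#' @param window a [make_window()] object.
#' @return numeric vector of `2*(half_length + 1) + 1` derivative
#'   coefficients on the extended support `[-(M+1), M+1]`: the one-sample
#'   overhang carries the boundary mass of windows that do not vanish at
#'   their endpoints, and is required for the exact shift-theorem identity.
#' @export
window_derivative <- function(window) {
  stopifnot(inherits(window, "tfr_window"))
  central_diff(c(0, window$coef, 0))
}

central_diff <- function(v) {
  n <- length(v)
  padded <- c(0, v, 0)
  (padded[3:(n + 2)] - padded[1:n]) / 2
}

# Reconstruct window coefficients from the exponential decomposition;
# used by the recursion-state invariant check.
reconstruct_from_terms <- function(terms, M) {
  m <- seq.int(-M, M)
  out <- rep(0 + 0i, length(m))
  for (t in terms) out <- out + t$c * t$a^(-m)
  out
}

window_is_hermitian <- function(window, tol = 1e-12) {
  co <- window$coef
  all(abs(co - rev(co)) <= tol) && all(abs(Im(co)) <= tol)
}
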