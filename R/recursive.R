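#' Streaming recursion state
#'
#' Validates that a time window `h` admits first-order recursive streaming
#' and packages the per-term constants. A window is admissible when it is an
#' exact sum of exponential components `h[m] = sum_k c_k a_k^(-m)` on
#' `[-M, M]`: the rectangular window (one term, `a = 1`), the one-pole
#' exponential window (forgetting factor `alpha`), and the cosine families
#' (half-sine, Hamming, Hanning, Blackman) via conjugate exponential pairs.
#' Each component runs its own complex first-order recursion; the streams
#' are summed by linearity of the lag transform.
#'
#' @param g lag window, `h` time window ([make_window()]).
#' @param Nf number of frequency bins.
#' @return list of class `recursion_state` with per-term constants and
#'   per-lag accumulators.
#' @export
recursion_state <- function(g, h, Nf) {
  if (is.null(h$exp_terms)) {
    stop("time window '", h$name, "' has no exact exponential decomposition; ",
         "admissible families: rectangular, exponential, half_sine, ",
         "hamming, hanning, blackman")
  }
  M <- h$half_length; L <- g$half_length
  recon <- reconstruct_from_terms(h$exp_terms, M)
  if (max(abs(recon - h$coef)) > 1e-12 * max(1, max(abs(h$coef)))) {
    stop("exponential decomposition does not reconstruct the window")
  }
  nl <- 2L * L + 1L
  terms <- lapply(h$exp_terms, function(t) {
    list(a = t$a,
         cpM = t$c * t$a^(-M),         # weight of the entering sample
         cmM = t$c * t$a^(M + 1),      # weight of the leaving sample
         A = rep(0 + 0i, nl),          # plain accumulator  S[n, l]
         B = rep(0 + 0i, nl))          # time-weighted accumulator T[n, l]
  })
  structure(list(terms = terms, M = M, L = L, Nf = Nf,
                 g = g, gd = window_derivative(g),
                 alpha = if (h$name == "exponential") h$alpha else NA_real_,
                 h_name = h$name),
            class = "recursion_state")
}

# Core streaming engine. Per emitted time step n the per-lag accumulators
# are updated from the two boundary columns of the instantaneous
# autocorrelation only:
#   S[n,l] = a S[n-1,l] + c a^-M R[n+M,l] - c a^(M+1) R[n-M-1,l]
#   T[n,l] = a T[n-1,l] - S[n,l] + (M+1) c a^-M R[n+M,l]
#                                +  M    c a^(M+1) R[n-M-1,l]
# (one such pair per exponential component of h), so the per-step cost is
# independent of M. The lag transform of g*S, g*T and g'*S then yields the
# plain, T- and D-modified smoothed-pseudo WVD rows.
recursive_streams <- function(x, g, h, Nf, want = c("none", "T", "D"),
                              count_ops = FALSE) {
  x <- as_signal(x)
  check_analytic_input(x)
  state <- recursion_state(g, h, Nf)
  M <- state$M
  # run all streams on the lag support extended by one sample so the
  # derivative lag window (which overhangs by one) applies to the same
  # accumulators; the plain window is zero-padded there
  L <- state$L + 1L
  gplain <- c(0, state$g$coef, 0)
  xs <- as.complex(x$samples)
  N <- length(xs)
  lags <- seq.int(-L, L)
  nl <- length(lags)
  need_B <- "T" %in% want

  rcol <- function(np) {
    # column R[np, l] over l = -L..L, zero outside support
    if (np < 0L || np > N - 1L + L) return(rep(0 + 0i, nl))
    ip <- np + lags; im <- np - lags
    ok <- ip >= 0L & ip < N & im >= 0L & im < N
    out <- rep(0 + 0i, nl)
    out[ok] <- xs[ip[ok] + 1L] * Conj(xs[im[ok] + 1L])
    out
  }

  Amat <- matrix(0 + 0i, nl, N)
  Bmat <- if (need_B) matrix(0 + 0i, nl, N) else NULL
  adds <- 0; mults <- 0; steps <- 0L
  terms <- lapply(state$terms, function(tk) {
    tk$A <- rep(0 + 0i, nl); tk$B <- rep(0 + 0i, nl); tk
  })
  for (n in seq.int(-M, N - 1L)) {
    Rp <- rcol(n + M)
    Rm <- rcol(n - M - 1L)
    for (k in seq_along(terms)) {
      tk <- terms[[k]]
      Anew <- tk$a * tk$A + tk$cpM * Rp - tk$cmM * Rm
      if (need_B) {
        terms[[k]]$B <- tk$a * tk$B - Anew +
          ((M + 1) * tk$cpM) * Rp + (M * tk$cmM) * Rm
      }
      terms[[k]]$A <- Anew
      if (count_ops && n >= 0L) {
        mults <- mults + 3 * nl + if (need_B) 3 * nl else 0
        adds <- adds + 2 * nl + if (need_B) 3 * nl else 0
      }
    }
    if (n >= 0L) {
      steps <- steps + 1L
      acolA <- terms[[1L]]$A
      if (length(terms) > 1L) {
        for (k in seq.int(2L, length(terms))) acolA <- acolA + terms[[k]]$A
      }
      Amat[, n + 1L] <- acolA
      if (need_B) {
        acolB <- terms[[1L]]$B
        if (length(terms) > 1L) {
          for (k in seq.int(2L, length(terms))) acolB <- acolB + terms[[k]]$B
        }
        Bmat[, n + 1L] <- acolB
      }
    }
  }

  n_axis <- seq.int(0L, N - 1L)
  kern <- function(mod) list(id = "wigner_ville", modified = mod,
                             g = g$name, h = h$name, L = L, M = M,
                             mode = "recursive")
  out <- list()
  if ("none" %in% want) {
    out$none <- tfr_grid(Re(t(lag_dft(Amat * gplain, L, Nf))),
                         n_axis, freq_axis_of(Nf), kern("none"), x$fs)
  }
  if ("T" %in% want) {
    out$T <- tfr_grid(Re(t(lag_dft(Bmat * gplain, L, Nf))),
                      n_axis, freq_axis_of(Nf), kern("T"), x$fs)
  }
  if ("D" %in% want) {
    out$D <- tfr_grid(t(lag_dft(Amat * state$gd, L, Nf)),
                      n_axis, freq_axis_of(Nf), kern("D"), x$fs)
  }
  if (count_ops) {
    attr(out, "op_counts") <- list(additions = adds, multiplications = mults,
                                   steps = steps,
                                   additions_per_step = adds / steps,
                                   multiplications_per_step = mults / steps)
  }
  out
}

#' Recursive (streaming) smoothed-pseudo Wigner-Ville distribution
#'
#' Evaluates the smoothed-pseudo WVD with a first-order recursion in time:
#' each step touches only the entering column `R[n + M, l]` and the leaving
#' column `R[n - M - 1, l]` of the instantaneous autocorrelation, so the
#' per-step cost does not grow with the time-smoothing half-length `M`.
#' Requires a time window with an exact exponential decomposition (see
#' [recursion_state()]). Output equals [smoothed_pwvd()] up to rounding.
#'
#' @param x [eeg_signal()], preferably analytic.
#' @param g lag window, `h` admissible time window.
#' @param Nf number of frequency bins.
#' @param count_ops attach instrumented per-step operation counts as the
#'   `op_counts` attribute.
#' @return [tfr_grid()].
#' @export
recursive_spwvd_stream <- function(x, g, h, Nf, count_ops = FALSE) {
  st <- recursive_streams(x, g, h, Nf, want = "none", count_ops = count_ops)
  out <- st$none
  if (count_ops) attr(out, "op_counts") <- attr(st, "op_counts")
  out
}

#' Recursive evaluation of the modified (T / D) streams
#'
#' Streaming evaluation of the time-weighted (`which = "T"`) or
#' lag-derivative (`which = "D"`) modified smoothed-pseudo WVD. The T stream
#' couples to the plain stream through the recursion; the D stream reuses the
#' plain per-lag accumulators under the derivative lag window. Equals the
#' corresponding direct [smoothed_pwvd()] evaluation up to rounding.
#'
#' @param x [eeg_signal()], preferably analytic.
#' @param g lag window, `h` admissible time window.
#' @param Nf number of frequency bins.
#' @param which `"T"` or `"D"`.
#' @param count_ops attach instrumented op counts.
#' @return [tfr_grid()].
#' @export
recursive_modified_stream <- function(x, g, h, Nf, which = c("T", "D"),
                                      count_ops = FALSE) {
  which <- match.arg(which)
  st <- recursive_streams(x, g, h, Nf, want = which, count_ops = count_ops)
  out <- st[[which]]
  if (count_ops) attr(out, "op_counts") <- attr(st, "op_counts")
  out
}
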