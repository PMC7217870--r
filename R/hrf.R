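#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma shape: a positive lobe peaking near 5 s minus an
#' undershoot near 15-16 s scaled by 1/6, normalized to unit peak. Sampled on
#' a fine grid of \code{tr / oversampling} seconds for oversampled
#' convolution.
#'
#' @param tr repetition time in seconds.
#' @param oversampling fine-grid samples per TR (default 16).
#' @param duration kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds, with
#'   unit dispersion).
#' @param undershoot_ratio positive-lobe to undershoot amplitude ratio.
#' @return numeric kernel sampled at \code{tr / oversampling}; attributes
#'   \code{dt} and \code{times}.
#' @export
canonical_hrf <- function(tr, oversampling = 16L, duration = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 6) {
  stop_if_not(tr > 0, "tr must be positive")
  dt <- tr / oversampling
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = peak_delay, rate = 1) -
    dgamma(t, shape = undershoot_delay, rate = 1) / undershoot_ratio
  h <- h / max(h)
  attr(h, "dt") <- dt
  attr(h, "times") <- t
  h
}

#' Convolve events with the canonical HRF and sample at volume times
#'
#' Events are laid down as amplitude-weighted boxcars on a fine grid
#' (\code{tr / oversampling}), convolved with the double-gamma kernel, and
#' sampled at acquisition times \code{0, tr, 2 tr, ...}.
#'
#' @param onsets event onsets in seconds.
#' @param durations event durations in seconds (scalar or per event).
#' @param amplitudes event amplitudes (scalar or per event; e.g. a
#'   parametric-modulator value).
#' @param n_volumes number of volumes.
#' @param tr repetition time (seconds).
#' @param oversampling fine-grid factor.
#' @return numeric vector of length \code{n_volumes}.
#' @export
convolve_events <- function(onsets, durations, amplitudes = 1, n_volumes, tr,
                            oversampling = 16L) {
  ev <- list(list(onsets = onsets, durations = durations, amplitudes = amplitudes))
  drop(convolve_event_columns(ev, n_volumes, tr, oversampling))
}

# kernel cache: the double-gamma shape is fixed, only (tr, oversampling) vary
.hrf_cache <- new.env(parent = emptyenv())

cached_hrf <- function(tr, oversampling) {
  key <- paste(tr, oversampling)
  if (is.null(.hrf_cache[[key]]))
    .hrf_cache[[key]] <- canonical_hrf(tr, oversampling)
  .hrf_cache[[key]]
}

# batch convolution: one column per event set, convolved jointly via mvfft
convolve_event_columns <- function(event_sets, n_volumes, tr, oversampling = 16L) {
  h <- cached_hrf(tr, oversampling)
  dt <- attr(h, "dt")
  n_fine <- n_volumes * oversampling + length(h)
  nf <- stats::nextn(n_fine + length(h), 2)
  X <- matrix(0, nf, length(event_sets))
  for (j in seq_along(event_sets)) {
    es <- event_sets[[j]]
    durations <- rep_len(es$durations, length(es$onsets))
    amplitudes <- rep_len(es$amplitudes %||% 1, length(es$onsets))
    for (k in seq_along(es$onsets)) {
      i0 <- floor(es$onsets[k] / dt) + 1L
      # events shorter than one fine bin still occupy one (impulse semantics)
      i1 <- min(n_fine, max(i0, floor((es$onsets[k] + durations[k]) / dt)))
      if (i0 <= n_fine)
        X[i0:i1, j] <- X[i0:i1, j] + amplitudes[k]
    }
  }
  H <- fft(c(h, numeric(nf - length(h))))
  Y <- Re(mvfft(mvfft(X) * H, inverse = TRUE)) / nf
  Y[(seq_len(n_volumes) - 1L) * oversampling + 1L, , drop = FALSE]
}
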