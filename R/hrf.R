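# Canonical haemodynamic response function and event convolution.

.hrf_peak_cache <- new.env(parent = emptyenv())

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with modes at `peak_delay` (response,
#' 6 s) and `undershoot_delay` (undershoot, 16 s) and a peak-to-undershoot
#' ratio of `ratio`, normalized to unit peak amplitude. Zero for t < 0.
#'
#' @param t time in seconds (vector).
#' @param peak_delay response peak time in seconds.
#' @param undershoot_delay undershoot peak time in seconds.
#' @param ratio peak/undershoot amplitude ratio.
#' @return HRF amplitude at `t` (unit peak).
#' @export
hrf <- function(t, peak_delay = 6, undershoot_delay = 16, ratio = 6) {
  raw <- function(tt) {
    out <- numeric(length(tt))
    ok <- tt >= 0
    out[ok] <- stats::dgamma(tt[ok], shape = peak_delay + 1, rate = 1) -
      stats::dgamma(tt[ok], shape = undershoot_delay + 1, rate = 1) / ratio
    out
  }
  key <- paste(peak_delay, undershoot_delay, ratio)
  peak <- .hrf_peak_cache[[key]]
  if (is.null(peak)) {
    peak <- max(raw(seq(0, undershoot_delay + 16, by = 0.01)))
    .hrf_peak_cache[[key]] <- peak
  }
  raw(t) / peak
}

# Fine-grid boxcar matrix (one column per event row). Zero-duration
# events become unit-area impulses.
fine_boxcars <- function(events, n_fine, dt) {
  X <- matrix(0, n_fine, nrow(events))
  amp <- events$amplitude %||% rep(1, nrow(events))
  for (k in seq_len(nrow(events))) {
    i0 <- floor(events$onset[k] / dt) + 1L
    if (i0 > n_fine) next
    if (events$duration[k] < dt) {
      X[i0, k] <- X[i0, k] + amp[k] / dt
    } else {
      i1 <- min(n_fine, floor((events$onset[k] + events$duration[k]) / dt))
      X[i0:i1, k] <- X[i0:i1, k] + amp[k]
    }
  }
  X
}

# Convolve fine-grid columns with the HRF (batched FFT, power-of-2
# padding) and sample at the acquisition grid.
conv_hrf_sample <- function(Xfine, tr, n_timepoints, dt) {
  n_fine <- nrow(Xfine)
  h <- hrf(seq(0, 32, by = dt))
  L <- stats::nextn(n_fine + length(h) - 1L, 2)
  H <- stats::fft(c(h, numeric(L - length(h))))
  Xp <- rbind(Xfine, matrix(0, L - n_fine, ncol(Xfine)))
  conv <- Re(stats::mvfft(stats::mvfft(Xp) * H, inverse = TRUE)) / L * dt
  idx <- pmin(n_fine, round((seq_len(n_timepoints) - 1L) * tr / dt) + 1L)
  conv[idx, , drop = FALSE]
}

#' Convolve events with the canonical HRF
#'
#' Each event is a boxcar of its duration (a delta "of width equal to the
#' event duration"); zero-duration events are unit-area impulses. The
#' boxcar train is convolved with [hrf()] on a fine time grid and sampled
#' at the acquisition times `(0, tr, 2 tr, ...)`.
#'
#' @param events data.frame with columns `onset`, `duration` (seconds) and
#'   optionally `amplitude` (default 1). May have zero rows.
#' @param tr repetition time in seconds.
#' @param n_timepoints number of acquired volumes.
#' @param dt fine-grid resolution in seconds.
#' @return numeric regressor of length `n_timepoints`.
#' @export
convolve_events <- function(events, tr, n_timepoints, dt = 0.1) {
  if (nrow(events) > 0 && any(events$duration < 0)) {
    stop_invalid("event durations must be non-negative")
  }
  n_fine <- ceiling((n_timepoints - 1) * tr / dt) + 1L
  if (nrow(events) == 0L) return(numeric(n_timepoints))
  x <- matrix(rowSums(fine_boxcars(events, n_fine, dt)), n_fine, 1)
  as.numeric(conv_hrf_sample(x, tr, n_timepoints, dt))
}

# One HRF regressor per event row (timepoints x events matrix).
event_regressors <- function(events, tr, n_timepoints, dt = 0.1) {
  if (nrow(events) == 0L) return(matrix(0, n_timepoints, 0))
  if (any(events$duration < 0)) {
    stop_invalid("event durations must be non-negative")
  }
  n_fine <- ceiling((n_timepoints - 1) * tr / dt) + 1L
  conv_hrf_sample(fine_boxcars(events, n_fine, dt), tr, n_timepoints, dt)
}
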