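#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the montage average is zero everywhere.
#'
#' @param epochs an [epoch_set()] with at least 2 channels.
#' @return the re-referenced `epoch_set`.
#' @export
common_average_reference <- function(epochs) {
  d <- dim(epochs$data)
  if (d[2] < 2) stop("common average reference needs >= 2 channels")
  out <- epochs$data
  for (i in seq_len(d[1])) {
    x <- out[i, , ]
    out[i, , ] <- sweep(x, 2, colMeans(x), "-")
  }
  epochs$data <- out
  epochs
}

# Squared magnitude response of a bilinear-transformed Butterworth
# band-pass (the zero-phase forward-backward response), evaluated in
# closed form from the prewarped analog prototype:
#   |H(w)|^2 = 1 / (1 + ((W^2 - Wl*Wh) / ((Wh - Wl) W))^(2*order)),
# with W = tan(pi f / fs).  Unconditionally stable for arbitrarily
# narrow bands, unlike the expanded transfer-function coefficients.
butter_bandpass_gain <- function(freq_hz, low, high, sample_rate,
                                 order = 4) {
  w <- pmin(pmax(abs(freq_hz), 1e-12), sample_rate / 2 * (1 - 1e-12))
  W <- tan(pi * w / sample_rate)
  Wl <- tan(pi * low / sample_rate)
  Wh <- tan(pi * high / sample_rate)
  r <- (W^2 - Wl * Wh) / ((Wh - Wl) * W)
  1 / (1 + r^(2 * order))
}

# Odd-reflection padding indices/values for one trial matrix
# (samples x channels), padded to a 5-smooth FFT length.
pad_reflect <- function(x, pad_left, pad_right) {
  n <- nrow(x)
  top <- 2 * matrix(x[1, ], pad_left, ncol(x), byrow = TRUE) -
    x[(pad_left + 1):2, , drop = FALSE]
  bottom <- 2 * matrix(x[n, ], pad_right, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - pad_right), , drop = FALSE]
  rbind(top, x, bottom)
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass with zero phase response
#' (the forward-backward squared-magnitude response), realized spectrally
#' from the closed-form prewarped response with odd-reflection padding.
#' Zero phase is required because the connectivity stage consumes
#' instantaneous phase.
#'
#' @param epochs an [epoch_set()].
#' @param band_edges `c(low, high)` in Hz, `0 < low < high < Nyquist`.
#' @param order Butterworth order (default 4).
#' @return the filtered `epoch_set`.
#' @export
bandpass <- function(epochs, band_edges, order = 4) {
  fs <- epochs$sample_rate
  low <- band_edges[1]; high <- band_edges[2]
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("band edge at or above Nyquist frequency")
  d <- dim(epochs$data)
  n <- d[3]
  total <- nextn(2 * n, c(2, 3, 5))
  pad_left <- (total - n) %/% 2
  pad_right <- total - n - pad_left
  if (pad_left > n - 1 || pad_right > n - 1) {
    total <- 2 * n
    pad_left <- (total - n) %/% 2
    pad_right <- total - n - pad_left
  }
  freqs <- (seq_len(total) - 1) / total * fs
  freqs <- pmin(freqs, fs - freqs)
  H <- butter_bandpass_gain(freqs, low, high, fs, order)
  out <- epochs$data
  for (i in seq_len(d[1])) {
    x <- t(out[i, , , drop = TRUE])
    if (d[2] == 1) x <- matrix(out[i, 1, ], ncol = 1)
    xp <- pad_reflect(x, pad_left, pad_right)
    Xf <- mvfft(xp) * H
    y <- Re(mvfft(Xf, inverse = TRUE)) / total
    out[i, , ] <- t(y[pad_left + seq_len(n), , drop = FALSE])
  }
  epochs$data <- out
  epochs
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' pre-stimulus baseline span.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_span `c(start, end)` in ms relative to stimulus onset;
#'   samples with `start <= t < end` form the baseline.
#' @return the baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_span = c(-200, 0)) {
  t_ms <- epoch_times(epochs)
  sel <- which(t_ms >= baseline_span[1] & t_ms < baseline_span[2])
  if (length(sel) == 0) stop("baseline span contains no samples")
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1])) {
    base <- rowMeans(matrix(out[i, , sel], nrow = d[2]))
    out[i, , ] <- out[i, , ] - base
  }
  epochs$data <- out
  epochs
}

# Sample indices of post-stimulus analysis window `w` (1-based).
window_indices <- function(n_samples, time_zero_index, sample_rate,
                           window_index, window_ms) {
  spw <- round(window_ms * sample_rate / 1000)
  start <- time_zero_index + (window_index - 1L) * spw
  if (start + spw - 1L > n_samples)
    stop("analysis window ", window_index, " exceeds the epoch span")
  start:(start + spw - 1L)
}

#' Split epochs into sequential post-stimulus analysis windows
#'
#' Slices `n_windows` contiguous, non-overlapping windows of `window_ms`
#' each, starting at stimulus onset (time 0). Filtering and the Hilbert
#' transform are always applied to the full epoch upstream; only the
#' already-processed data are sliced here.
#'
#' @param epochs an [epoch_set()].
#' @param n_windows number of windows.
#' @param window_ms window length in ms.
#' @param band_label optional band label carried into the slices.
#' @param band_edges optional band edges carried into the slices.
#' @return list of `band_window` objects, each holding
#'   `trials x channels x window-samples` data, its window index and ms
#'   span.
#' @export
window_split <- function(epochs, n_windows = 5, window_ms = 100,
                         band_label = NA_character_, band_edges = NULL) {
  fs <- epochs$sample_rate
  d <- dim(epochs$data)
  spw <- window_ms * fs / 1000
  if (abs(spw - round(spw)) > 1e-9)
    stop("window_ms is not an integer number of samples")
  if (epochs$time_zero_index + n_windows * round(spw) - 1 > d[3])
    stop("post-stimulus span too short for ", n_windows, " windows of ",
         window_ms, " ms")
  lapply(seq_len(n_windows), function(w) {
    idx <- window_indices(d[3], epochs$time_zero_index, fs, w, window_ms)
    structure(
      list(band_label = band_label, band_edges = band_edges,
           window_index = w,
           window_span = c((w - 1) * window_ms, w * window_ms),
           data = epochs$data[, , idx, drop = FALSE],
           sample_rate = fs, channel_labels = epochs$channel_labels),
      class = "band_window")
  })
}
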