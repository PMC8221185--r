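# Analytic signal of each column of a samples x signals matrix via the
# one-sided FFT (positive-frequency doubling).
hilbert_analytic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x) * h, inverse = TRUE) / n
}

#' Analytic signal, instantaneous amplitude and phase
#'
#' Builds the complex analytic signal of a single channel (real part the
#' signal itself, imaginary part its Hilbert transform), and from it the
#' instantaneous amplitude and the four-quadrant instantaneous phase.
#'
#' @param signal numeric vector of at least 4 finite samples, not all
#'   zero (the phase of the zero signal is undefined).
#' @return an object of class `analytic_signal` with fields `real`,
#'   `quadrature`, `amplitude` and `phase` (radians in (-pi, pi\]).
#' @export
analytic_phase <- function(signal) {
  if (length(signal) < 4) stop("need at least 4 samples")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  if (max(abs(signal)) == 0)
    stop("all-zero signal: instantaneous phase is undefined")
  z <- hilbert_analytic(matrix(signal, ncol = 1))[, 1]
  phase <- atan2(Im(z), Re(z))
  phase[phase <= -pi] <- pi
  structure(list(real = Re(z), quadrature = Im(z),
                 amplitude = Mod(z), phase = phase),
            class = "analytic_signal")
}

#' Phase lag index of a channel pair
#'
#' The PLI is the absolute time-average of the signum of the sine of the
#' instantaneous phase difference. The three-valued signum (with
#' sgn(0) = 0) removes zero-lag synchronization, which is what makes the
#' index robust to volume conduction. Sine values within `tol` of zero
#' are treated as exactly zero so analytically zero-lag inputs behave
#' deterministically.
#'
#' @param phase_a,phase_b phase series in radians, equal length >= 1.
#' @param tol tolerance below which `sin` of the phase difference is
#'   treated as zero.
#' @return PLI value in \[0, 1\].
#' @export
pli_pair <- function(phase_a, phase_b, tol = 1e-12) {
  if (length(phase_a) != length(phase_b))
    stop("phase series lengths differ")
  if (length(phase_a) < 1) stop("empty phase series")
  s <- sin(phase_a - phase_b)
  s[abs(s) < tol] <- 0
  abs(mean(sign(s)))
}

# Core: PLI over all pairs of a channels x samples phase matrix.
pli_matrix_core <- function(phases, tol = 1e-12) {
  nc <- nrow(phases)
  ns <- ncol(phases)
  out <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1)) {
    rest <- (i + 1):nc
    d <- phases[rest, , drop = FALSE] -
      matrix(phases[i, ], length(rest), ns, byrow = TRUE)
    s <- sin(d)
    s[abs(s) < tol] <- 0
    v <- abs(rowMeans(sign(s)))
    out[i, rest] <- v
    out[rest, i] <- v
  }
  out
}

#' Phase-lag-index adjacency matrix
#'
#' Fills all unordered channel pairs with their PLI; the result is
#' symmetric with a zero diagonal and entries in \[0, 1\].
#'
#' @param phases either a `channels x samples` matrix of instantaneous
#'   phases, or a `band_window` object from [window_split()] (phases are
#'   then computed per channel via [analytic_phase()]).
#' @param trial trial index, required when `phases` is a `band_window`.
#' @param tol zero tolerance passed to the signum, see [pli_pair()].
#' @return `channels x channels` PLI matrix; for a `band_window` input
#'   the band label and window index are attached as attributes.
#' @export
pli_matrix <- function(phases, trial = NULL, tol = 1e-12) {
  if (inherits(phases, "band_window")) {
    if (is.null(trial)) stop("`trial` is required for band_window input")
    dat <- phases$data[trial, , , drop = TRUE]
    if (is.null(dim(dat))) dat <- matrix(dat, nrow = dim(phases$data)[2])
    ph <- t(apply(dat, 1, function(ch) analytic_phase(ch)$phase))
    out <- pli_matrix_core(ph, tol)
    dimnames(out) <- list(phases$channel_labels, phases$channel_labels)
    attr(out, "band_label") <- phases$band_label
    attr(out, "window_index") <- phases$window_index
    attr(out, "n_samples") <- dim(phases$data)[3]
    return(out)
  }
  if (!is.matrix(phases) || nrow(phases) < 2)
    stop("need a phase matrix with >= 2 channels")
  pli_matrix_core(phases, tol)
}

#' Per-trial PLI networks across bands and windows
#'
#' The full connectivity stage: for every band in the plan the epochs
#' are zero-phase band-pass filtered, instantaneous phases are computed
#' on the full epoch (so filter and Hilbert edge effects stay outside
#' the analysis span), sliced into the post-stimulus windows, and a PLI
#' adjacency matrix is computed per trial, band and window.
#'
#' @param epochs an [epoch_set()], already re-referenced and baseline
#'   corrected as required.
#' @param band_plan named list of band edges (Hz pairs).
#' @param n_windows number of 100-ms analysis windows (default 5).
#' @param window_ms window length in ms.
#' @return an object of class `pli_stack`: list with `pli` (array
#'   `channels x channels x trials x bands x windows`), `meta` (per-trial
#'   data.frame with `trial`, `condition`, `subject`), `bands`,
#'   `channel_labels`, `n_windows`, `window_ms`.
#' @export
connectivity_stack <- function(epochs, band_plan = default_band_plan(),
                               n_windows = 5, window_ms = 100) {
  d <- dim(epochs$data)
  nb <- length(band_plan)
  idx_w <- lapply(seq_len(n_windows), function(w)
    window_indices(d[3], epochs$time_zero_index, epochs$sample_rate,
                   w, window_ms))
  pli <- array(0, c(d[2], d[2], d[1], nb, n_windows),
               dimnames = list(epochs$channel_labels,
                               epochs$channel_labels, NULL,
                               names(band_plan), NULL))
  for (b in seq_len(nb)) {
    filt <- bandpass(epochs, band_plan[[b]])
    for (i in seq_len(d[1])) {
      x <- t(filt$data[i, , , drop = TRUE])
      if (d[2] == 1) stop("connectivity needs >= 2 channels")
      z <- hilbert_analytic(x)
      ph <- t(atan2(Im(z), Re(z)))
      for (w in seq_len(n_windows)) {
        pli[, , i, b, w] <- pli_matrix_core(ph[, idx_w[[w]],
                                               drop = FALSE])
      }
    }
  }
  structure(
    list(pli = pli,
         meta = data.frame(trial = seq_len(d[1]),
                           condition = epochs$condition,
                           subject = epochs$subject,
                           stringsAsFactors = FALSE),
         bands = names(band_plan), channel_labels = epochs$channel_labels,
         n_windows = as.integer(n_windows), window_ms = window_ms),
    class = "pli_stack")
}

#' @export
print.pli_stack <- function(x, ...) {
  d <- dim(x$pli)
  cat(sprintf(
    "<pli_stack> %d channels, %d trials, %d bands x %d windows\n",
    d[1], d[3], d[4], d[5]))
  invisible(x)
}
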