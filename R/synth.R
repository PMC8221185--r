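#' Default frequency-band plan
#'
#' The five classical EEG bands used throughout the pipeline.
#'
#' @return named list of `c(low, high)` band edges in Hz.
#' @export
default_band_plan <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(13, 30), gamma = c(31, 46))
}

#' Phase-coupling graph
#'
#' An undirected graph over the channels whose edges carry a target phase
#' lag (radians) and a coupling weight in \[0, 1\]. The generator makes
#' every coupled pair share a common narrowband phase process offset by
#' the target lag, so the pair's phase-lag index is driven toward 1 when
#' the lag is away from 0 and pi. Zero-lag edges are legal but invisible
#' to the PLI by construction (the signum of the sine removes them).
#'
#' @param n_nodes number of channels.
#' @param edges data.frame with columns `i`, `j` (1-based channel
#'   indices), `lag` (radians, in (-pi, pi\]) and `weight` (in \[0, 1\]).
#' @param carrier carrier scoping. `"component"`: one shared phase
#'   carrier per connected component, with per-node offsets accumulated
#'   along the edges — every node pair in a component is phase locked,
#'   which is the right model for a star (equal edge lags make all
#'   leaf-leaf pairs zero-lag, hence invisible to the PLI). `"edge"`:
#'   one carrier per edge, mixed at the two endpoints only — locking is
#'   strictly pairwise, which is the right model for a path (a shared
#'   carrier would phase-lock distant node pairs at visible lags).
#' @return an object of class `coupling_graph`.
#' @export
coupling_graph <- function(n_nodes, edges,
                           carrier = c("component", "edge")) {
  carrier <- match.arg(carrier)
  edges <- as.data.frame(edges)
  stopifnot(all(c("i", "j", "lag", "weight") %in% names(edges)))
  if (any(edges$i == edges$j)) stop("self-edges are not allowed")
  if (any(edges$i < 1 | edges$j < 1 | edges$i > n_nodes |
          edges$j > n_nodes))
    stop("edge endpoints outside 1..n_nodes")
  key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  if (anyDuplicated(key)) stop("duplicate (unordered) edges")
  if (any(edges$lag <= -pi | edges$lag > pi))
    stop("edge lags must lie in (-pi, pi]")
  if (any(edges$weight < 0 | edges$weight > 1))
    stop("edge weights must lie in [0, 1]")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 carrier = carrier),
            class = "coupling_graph")
}

#' Star coupling topology
#'
#' All channels couple to a single hub: the planted analogue of a
#' star-like (hub-integrated) network backbone.
#'
#' @param n_nodes number of channels.
#' @param hub hub channel index.
#' @param lag target phase lag in radians (must differ from 0 to be
#'   visible to the PLI).
#' @param weight coupling weight in \[0, 1\].
#' @return a `coupling_graph`.
#' @export
star_coupling <- function(n_nodes, hub = 1, lag = pi / 2, weight = 1) {
  others <- setdiff(seq_len(n_nodes), hub)
  coupling_graph(n_nodes, data.frame(i = hub, j = others, lag = lag,
                                     weight = weight))
}

#' Chain coupling topology
#'
#' Channels couple along a simple path 1-2-...-N: the planted analogue of
#' a line-like network backbone.
#'
#' @inheritParams star_coupling
#' @return a `coupling_graph`.
#' @export
chain_coupling <- function(n_nodes, lag = pi / 2, weight = 1) {
  coupling_graph(n_nodes, data.frame(i = seq_len(n_nodes - 1),
                                     j = 2:n_nodes, lag = lag,
                                     weight = weight),
                 carrier = "edge")
}

#' Synthetic-dataset configuration
#'
#' Defines the study conditions emulated by the generator: the trial
#' structure, acquisition parameters (63 channels at 1000 Hz, epochs from
#' -200 to 800 ms around stimulus onset by default), the band plan, and a
#' coupling plan mapping (condition, band, analysis window) to a planted
#' [coupling_graph()].
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per condition per subject.
#' @param n_channels number of channels (default 63).
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param epoch_span epoch extent in ms around stimulus onset,
#'   `c(start, end)` with start < 0 < end.
#' @param band_plan named list of band edges; see [default_band_plan()].
#' @param conditions condition labels; by default two contrast conditions
#'   (`"face"`, `"ketch"`) plus the reference condition (`"scrambled"`).
#' @param coupling_plan nested named list
#'   `plan[[condition]][[band]][[window]]` of [coupling_graph()] objects;
#'   window keys are the analysis-window indices `"1"`..`"5"` as names.
#'   Conditions/bands/windows absent from the plan get independent
#'   phases.
#' @param coupling_strength global multiplier on edge weights, in
#'   \[0, 1\].
#' @param noise_sd standard deviation of the additive broadband noise, in
#'   units of the (unit-RMS) narrowband components.
#' @param n_windows number of post-stimulus analysis windows.
#' @param window_ms analysis-window length in ms.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 1, trials_per_condition = 10,
                         n_channels = 63, sample_rate = 1000,
                         epoch_span = c(-200, 800),
                         band_plan = default_band_plan(),
                         conditions = c("face", "ketch", "scrambled"),
                         coupling_plan = list(),
                         coupling_strength = 0.9, noise_sd = 1,
                         n_windows = 5, window_ms = 100, seed = 1) {
  if (epoch_span[1] >= 0 || epoch_span[2] <= 0)
    stop("epoch_span must satisfy start < 0 < end")
  ns <- diff(epoch_span) * sample_rate / 1000
  if (abs(ns - round(ns)) > 1e-9)
    stop("epoch_span does not span an integer number of samples")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_windows * window_ms > epoch_span[2])
    stop("analysis windows do not fit in the post-stimulus span")
  for (cond in names(coupling_plan)) {
    if (!cond %in% conditions)
      stop("coupling_plan condition '", cond, "' not in `conditions`")
    for (band in names(coupling_plan[[cond]])) {
      if (!band %in% names(band_plan))
        stop("coupling_plan band '", band, "' not in `band_plan`")
      wins <- coupling_plan[[cond]][[band]]
      for (w in names(wins)) {
        wi <- suppressWarnings(as.integer(w))
        if (is.na(wi) || wi < 1 || wi > n_windows)
          stop("coupling_plan window index '", w,
               "' outside 1..", n_windows)
        g <- wins[[w]]
        if (!inherits(g, "coupling_graph") || g$n_nodes != n_channels)
          stop("coupling_plan entries must be coupling_graph objects ",
               "with n_channels nodes")
      }
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_condition = as.integer(trials_per_condition),
         n_channels = as.integer(n_channels),
         sample_rate = sample_rate, epoch_span = epoch_span,
         band_plan = band_plan, conditions = conditions,
         coupling_plan = coupling_plan,
         coupling_strength = coupling_strength, noise_sd = noise_sd,
         n_windows = as.integer(n_windows), window_ms = window_ms,
         seed = as.integer(seed)),
    class = "synth_config")
}

# Complex analytic band-limited Gaussian noise, one column per signal.
# Synthesized in the frequency domain: independent complex-Gaussian
# amplitudes on the positive-frequency bins inside [lo, hi], zeros
# elsewhere, so the inverse FFT is the analytic signal directly.  Each
# column is scaled so its real part has unit RMS.
analytic_band_noise <- function(n_samples, n_signals, lo, hi,
                                sample_rate) {
  freqs <- (seq_len(n_samples) - 1) * sample_rate / n_samples
  sel <- which(freqs >= lo & freqs <= hi & freqs < sample_rate / 2)
  if (length(sel) == 0)
    stop("band [", lo, ", ", hi, "] Hz contains no frequency bins at ",
         "this epoch length")
  spec <- matrix(0 + 0i, n_samples, n_signals)
  nb <- length(sel)
  spec[sel, ] <- matrix(complex(real = rnorm(nb * n_signals),
                                imaginary = rnorm(nb * n_signals)),
                        nb, n_signals)
  z <- mvfft(spec, inverse = TRUE) / n_samples
  scale <- sqrt(colMeans(Re(z)^2))
  scale[scale == 0] <- 1
  sweep(z, 2, scale, "/")
}

# Raised-cosine envelope that is 1 inside an analysis window and 0
# outside, crossfaded with a `ramp_ms` cosine ramp centred on each
# window border (half the ramp inside, half outside), which avoids
# mixing discontinuities while leaving almost all in-window samples at
# full coupling.
window_envelope <- function(n_samples, time_zero_index, sample_rate,
                            window_index, window_ms, ramp_ms = 10) {
  spw <- round(window_ms * sample_rate / 1000)
  ramp <- max(2L, round(ramp_ms * sample_rate / 1000))
  half <- ramp %/% 2L
  start <- time_zero_index + (window_index - 1L) * spw
  env <- numeric(n_samples)
  lo <- max(1L, start - half)
  hi <- min(n_samples, start + spw - 1L + half)
  env[lo:hi] <- 1
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
  rise <- (start - half) + seq_len(ramp) - 1L
  ok <- rise >= 1 & rise <= n_samples
  env[rise[ok]] <- up[ok]
  fall <- (start + spw - 1L + half) - seq_len(ramp) + 1L
  ok <- fall >= 1 & fall <= n_samples
  env[fall[ok]] <- up[ok]
  env
}

# Per-node phase offsets implied by a coupling graph: breadth-first walk
# from each component root accumulating the signed edge lags.  For tree-
# shaped graphs (star, chain) the offsets reproduce every edge lag
# exactly; on graphs with cycles the walk uses a spanning subset of the
# edges.
coupling_offsets <- function(graph) {
  n <- graph$n_nodes
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    adj[[e$i]] <- rbind(adj[[e$i]], c(e$j, e$lag))
    adj[[e$j]] <- rbind(adj[[e$j]], c(e$i, -e$lag))
  }
  offset <- rep(NA_real_, n)
  component <- rep(NA_integer_, n)
  comp <- 0L
  for (root in seq_len(n)) {
    if (!is.na(offset[root])) next
    comp <- comp + 1L
    offset[root] <- 0
    component[root] <- comp
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (is.na(offset[u])) {
          # lag convention: phase(i) - phase(j) = lag on edge (i, j)
          offset[u] <- offset[v] - nb[r, 2]
          component[u] <- comp
          queue <- c(queue, u)
        }
      }
    }
  }
  list(offset = offset, component = component,
       n_components = comp)
}

#' Generate a synthetic epoch set with planted coupling topologies
#'
#' Each channel is a sum over bands of unit-RMS narrowband Gaussian
#' oscillations plus broadband noise. Within an analysis window that
#' carries a planted [coupling_graph()], coupled channels replace a
#' fraction `weight * coupling_strength` of their independent narrowband
#' component by a common band-limited phase carrier offset by the edge's
#' target lag; the mixing coefficient is crossfaded with a 10-ms cosine
#' ramp inside the window borders. Windows without a planted graph keep
#' fully independent phases.
#'
#' @param config a [synth_config()].
#' @return an [epoch_set()]; trials are ordered by condition, then
#'   subject, then repetition. Regenerating with the same configuration
#'   yields bit-identical data.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sample_rate
  n <- as.integer(round(diff(config$epoch_span) * fs / 1000))
  tz <- as.integer(round(-config$epoch_span[1] * fs / 1000)) + 1L
  nc <- config$n_channels
  per_cond <- config$n_subjects * config$trials_per_condition
  nt <- per_cond * length(config$conditions)
  dat <- array(0, c(nt, nc, n))
  condition <- character(nt)
  subject <- character(nt)
  set.seed(config$seed)
  trial <- 0L
  for (cond in config$conditions) {
    plan_c <- config$coupling_plan[[cond]]
    # precompute offsets per (band, window) once per condition
    offsets_c <- lapply(plan_c, function(bands) lapply(bands,
                                                       coupling_offsets))
    for (s in seq_len(config$n_subjects)) {
      for (r in seq_len(config$trials_per_condition)) {
        trial <- trial + 1L
        condition[trial] <- cond
        subject[trial] <- sprintf("s%02d", s)
        x <- matrix(0, n, nc)
        for (band in names(config$band_plan)) {
          edges <- config$band_plan[[band]]
          z_ind <- analytic_band_noise(n, nc, edges[1], edges[2], fs)
          mix <- matrix(0, n, nc)
          coupled <- matrix(0 + 0i, n, nc)
          wins <- plan_c[[band]]
          for (w in names(wins)) {
            g <- wins[[w]]
            env <- window_envelope(n, tz, fs, as.integer(w),
                                   config$window_ms)
            m_node <- numeric(nc)
            for (k in seq_len(nrow(g$edges))) {
              e <- g$edges[k, ]
              wgt <- e$weight * config$coupling_strength
              m_node[e$i] <- max(m_node[e$i], wgt)
              m_node[e$j] <- max(m_node[e$j], wgt)
            }
            node_carrier <- matrix(0 + 0i, n, nc)
            if (g$carrier == "component") {
              off <- offsets_c[[band]][[w]]
              carriers <- analytic_band_noise(n, off$n_components,
                                              edges[1], edges[2], fs)
              for (v in which(m_node > 0)) {
                node_carrier[, v] <- carriers[, off$component[v]] *
                  exp(1i * off$offset[v])
              }
            } else {
              ne <- nrow(g$edges)
              carriers <- analytic_band_noise(n, ne, edges[1],
                                              edges[2], fs)
              n_inc <- numeric(nc)
              for (k in seq_len(ne)) {
                e <- g$edges[k, ]
                node_carrier[, e$i] <- node_carrier[, e$i] +
                  carriers[, k] * exp(1i * e$lag / 2)
                node_carrier[, e$j] <- node_carrier[, e$j] +
                  carriers[, k] * exp(-1i * e$lag / 2)
                n_inc[e$i] <- n_inc[e$i] + 1
                n_inc[e$j] <- n_inc[e$j] + 1
              }
              for (v in which(n_inc > 0))
                node_carrier[, v] <- node_carrier[, v] / sqrt(n_inc[v])
            }
            for (v in which(m_node > 0)) {
              coupled[, v] <- coupled[, v] +
                env * m_node[v] * node_carrier[, v]
              mix[, v] <- mix[, v] + env * m_node[v]
            }
          }
          mix <- pmin(mix, 1)
          x <- x + Re((1 - mix) * z_ind + coupled)
        }
        if (config$noise_sd > 0)
          x <- x + matrix(rnorm(n * nc, sd = config$noise_sd), n, nc)
        dat[trial, , ] <- t(x)
      }
    }
  }
  epoch_set(dat, fs, tz, montage_1010(nc), condition, subject)
}

#' Experiment trial arithmetic
#'
#' Per-category trial count of a fully crossed design: subjects x
#' stimuli per category x repetitions.
#'
#' @param n_subjects,stimuli_per_category,repetitions positive counts.
#' @return the product, as an integer-valued numeric.
#' @export
#' @examples
#' experiment_counts(28, 48, 6)  # 8064
experiment_counts <- function(n_subjects, stimuli_per_category,
                              repetitions) {
  if (any(c(n_subjects, stimuli_per_category, repetitions) <= 0))
    stop("all counts must be positive")
  n_subjects * stimuli_per_category * repetitions
}

#' Split an epoch set into two condition-stratified subsets
#'
#' Within each condition, `round(fraction * n)` trials are drawn at
#' random into the first subset and the remainder into the second;
#' membership is disjoint, exhaustive, and reproducible under `seed`.
#'
#' @param epochs an `epoch_set`.
#' @param fraction proportion of each condition in the first subset,
#'   strictly between 0 and 1.
#' @param seed integer seed for the random draw.
#' @return list with elements `analysis` and `holdout`, both
#'   `epoch_set`s.
#' @export
split_dataset <- function(epochs, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be strictly between 0 and 1")
  set.seed(seed)
  first <- integer(0)
  for (cond in unique(epochs$condition)) {
    idx <- which(epochs$condition == cond)
    if (length(idx) < 2)
      stop("condition '", cond, "' has fewer than 2 trials")
    k <- round(fraction * length(idx))
    first <- c(first, sort(sample(idx, k)))
  }
  first <- sort(first)
  second <- setdiff(seq_len(n_trials(epochs)), first)
  list(analysis = subset_epochs(epochs, first),
       holdout = subset_epochs(epochs, second))
}
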