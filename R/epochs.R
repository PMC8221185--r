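#' Construct an epoch set
#'
#' The central data container: trial-structured multichannel signals with
#' their sampling rate, the sample index of stimulus onset, channel labels,
#' and per-trial condition and subject labels.
#'
#' @param data numeric array `trials x channels x samples`; all values
#'   must be finite.
#' @param sample_rate sampling rate in Hz.
#' @param time_zero_index 1-based sample index of stimulus onset (time 0).
#' @param channel_labels character vector, one label per channel. Defaults
#'   to [montage_1010()].
#' @param condition per-trial condition label (length = number of trials).
#' @param subject per-trial subject identifier (length = number of trials).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, sample_rate, time_zero_index,
                      channel_labels = NULL, condition = NULL,
                      subject = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  d <- dim(data)
  if (sample_rate <= 0) stop("`sample_rate` must be positive")
  if (time_zero_index < 1 || time_zero_index > d[3])
    stop("`time_zero_index` out of range")
  if (is.null(channel_labels)) channel_labels <- montage_1010(d[2])
  if (length(channel_labels) != d[2])
    stop("length(channel_labels) must equal the channel dimension")
  if (is.null(condition)) condition <- rep("all", d[1])
  if (is.null(subject)) subject <- rep("s1", d[1])
  if (length(condition) != d[1] || length(subject) != d[1])
    stop("`condition` and `subject` must have one entry per trial")
  structure(
    list(data = data, sample_rate = sample_rate,
         time_zero_index = as.integer(time_zero_index),
         channel_labels = as.character(channel_labels),
         condition = as.character(condition),
         subject = as.character(subject)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sample_rate))
  cat(sprintf("  stimulus onset at sample %d (%.0f ms span)\n",
              x$time_zero_index,
              (d[3]) / x$sample_rate * 1000))
  tab <- table(x$condition)
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset trials of an epoch set
#'
#' @param epochs an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return an `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$sample_rate,
            epochs$time_zero_index, epochs$channel_labels,
            epochs$condition[idx], epochs$subject[idx])
}

#' Time axis of an epoch set
#' @param epochs an `epoch_set`.
#' @return numeric vector of per-sample times in ms relative to stimulus
#'   onset.
#' @export
epoch_times <- function(epochs) {
  (seq_len(dim(epochs$data)[3]) - epochs$time_zero_index) *
    1000 / epochs$sample_rate
}

#' Write an epoch archive to disk
#'
#' Plain-text archive: one CSV matrix (channels x samples, no headers) per
#' trial, a JSON sidecar with the shared metadata and a CSV manifest
#' listing the trials.
#'
#' @param epochs an `epoch_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epoch_archive <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- n_trials(epochs)
  files <- sprintf("trial_%05d.csv", seq_len(nt))
  for (i in seq_len(nt)) {
    write.table(epochs$data[i, , ], file.path(dir, files[i]),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(sample_rate = epochs$sample_rate,
         time_zero_index = epochs$time_zero_index,
         channel_labels = epochs$channel_labels),
    file.path(dir, "sidecar.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(trial = seq_len(nt), file = files,
                       condition = epochs$condition,
                       subject = epochs$subject),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an epoch archive from disk
#'
#' @param dir directory written by [write_epoch_archive()].
#' @return an `epoch_set`.
#' @export
read_epoch_archive <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  man <- read.csv(file.path(dir, "manifest.csv"),
                  stringsAsFactors = FALSE)
  first <- as.matrix(read.csv(file.path(dir, man$file[1]), header = FALSE))
  dat <- array(0, c(nrow(man), nrow(first), ncol(first)))
  dat[1, , ] <- first
  for (i in seq_len(nrow(man))[-1]) {
    dat[i, , ] <- as.matrix(read.csv(file.path(dir, man$file[i]),
                                     header = FALSE))
  }
  epoch_set(dat, side$sample_rate, side$time_zero_index,
            side$channel_labels, man$condition, man$subject)
}
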