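#' Standard 10-10 channel montage
#'
#' Returns the default channel labels used by the synthetic generator.
#' For 63 channels the labels follow the international 10-10 system
#' (a 64-electrode cap with the reference electrode dropped); for any
#' other count generic `Ch01`, `Ch02`, ... labels are produced.
#'
#' @param n_channels number of channels.
#' @return character vector of length `n_channels`.
#' @export
#' @examples
#' montage_1010(63)[1:5]
montage_1010 <- function(n_channels = 63) {
  labels_63 <- c(
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  if (n_channels == length(labels_63)) {
    labels_63
  } else {
    sprintf("Ch%02d", seq_len(n_channels))
  }
}

#' Occipito-temporal channel set
#'
#' The occipito-temporal electrode labels used as the default channel
#' subset for the time-segment baseline features.
#'
#' @return character vector of channel labels.
#' @export
occipito_temporal_channels <- function() {
  c("P7", "PO7", "PO3", "O1", "POz", "Oz", "O2", "PO4", "PO8", "P8",
    "TP9", "TP10")
}
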