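#' Construct an EEG recording object
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channel_names Character vector, one per row of `data`.
#' @param sfreq_hz Sampling rate in Hz.
#' @param t0_s Time of the first sample relative to run start (seconds).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channel_names, sfreq_hz, t0_s = 0) {
  data <- rbind(data)
  stopifnot(nrow(data) == length(channel_names), sfreq_hz > 0)
  if (!all(is.finite(data))) stop("EEG samples must all be finite", call. = FALSE)
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names,
                 sfreq_hz = sfreq_hz, t0_s = t0_s),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channel(s) x ", ncol(x$data),
      " samples @ ", x$sfreq_hz, " Hz (",
      round(ncol(x$data) / x$sfreq_hz, 2), " s)\n", sep = "")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write an EEG recording as plain-text array plus sidecar
#'
#' The sample array goes to `<path>.tsv` (samples in rows, channels in
#' columns) and a sidecar `<path>_channels.tsv` records channel names and
#' the sampling rate.
#' @param rec An `eeg_recording`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  df <- tibble::as_tibble(t(rec$data), .name_repair = "minimal")
  names(df) <- rec$channel_names
  readr::write_tsv(df, paste0(path, ".tsv"))
  readr::write_tsv(
    tibble::tibble(name = rec$channel_names, sampling_rate_hz = rec$sfreq_hz,
                   t0_s = rec$t0_s),
    paste0(path, "_channels.tsv"))
  invisible(path)
}

#' Read an EEG recording written by [write_eeg()]
#' @param path Path stem used when writing.
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(path) {
  dat <- readr::read_tsv(paste0(path, ".tsv"), show_col_types = FALSE)
  side <- readr::read_tsv(paste0(path, "_channels.tsv"), show_col_types = FALSE)
  eeg_recording(t(as.matrix(dat)), side$name, side$sampling_rate_hz[1],
                t0_s = side$t0_s[1])
}
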