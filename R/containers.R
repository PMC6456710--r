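#' EEG recording container
#'
#' A continuous multichannel recording: a channels-by-samples numeric matrix in
#' microvolts with a sampling rate and an ordered 10/20 montage.
#'
#' @param data Numeric matrix, channels x samples (µV).
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Ordered channel labels; must be unique, one per row of `data`.
#' @param reference Reference electrode label (metadata only; data are used as
#'   recorded).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, reference = "CPz") {
  data <- as.matrix(data)
  fs <- as.numeric(fs)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(fs > 0, length(labels) == nrow(data), !anyDuplicated(labels))
  structure(list(data = data, fs = fs, labels = labels, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.3f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  invisible(x)
}

#' Event-locked epoch container
#'
#' Trials x channels x samples array with a time axis in seconds relative to
#' the event; time 0 is the event sample.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param times Time axis in seconds, length = samples, containing 0.
#' @param labels Channel labels.
#' @param event_kind Event-kind label per trial (recycled if length 1).
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, times, labels = NULL, event_kind = "event") {
  stopifnot(length(dim(data)) == 3L, fs > 0, length(times) == dim(data)[3L])
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(data)[2L]))
  stopifnot(length(labels) == dim(data)[2L])
  event_kind <- rep_len(event_kind, dim(data)[1L])
  structure(list(data = data, fs = fs, times = times, labels = labels,
                 event_kind = event_kind),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t in [%.4g, %.4g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
#' @rdname eeg_epochs
#' @param x An `eeg_epochs` object.
#' @param ... Unused.
tidy.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$labels, each = d[1]), times = d[3]),
    time_s = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

n_trials <- function(epochs) dim(epochs$data)[1L]
n_channels <- function(epochs) dim(epochs$data)[2L]
n_samples <- function(epochs) dim(epochs$data)[3L]
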