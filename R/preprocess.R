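# Event-locked segmentation and decimation. Epoch windows are half-open
# [-pre, +post) in samples, 0-based at the event sample, so 1.5 s at 32 Hz is
# exactly 48 samples; decimation low-passes (zero-phase) then keeps every
# (fs/target_fs)-th sample with time 0 retained.

#' Extract event-locked epochs from a recording
#'
#' One trial per event whose full `[-pre, +post)` window lies inside the
#' recording; events clipped by either edge are dropped and reported in the
#' `dropped` attribute. Epoch sample `k` (0-based) maps to recording sample
#' `event_index - pre*fs + k`.
#'
#' @param recording An [eeg_recording()].
#' @param events Tibble with `time_s` (and optionally `kind`).
#' @param pre Seconds before the event (>= 0); study design 0.5.
#' @param post Seconds after the event (>= 0); study design 1.0.
#' @param demean Subtract the per-trial, per-channel mean (AR models assume
#'   zero-mean data). Default `TRUE`.
#' @return An [eeg_epochs()] with attribute `dropped` (tibble of dropped
#'   events).
#' @export
extract_epochs <- function(recording, events, pre = 0.5, post = 1.0,
                           demean = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"), pre >= 0, post >= 0,
            pre + post > 0)
  fs <- recording$fs
  N <- ncol(recording$data)
  npre <- round(pre * fs)
  npost <- round(post * fs)
  idx0 <- round(events$time_s * fs) + 1L   # 1-based sample of the event peak
  lo <- idx0 - npre
  hi <- idx0 + npost - 1L
  ok <- lo >= 1L & hi <= N
  if (!any(ok)) abort("no event has a full epoch window inside the recording")
  kinds <- rep_len(events$kind %||% "event", length(idx0))
  n_ch <- nrow(recording$data)
  nsamp <- npre + npost
  data <- array(0, dim = c(sum(ok), n_ch, nsamp))
  for (r in seq_along(which(ok))) {
    i <- which(ok)[r]
    seg <- recording$data[, lo[i]:hi[i], drop = FALSE]
    if (demean) seg <- seg - rowMeans(seg)
    data[r, , ] <- seg
  }
  ep <- eeg_epochs(data, fs = fs, times = (-npre:(npost - 1L)) / fs,
                   labels = recording$labels, event_kind = kinds[ok])
  attr(ep, "dropped") <- tibble::tibble(time_s = events$time_s[!ok],
                                        kind = kinds[!ok],
                                        reason = "window outside recording")
  ep
}

#' Decimate epochs to a lower analysis rate
#'
#' Zero-phase anti-alias low-pass (4th-order Butterworth applied forward and
#' backward, cutoff `0.4 * target_fs`) followed by keeping every
#' `fs/target_fs`-th sample, phased so the time-0 sample is retained. Channel
#' means are removed before filtering and restored afterwards, so constant
#' offsets pass through exactly.
#'
#' @param epochs An [eeg_epochs()].
#' @param target_fs Target rate in Hz; must divide `fs` exactly. The study's
#'   analysis time base is 32 Hz.
#' @return Decimated [eeg_epochs()].
#' @export
decimate_epochs <- function(epochs, target_fs = 32) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  if (target_fs >= fs) abort("target_fs must be below the current rate")
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf("fs (%g) is not an integer multiple of target_fs (%g)", fs, target_fs))
  }
  factor <- as.integer(round(factor))
  idx0 <- which.min(abs(epochs$times))
  keep <- which((seq_along(epochs$times) - idx0) %% factor == 0L)
  bf <- signal::butter(4, 0.4 * target_fs / (fs / 2), type = "low")
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], d[2], length(keep)))
  for (r in seq_len(d[1])) {
    for (c_ in seq_len(d[2])) {
      x <- epochs$data[r, c_, ]
      mu <- mean(x)
      y <- signal::filtfilt(bf, x - mu) + mu
      out[r, c_, ] <- y[keep]
    }
  }
  ep <- eeg_epochs(out, fs = target_fs, times = epochs$times[keep],
                   labels = epochs$labels, event_kind = epochs$event_kind)
  attr(ep, "dropped") <- attr(epochs, "dropped")
  ep
}

#' Interpolate an artifact window in epochs
#'
#' Replaces samples whose epoch time falls in `[start, end)` (ms) with a cubic
#' spline fitted to the flanking samples, per channel and trial. A zero-width
#' window is the identity.
#'
#' @param epochs An [eeg_epochs()].
#' @param window Numeric length-2, start and end of the window in ms relative
#'   to the event.
#' @param n_flank Flanking samples used on each side of the window.
#' @return [eeg_epochs()] with the window replaced.
#' @export
interpolate_artifact <- function(epochs, window = c(0, 10), n_flank = 8L) {
  stopifnot(inherits(epochs, "eeg_epochs"), length(window) == 2L,
            window[1] <= window[2])
  t_ms <- epochs$times * 1000
  if (window[1] < min(t_ms) || window[2] > max(t_ms) + 1000 / epochs$fs) {
    abort("artifact window lies outside the epoch")
  }
  bad <- which(t_ms >= window[1] & t_ms < window[2])
  if (length(bad) == 0L) return(epochs)
  nsamp <- n_samples(epochs)
  left <- max(1L, min(bad) - n_flank):(min(bad) - 1L)
  right_lo <- max(bad) + 1L
  right <- if (right_lo <= nsamp) right_lo:min(nsamp, max(bad) + n_flank) else integer()
  anchors <- c(left[left >= 1L], right)
  if (length(anchors) < 4L) abort("not enough flanking samples to interpolate")
  d <- dim(epochs$data)
  for (r in seq_len(d[1])) {
    for (c_ in seq_len(d[2])) {
      fit <- spline(anchors, epochs$data[r, c_, anchors], xout = bad,
                    method = "natural")
      epochs$data[r, c_, bad] <- fit$y
    }
  }
  epochs
}
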