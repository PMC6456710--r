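# Nonstationary MVAR simulation: X(t) = sum_i A_i(t) X(t-i) + E(t),
# E ~ N(0, noise_cov). The generative direction of the TV-MVAAR model.

chol_or_abort <- function(noise_cov, n) {
  noise_cov <- as.matrix(noise_cov)
  stopifnot(nrow(noise_cov) == n, ncol(noise_cov) == n)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10) {
    abort("noise_cov must be symmetric")
  }
  L <- tryCatch(chol(noise_cov), error = function(e) NULL)
  if (is.null(L)) abort("noise_cov must be positive definite")
  t(L)
}

mvar_drive <- function(phi_get, n, p, N, L, burn_noise) {
  # burn_noise: n x N innovations already drawn; first p samples are pure noise
  X <- matrix(0, n, N)
  X[, seq_len(min(p, N))] <- burn_noise[, seq_len(min(p, N)), drop = FALSE]
  if (N > p) {
    for (k in (p + 1L):N) {
      z <- as.vector(X[, k - seq_len(p), drop = FALSE])
      X[, k] <- phi_get(k) %*% z + burn_noise[, k]
    }
  }
  X
}

#' Simulate event-locked trials from a coefficient schedule
#'
#' Draws `n_trials` independent realizations of the nonstationary MVAR process
#' defined by `schedule`, sampled at `fs` over the schedule's time span. The
#' first p samples of each trial are pure innovations. Deterministic in
#' `(schedule, noise_cov, fs, n_trials, seed)`.
#'
#' @param schedule A [build_coefficient_schedule()] object.
#' @param fs Sampling rate in Hz.
#' @param n_trials Number of independent trials.
#' @param noise_cov Innovation covariance (symmetric positive definite);
#'   default identity.
#' @param seed Integer seed (required: generators are pure functions of their
#'   inputs and the seed).
#' @param labels Channel labels; defaults to the first n labels of
#'   [montage_1020_32()] when n <= 32.
#' @return An [eeg_epochs()] object with the ground-truth schedule attached as
#'   attribute `ground_truth` and the seed as attribute `seed`.
#' @export
simulate_tvmvar <- function(schedule, fs, n_trials = 1, noise_cov = NULL,
                            seed, labels = NULL) {
  stopifnot(inherits(schedule, "coef_schedule"), fs > 0, n_trials >= 1)
  n <- schedule$n_nodes
  p <- schedule$order
  if (is.null(noise_cov)) noise_cov <- diag(n)
  L <- chol_or_abort(noise_cov, n)
  duration <- schedule$t_end - schedule$t_start
  N <- round(duration * fs)
  if (N <= p) abort("schedule duration shorter than the model order in samples")
  times <- schedule$t_start + (seq_len(N) - 1L) / fs
  lut <- schedule_phi_lookup(schedule, times)
  if (is.null(labels)) {
    labels <- if (n <= 32) montage_1020_32()[seq_len(n)] else paste0("ch", seq_len(n))
  }
  data <- with_seed_(seed, {
    out <- array(0, dim = c(n_trials, n, N))
    for (r in seq_len(n_trials)) {
      E <- L %*% matrix(rnorm(n * N), n, N)
      out[r, , ] <- mvar_drive(lut$get, n, p, N, L, E)
    }
    out
  })
  ep <- eeg_epochs(data, fs = fs, times = times, labels = labels,
                   event_kind = "simulated")
  attr(ep, "ground_truth") <- schedule
  attr(ep, "seed") <- seed
  ep
}

#' Place periodic TMS pulse events on a recording timeline
#'
#' Pulses at `start_offset + k * interval` seconds; only events whose full
#' peri-event window `[-pre, +post]` fits inside the recording are kept, so
#' every returned event is epochable.
#'
#' @param duration Recording duration in seconds.
#' @param interval Inter-pulse interval in seconds (the study design uses 4 s).
#' @param start_offset First-pulse time in seconds.
#' @param pre,post Epoch window half-widths in seconds (defaults 0.5 and 1.0).
#' @param kind Event kind label.
#' @return A tibble with columns `time_s`, `kind`, sorted.
#' @export
#' @examples
#' place_tms_events(120, 4, 0.5)
place_tms_events <- function(duration, interval, start_offset = 0,
                             pre = 0.5, post = 1.0, kind = "tms") {
  if (interval <= 0) abort("interval must be > 0")
  stopifnot(duration > 0, start_offset >= 0)
  times <- seq(start_offset, duration, by = interval)
  times <- times[times - pre >= 0 & times + post <= duration]
  if (length(times) == 0L) {
    abort("duration too short for a single epochable event")
  }
  tibble::tibble(time_s = times, kind = kind)
}

#' Simulate a continuous recording with event-locked dynamics
#'
#' Builds a continuous multichannel series in which the coefficient schedule
#' plays out relative to each event (the schedule's clock is re-zeroed at every
#' event time); between event windows the schedule's first segment (the
#' pre-event baseline) holds.
#'
#' @inheritParams simulate_tvmvar
#' @param duration Total duration in seconds.
#' @param events Event tibble from [place_tms_events()] (or any tibble with a
#'   `time_s` column).
#' @return An [eeg_recording()] with attributes `ground_truth`, `events`,
#'   `seed`.
#' @export
simulate_session <- function(schedule, fs, duration, events, noise_cov = NULL,
                             seed, labels = NULL) {
  stopifnot(inherits(schedule, "coef_schedule"), fs > 0, duration > 0)
  n <- schedule$n_nodes
  p <- schedule$order
  if (is.null(noise_cov)) noise_cov <- diag(n)
  L <- chol_or_abort(noise_cov, n)
  N <- round(duration * fs)
  if (N <= p) abort("duration shorter than the model order in samples")
  if (is.null(labels)) {
    labels <- if (n <= 32) montage_1020_32()[seq_len(n)] else paste0("ch", seq_len(n))
  }
  times <- (seq_len(N) - 1L) / fs
  ev <- sort(events$time_s)
  # per-sample relative time vs the most recent event, NA outside all windows
  rel <- rep(NA_real_, N)
  for (e in ev) {
    k0 <- max(1L, floor((e + schedule$t_start) * fs) + 1L)
    k1 <- min(N, ceiling((e + schedule$t_end) * fs))
    if (k1 >= k0) {
      kk <- k0:k1
      r <- times[kk] - e
      ok <- r >= schedule$t_start & r < schedule$t_end
      rel[kk[ok]] <- r[ok]
    }
  }
  baseline_phi <- do.call(cbind, schedule$segments[[1L]]$A)
  phi_get <- function(k) {
    if (is.na(rel[k])) baseline_phi else do.call(cbind, schedule_at(schedule, rel[k]))
  }
  data <- with_seed_(seed, {
    E <- L %*% matrix(rnorm(n * N), n, N)
    mvar_drive(phi_get, n, p, N, L, E)
  })
  rec <- eeg_recording(data, fs = fs, labels = labels)
  attr(rec, "ground_truth") <- schedule
  attr(rec, "events") <- tibble::tibble(time_s = ev,
                                        kind = rep_len(events$kind %||% "tms",
                                                       length(ev)))
  attr(rec, "seed") <- seed
  rec
}

#' Inject a decaying TMS-like artifact at event times
#'
#' Adds an exponentially decaying transient (amplitude µV, time constant
#' `decay_ms`, support `duration_ms`) to every channel starting at each event
#' time (for recordings) or at epoch time 0 (for epochs). Plumbing for testing
#' artifact interpolation; no physical artifact model is implied.
#'
#' @param x An `eeg_recording` or `eeg_epochs`.
#' @param at_s Event times in seconds (recordings only; epochs use t = 0).
#' @param amplitude Peak amplitude in µV.
#' @param decay_ms Exponential time constant in ms.
#' @param duration_ms Artifact support in ms.
#' @return Object of the same class with the transient added.
#' @export
inject_tms_artifact <- function(x, at_s = NULL, amplitude = 500,
                                decay_ms = 3, duration_ms = 10) {
  kernel <- function(fs) {
    nk <- max(1L, round(duration_ms / 1000 * fs))
    tt <- (seq_len(nk) - 1L) / fs * 1000
    amplitude * exp(-tt / decay_ms)
  }
  if (inherits(x, "eeg_recording")) {
    stopifnot(!is.null(at_s))
    kv <- kernel(x$fs)
    for (e in at_s) {
      k0 <- round(e * x$fs) + 1L
      idx <- k0:min(ncol(x$data), k0 + length(kv) - 1L)
      x$data[, idx] <- x$data[, idx] +
        matrix(kv[seq_along(idx)], nrow(x$data), length(idx), byrow = TRUE)
    }
    x
  } else if (inherits(x, "eeg_epochs")) {
    kv <- kernel(x$fs)
    k0 <- which.min(abs(x$times))
    idx <- k0:min(n_samples(x), k0 + length(kv) - 1L)
    x$data[, , idx] <- sweep(x$data[, , idx, drop = FALSE], 3L,
                             kv[seq_along(idx)], `+`)
    x
  } else {
    abort("x must be an eeg_recording or eeg_epochs")
  }
}
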