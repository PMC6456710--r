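# Adaptive directed transfer function. From the tracked coefficients,
# H(f,t) = [I - sum_i A_i(t) exp(-j 2 pi f i / fs)]^-1; the ADTF is the
# sink-normalized squared magnitude gamma2_ij(f,t) = |H_ij|^2 / sum_m |H_im|^2
# (row i = sink, column j = source), so each sink row sums to one. Band
# integration averages gamma2 over the grid frequencies inside the band, and
# the normalized total information outflow of node j is
# Q_j^2(t) = sum_{k != j} theta_kj(t) / (n - 1).

#' Time-varying transfer function of a fitted MVAR model
#'
#' @param fit A [fit_tvmvar()] object (or a list with elements `A`
#'   (n x n x p x T), `fs`, `times`, `labels`).
#' @param freqs Frequency grid in Hz, within `(0, fs/2]`. Default 1 Hz steps
#'   from 1 to `fs/2 - 1`.
#' @return A `transfer_tensor`: complex array `H` (n x n x F x T), `freqs`,
#'   `times`, `labels`, and `log` (pseudo-inverse fallbacks, if any).
#' @export
transfer_function <- function(fit, freqs = NULL) {
  dims <- dim(fit$A)
  n <- dims[1]; p <- dims[3]; Tn <- dims[4]
  fs <- fit$fs
  if (is.null(freqs)) freqs <- seq(1, fs / 2 - 1, by = 1)
  stopifnot(length(freqs) >= 1, all(freqs >= 0), all(freqs <= fs / 2))
  H <- array(complex(real = 0), dim = c(n, n, length(freqs), Tn))
  logs <- character()
  Id <- diag(n)
  # phase factors exp(-j 2 pi f i / fs) per frequency and lag
  ph <- outer(freqs, seq_len(p), function(f, i) exp(-2i * pi * f * i / fs))
  for (t in seq_len(Tn)) {
    At <- fit$A[, , , t, drop = FALSE]
    for (fi in seq_along(freqs)) {
      Af <- Id
      for (i in seq_len(p)) Af <- Af - At[, , i, 1] * ph[fi, i]
      Hf <- tryCatch(solve(Af), error = function(e) NULL)
      if (is.null(Hf)) {
        logs <- c(logs, sprintf("t=%d f=%g: singular A(f,t), pseudo-inverse used",
                                t, freqs[fi]))
        sv <- svd(Af)
        pos <- sv$d > max(sv$d) * 1e-12
        Hf <- sv$v[, pos, drop = FALSE] %*%
          ((1 / sv$d[pos]) * Conj(t(sv$u[, pos, drop = FALSE])))
      }
      H[, , fi, t] <- Hf
    }
  }
  if (length(logs) > 0) warn(sprintf("%d singular A(f,t) point(s) pseudo-inverted", length(logs)))
  structure(list(H = H, freqs = freqs, times = fit$times,
                 labels = fit$labels %||% paste0("ch", seq_len(n)), fs = fs,
                 log = logs),
            class = "transfer_tensor")
}

#' Sink-normalized ADTF from a transfer tensor
#'
#' @param tf A [transfer_function()] result.
#' @return An `adtf_tensor`: array `gamma2` (n x n x F x T) in `[0, 1]` with
#'   every sink row summing to 1, plus the grids.
#' @export
adtf_normalize <- function(tf) {
  P <- Mod(tf$H)^2
  denom <- apply(P, c(1, 3, 4), sum)   # sink x F x T
  if (any(denom == 0)) abort("degenerate system: a sink row of H is all zero")
  g2 <- P
  for (j in seq_len(dim(P)[2])) g2[, j, , ] <- P[, j, , ] / denom
  structure(list(gamma2 = g2, freqs = tf$freqs, times = tf$times,
                 labels = tf$labels, fs = tf$fs),
            class = "adtf_tensor")
}

#' Band-integrated directed coupling
#'
#' Averages the ADTF over the grid frequencies inside `[band[1], band[2]]`
#' (inclusive), giving theta_ij(t): the directed coupling source j -> sink i.
#'
#' @param adtf An [adtf_normalize()] result.
#' @param band Length-2 numeric, band edges in Hz. Default 1-15 Hz, the full
#'   usable band under the 16-Hz Nyquist of the 32-Hz analysis base.
#' @return A `band_adtf`: array `theta` (n x n x T), `band`, `times`,
#'   `labels`.
#' @export
integrate_band <- function(adtf, band = c(1, 15)) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  sel <- which(adtf$freqs >= band[1] & adtf$freqs <= band[2])
  if (length(sel) == 0L) abort("no grid frequencies inside the band")
  theta <- apply(adtf$gamma2[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  structure(list(theta = theta, band = band, times = adtf$times,
                 labels = adtf$labels, fs = adtf$fs),
            class = "band_adtf")
}

#' @export
print.band_adtf <- function(x, ...) {
  cat(sprintf("<band_adtf> %d nodes x %d time points, band %g-%g Hz\n",
              dim(x$theta)[1], dim(x$theta)[3], x$band[1], x$band[2]))
  invisible(x)
}

#' @export
#' @rdname integrate_band
#' @param x A `band_adtf`.
#' @param ... Unused.
tidy.band_adtf <- function(x, ...) {
  n <- dim(x$theta)[1]; Tn <- dim(x$theta)[3]
  tibble::tibble(
    time_s = rep(x$times, each = n * n),
    sink = rep(rep(x$labels, times = n), times = Tn),
    source = rep(rep(x$labels, each = n), times = Tn),
    theta = as.vector(x$theta)
  ) |> dplyr::filter(.data$sink != .data$source)
}

#' Normalized total information outflow per node
#'
#' The per-node outflow `Q_j^2(t) = sum_{k != j} theta_kj(t) / (n - 1)`: the
#' mean of node j's outgoing band-integrated couplings over the other n - 1
#' nodes. Bounded in `[0, 1]`.
#'
#' @param band_adtf An [integrate_band()] result.
#' @return A tibble (class `outflow_series`) with columns `time_s`, `node`,
#'   `outflow`.
#' @export
total_outflow <- function(band_adtf) {
  th <- band_adtf$theta
  n <- dim(th)[1]
  if (n < 2) abort("outflow needs at least 2 nodes")
  Tn <- dim(th)[3]
  qs <- vapply(seq_len(Tn), function(t) {
    M <- th[, , t]
    (colSums(M) - diag(M)) / (n - 1)
  }, numeric(n))                       # n x T
  out <- tibble::tibble(
    time_s = rep(band_adtf$times, each = n),
    node = rep(band_adtf$labels, times = Tn),
    outflow = as.vector(qs)
  )
  class(out) <- c("outflow_series", class(out))
  out
}

#' Closed-form DTF of a stationary MVAR model
#'
#' The classical (non-adaptive) directed transfer function computed directly
#' from known coefficient matrices — used as the reference when validating the
#' adaptive estimate against ground truth.
#'
#' @param A List of p coefficient matrices (n x n).
#' @param freqs Frequency grid in Hz.
#' @param fs Sampling rate in Hz.
#' @param band Optional band; when given, returns the band-averaged n x n
#'   gamma2 matrix, else the n x n x F array.
#' @return Numeric array of sink-normalized squared transfer magnitudes.
#' @export
dtf_from_coefficients <- function(A, freqs, fs, band = NULL) {
  n <- nrow(A[[1]])
  p <- length(A)
  g2 <- array(0, dim = c(n, n, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(n)
    for (i in seq_len(p)) Af <- Af - A[[i]] * exp(-2i * pi * freqs[fi] * i / fs)
    H <- solve(Af)
    P <- Mod(H)^2
    g2[, , fi] <- P / rowSums(P)
  }
  if (is.null(band)) return(g2)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  apply(g2[, , sel, drop = FALSE], c(1, 2), mean)
}
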