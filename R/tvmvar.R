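# Time-varying multivariate adaptive autoregressive (TV-MVAAR) estimation.
#
# State-space reading: the AR coefficients are a slowly drifting state
# theta_t = theta_{t-1} + w_t, w_t ~ N(0, uc * I), observed through the linear
# regression x(t) = [x(t-1), ..., x(t-p)]' theta + e(t). All trials share the
# time-locked nonstationarity, so at each time point the filter assimilates
# the whole trial ensemble at once (exact stacked-observation Kalman update in
# information form). Forward-only filtering: no smoother.

#' Fit a time-varying MVAR model by Kalman-filter tracking
#'
#' Tracks the coefficient matrices A_1(t)..A_p(t) of
#' `X(t) = sum_i A_i(t) X(t-i) + E(t)` across the epoch. In `"multi-trial"`
#' mode (default) the state update at each time point uses the ensemble of all
#' trials; `"per-trial-average"` filters each trial separately and averages the
#' coefficient trajectories. Deterministic given its inputs.
#'
#' @param epochs An [eeg_epochs()] (zero-mean data assumed; see
#'   [extract_epochs()]).
#' @param order Model order p (>= 1); default 5.
#' @param uc Update coefficient in (0, 1): the random-walk state-noise scale
#'   that sets the adaptation speed. Default 0.01.
#' @param mode `"multi-trial"` or `"per-trial-average"`.
#' @return A `tvmvar_fit`: coefficient array `A` (n x n x p x T_ret), residual
#'   (innovation) covariance array `sigma` (n x n x T_ret), retained `times`
#'   (the first p samples carry no estimate), `fs`, `order`, `uc`, `n_trials`,
#'   and `log` (regularization events).
#' @export
fit_tvmvar <- function(epochs, order = 5L, uc = 0.01,
                       mode = c("multi-trial", "per-trial-average")) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "eeg_epochs"), order >= 1, uc > 0, uc < 1)
  R <- n_trials(epochs)
  n <- n_channels(epochs)
  Tn <- n_samples(epochs)
  p <- as.integer(order)
  if (Tn <= p) abort("epoch has no samples beyond the model order")
  if (mode == "per-trial-average") {
    fits <- purrr::map(seq_len(R), function(r) {
      one <- eeg_epochs(epochs$data[r, , , drop = FALSE], epochs$fs,
                        epochs$times, epochs$labels)
      kalman_mvar(one$data, p, uc)
    })
    A <- Reduce(`+`, purrr::map(fits, "A")) / R
    sigma <- Reduce(`+`, purrr::map(fits, "sigma")) / R
    logs <- unlist(purrr::map(fits, "log"))
  } else {
    k <- kalman_mvar(epochs$data, p, uc)
    A <- k$A; sigma <- k$sigma; logs <- k$log
  }
  structure(list(A = A, sigma = sigma, times = epochs$times[(p + 1L):Tn],
                 fs = epochs$fs, order = p, uc = uc, n_trials = R,
                 labels = epochs$labels, mode = mode, log = logs),
            class = "tvmvar_fit")
}

# Core filter on a trials x channels x samples array.
kalman_mvar <- function(data, p, uc) {
  R <- dim(data)[1]; n <- dim(data)[2]; Tn <- dim(data)[3]
  d <- n * p
  Theta <- matrix(0, d, n)        # column j predicts channel j
  P <- diag(d)                    # shared state covariance, init identity
  T_ret <- Tn - p
  A <- array(0, dim = c(n, n, p, T_ret))
  sigma <- array(0, dim = c(n, n, T_ret))
  logs <- character()
  Id <- diag(d)
  for (t in (p + 1L):Tn) {
    # Z: trials x d design of lagged samples [x(t-1), ..., x(t-p)]
    Z <- matrix(0, R, d)
    for (i in seq_len(p)) {
      Z[, ((i - 1L) * n + 1L):(i * n)] <- data[, , t - i, drop = FALSE]
    }
    Y <- matrix(data[, , t], R, n)
    innov <- Y - Z %*% Theta
    S_t <- crossprod(innov) / R
    r_t <- mean(diag(S_t))
    if (r_t < 1e-12) {
      if (sum(abs(Y)) > 0 || sum(abs(Z)) > 0) {
        logs <- c(logs, sprintf("t=%d: innovation variance floored", t))
      }
      r_t <- 1e-12
    }
    P <- P + uc * Id
    # information-form stacked update: P_new = (P^-1 + Z'Z / r)^-1
    G <- crossprod(Z) / r_t
    M <- Id + P %*% G
    P_new <- solve(M, P)
    P_new <- (P_new + t(P_new)) / 2
    Theta <- Theta + P_new %*% (crossprod(Z, innov) / r_t)
    P <- P_new
    k <- t - p
    for (i in seq_len(p)) {
      A[, , i, k] <- t(Theta[((i - 1L) * n + 1L):(i * n), , drop = FALSE])
    }
    sigma[, , k] <- S_t
  }
  list(A = A, sigma = sigma, log = logs)
}

#' @export
print.tvmvar_fit <- function(x, ...) {
  cat(sprintf("<tvmvar_fit> %d nodes, order %d, %d time points @ %g Hz, uc %g, %d trial(s), %s\n",
              dim(x$A)[1], x$order, dim(x$A)[4], x$fs, x$uc, x$n_trials, x$mode))
  invisible(x)
}

#' @export
#' @rdname fit_tvmvar
#' @param x A `tvmvar_fit`.
#' @param ... Unused.
tidy.tvmvar_fit <- function(x, ...) {
  dims <- dim(x$A)
  n <- dims[1]; p <- dims[3]; Tn <- dims[4]
  tibble::tibble(
    time_s = rep(x$times, each = n * n * p),
    lag = rep(rep(seq_len(p), each = n * n), times = Tn),
    sink = rep(rep(x$labels, times = n), times = p * Tn),
    source = rep(rep(x$labels, each = n), times = p * Tn),
    estimate = as.vector(x$A)
  )
}

#' @export
#' @rdname fit_tvmvar
glance.tvmvar_fit <- function(x, ...) {
  sig_bar <- apply(x$sigma, c(1, 2), mean)
  tibble::tibble(n_nodes = dim(x$A)[1], order = x$order, uc = x$uc,
                 n_trials = x$n_trials, n_times = dim(x$A)[4],
                 mean_resid_var = mean(diag(sig_bar)),
                 logdet_resid = determinant(sig_bar)$modulus[[1]])
}

#' Select the model order by AIC
#'
#' Fits each candidate order and scores it with the Akaike information
#' criterion of the time-averaged residual covariance:
#' `AIC(p) = log det(Sigma_bar) + 2 p n^2 / N_obs`, with
#' `N_obs = n_trials * retained time points`. The order minimizing AIC wins.
#'
#' @inheritParams fit_tvmvar
#' @param candidates Integer vector of candidate orders.
#' @return List with `order` (the winner p*) and `criteria` (tibble of
#'   `order`, `aic`, `logdet`).
#' @export
select_model_order <- function(epochs, candidates = 1:8, uc = 0.01,
                               mode = "multi-trial") {
  stopifnot(length(candidates) >= 1)
  rows <- purrr::map(sort(unique(as.integer(candidates))), function(p) {
    fit <- tryCatch(fit_tvmvar(epochs, order = p, uc = uc, mode = mode),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    n <- dim(fit$A)[1]
    # drop the adaptation transient: score on the second half of the epoch
    Tn <- dim(fit$sigma)[3]
    keep <- seq.int(max(1L, floor(Tn / 2)), Tn)
    sig_bar <- apply(fit$sigma[, , keep, drop = FALSE], c(1, 2), mean)
    ld <- determinant(sig_bar)$modulus[[1]]
    n_obs <- fit$n_trials * length(keep)
    tibble::tibble(order = p, logdet = ld,
                   aic = ld + 2 * p * n^2 / n_obs)
  })
  criteria <- dplyr::bind_rows(rows)
  if (nrow(criteria) == 0L) abort("all candidate orders failed to fit")
  list(order = criteria$order[which.min(criteria$aic)], criteria = criteria)
}
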