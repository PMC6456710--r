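# Network dynamics on time-varying directed graphs: surrogate-calibrated edge
# thresholds, binarization, key-node (hub) trajectories, enhanced/weakened
# edge classification against a pre-event baseline, scalp-region aggregation
# and modularity partitioning.

band_adtf_from_epochs <- function(epochs, order, uc, freqs, band, mode = "multi-trial") {
  fit <- fit_tvmvar(epochs, order = order, uc = uc, mode = mode)
  integrate_band(adtf_normalize(transfer_function(fit, freqs)), band)
}

#' Surrogate-data edge thresholds
#'
#' Builds a null distribution of the band-integrated coupling by independently
#' shuffling the trial order of every channel (destroying inter-channel
#' coupling while preserving each channel's per-trial spectra), re-running the
#' fit -> ADTF -> band pipeline on each surrogate, and taking per edge and time
#' point the k-th order statistic with `k = ceiling((1 - alpha) * (S + 1))` —
#' under exchangeability the exceedance probability is `(S + 1 - k)/(S + 1)
#' <= alpha` exactly.
#'
#' @param epochs An [eeg_epochs()] (>= 10 trials).
#' @param order,uc TV-MVAR settings, as in [fit_tvmvar()].
#' @param freqs Frequency grid (default as in [transfer_function()]).
#' @param band Integration band, as in [integrate_band()].
#' @param n_surrogates Number of surrogates S (>= 20).
#' @param alpha Per-edge-and-time exceedance level.
#' @param seed Integer seed.
#' @return An `edge_threshold`: array `value` (n x n x T) plus the method
#'   record (`alpha`, `n_surrogates`, `seed`).
#' @export
surrogate_threshold <- function(epochs, order = 5L, uc = 0.01, freqs = NULL,
                                band = c(1, 15), n_surrogates = 200L,
                                alpha = 0.05, seed) {
  stopifnot(inherits(epochs, "eeg_epochs"), n_surrogates >= 20L,
            alpha > 0, alpha <= 1)
  R <- n_trials(epochs)
  if (R < 10L) abort("surrogate thresholding needs at least 10 trials")
  n <- n_channels(epochs)
  tret <- epochs$times[(order + 1L):n_samples(epochs)]
  if (alpha >= 1) {
    # every edge passes: the (1 - alpha) quantile of a nonnegative statistic
    return(structure(list(
      value = array(0, dim = c(n, n, length(tret))),
      method = "trial-shuffle surrogate", alpha = alpha,
      n_surrogates = n_surrogates, seed = seed, times = tret,
      labels = epochs$labels), class = "edge_threshold"))
  }
  vals <- with_seed_(seed, {
    purrr::map(seq_len(n_surrogates), function(s) {
      perm_data <- epochs$data
      for (c_ in seq_len(n)) {
        perm_data[, c_, ] <- epochs$data[sample.int(R), c_, ]
      }
      sur <- eeg_epochs(perm_data, epochs$fs, epochs$times, epochs$labels)
      band_adtf_from_epochs(sur, order, uc, freqs, band)$theta
    })
  })
  arr <- array(unlist(vals), dim = c(dim(vals[[1]]), n_surrogates))
  k <- max(1L, min(n_surrogates, ceiling((1 - alpha) * (n_surrogates + 1))))
  thr <- apply(arr, c(1, 2, 3), function(v) sort(v, partial = k)[k])
  structure(list(value = thr, method = "trial-shuffle surrogate",
                 alpha = alpha, n_surrogates = n_surrogates, seed = seed,
                 times = tret, labels = epochs$labels),
            class = "edge_threshold")
}

#' Binarize a time-varying network
#'
#' Edge source j -> sink k is present at time t iff `theta[k, j, t] >
#' threshold[k, j, t]`. The diagonal is always absent.
#'
#' @param band_adtf An [integrate_band()] result.
#' @param thresholds Scalar, n x n matrix, n x n x T array, or an
#'   [surrogate_threshold()] object.
#' @return An `edge_presence`: logical array `present` (n x n x T) plus the
#'   threshold record.
#' @export
binarize_edges <- function(band_adtf, thresholds) {
  th <- band_adtf$theta
  record <- list(method = "fixed", value = thresholds)
  if (inherits(thresholds, "edge_threshold")) {
    record <- thresholds[c("method", "alpha", "n_surrogates", "seed")]
    thresholds <- thresholds$value
  }
  d <- dim(th)
  thr <- if (length(thresholds) == 1L) {
    array(thresholds, dim = d)
  } else if (is.matrix(thresholds)) {
    stopifnot(all(dim(thresholds) == d[1:2]))
    array(thresholds, dim = d)
  } else {
    stopifnot(all(dim(thresholds) == d))
    thresholds
  }
  present <- th > thr
  for (i in seq_len(d[1])) present[i, i, ] <- FALSE
  structure(list(present = present, threshold = record,
                 times = band_adtf$times, labels = band_adtf$labels),
            class = "edge_presence")
}

#' Key-node trajectory of a thresholded time-varying network
#'
#' At each time point the key node is the node with the highest total degree
#' (in + out) in the binarized graph; ties break first by larger summed
#' outflow Q_j^2(t), then by channel order. Time points whose graph is empty
#' have no key node (NA, reported). A conversion is recorded whenever the key
#' node changes between consecutive defined time points.
#'
#' @param presence A [binarize_edges()] result.
#' @param band_adtf The matching [integrate_band()] result (for the outflow
#'   tie-break).
#' @return A `key_node_trajectory`: `$trajectory` tibble (`time_s`,
#'   `key_node`, `degree`, `outflow`) and `$conversions` tibble (`time_s`,
#'   `from`, `to`).
#' @export
key_node_trajectory <- function(presence, band_adtf) {
  pr <- presence$present
  n <- dim(pr)[1]; Tn <- dim(pr)[3]
  q <- total_outflow(band_adtf)
  qmat <- matrix(q$outflow, n, Tn)     # node x time
  key <- integer(Tn); deg <- integer(Tn); outf <- numeric(Tn)
  for (t in seq_len(Tn)) {
    M <- pr[, , t]
    degs <- colSums(M) + rowSums(M)    # out (column source) + in (row sink)
    if (all(degs == 0L)) {
      key[t] <- NA_integer_; deg[t] <- 0L; outf[t] <- NA_real_
      next
    }
    best <- which(degs == max(degs))
    if (length(best) > 1L) {
      best <- best[order(-qmat[best, t], best)]
    }
    key[t] <- best[1L]
    deg[t] <- max(degs)
    outf[t] <- qmat[best[1L], t]
  }
  traj <- tibble::tibble(time_s = presence$times,
                         key_node = ifelse(is.na(key), NA_character_,
                                           presence$labels[key]),
                         degree = deg, outflow = outf)
  defined <- which(!is.na(key))
  conv <- tibble::tibble(time_s = numeric(), from = character(), to = character())
  if (length(defined) > 1L) {
    ch <- defined[-1L][key[defined[-1L]] != key[defined[-length(defined)]]]
    if (length(ch) > 0L) {
      prev <- vapply(ch, function(i) max(defined[defined < i]), 1L)
      conv <- tibble::tibble(time_s = presence$times[ch],
                             from = presence$labels[key[prev]],
                             to = presence$labels[key[ch]])
    }
  }
  structure(list(trajectory = traj, conversions = conv,
                 n_undefined = sum(is.na(key))),
            class = "key_node_trajectory")
}

#' @export
print.key_node_trajectory <- function(x, ...) {
  cat(sprintf("<key_node_trajectory> %d time points, %d conversion(s), %d undefined\n",
              nrow(x$trajectory), nrow(x$conversions), x$n_undefined))
  invisible(x)
}

#' @export
#' @rdname key_node_trajectory
#' @param x A `key_node_trajectory`.
#' @param ... Unused.
tidy.key_node_trajectory <- function(x, ...) x$trajectory

run_intervals <- function(state, min_run) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= min_run
  tibble::tibble(value = r$values[keep], start = starts[keep], end = ends[keep])
}

#' Classify enhanced and weakened edge dynamics
#'
#' Per directed edge, the post-event coupling trajectory is compared with the
#' pre-event baseline distribution (theta values at baseline time points):
#' a contiguous run of at least `min_run` analysis samples above the baseline
#' `1 - alpha/2` quantile is an *enhanced* interval, below the `alpha/2`
#' quantile a *weakened* interval; edges with neither are *unchanged*. Onset
#' and offset are the run boundaries in seconds; the effect size is the run
#' mean minus the baseline mean.
#'
#' @param band_adtf An [integrate_band()] result.
#' @param baseline_window Length-2 seconds, entirely before 0. Default
#'   `c(-0.5, -0.05)` (guard gap before the pulse).
#' @param analysis_window Length-2 seconds, at or after 0. Default 0 to the
#'   epoch end.
#' @param alpha Two-sided level for the baseline percentile band.
#' @param min_run Minimum run length in samples (default 3).
#' @return A tibble (class `edge_dynamics`) with one row per detected
#'   interval: `source`, `sink`, `class`, `onset_s`, `offset_s`,
#'   `effect_size`; unchanged edges get one row with NA interval. Edges with a
#'   zero-variance baseline are skipped and flagged in attribute `skipped`.
#' @export
classify_edge_dynamics <- function(band_adtf,
                                   baseline_window = c(-0.5, -0.05),
                                   analysis_window = NULL,
                                   alpha = 0.05, min_run = 3L) {
  tms <- band_adtf$times
  stopifnot(baseline_window[1] < baseline_window[2], baseline_window[2] <= 0)
  if (is.null(analysis_window)) analysis_window <- c(0, max(tms))
  stopifnot(analysis_window[1] >= 0)
  base_idx <- which(tms >= baseline_window[1] & tms <= baseline_window[2])
  ana_idx <- which(tms >= analysis_window[1] & tms <= analysis_window[2])
  if (length(base_idx) < 3L) abort("baseline window holds fewer than 3 samples")
  if (length(ana_idx) == 0L) abort("no analysis samples at or after the event")
  th <- band_adtf$theta
  n <- dim(th)[1]
  dt <- if (length(tms) > 1) tms[2] - tms[1] else 1 / band_adtf$fs
  rows <- list(); skipped <- character()
  for (j in seq_len(n)) {       # source
    for (k in seq_len(n)) {     # sink
      if (j == k) next
      base <- th[k, j, base_idx]
      if (sd(base) == 0) {
        skipped <- c(skipped, sprintf("%s->%s", band_adtf$labels[j],
                                      band_adtf$labels[k]))
        next
      }
      hi <- quantile(base, 1 - alpha / 2, names = FALSE)
      lo <- quantile(base, alpha / 2, names = FALSE)
      x <- th[k, j, ana_idx]
      state <- ifelse(x > hi, 1L, ifelse(x < lo, -1L, 0L))
      runs <- run_intervals(state, min_run)
      if (nrow(runs) == 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          source = band_adtf$labels[j], sink = band_adtf$labels[k],
          class = "unchanged", onset_s = NA_real_, offset_s = NA_real_,
          effect_size = mean(x) - mean(base))
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          source = band_adtf$labels[j], sink = band_adtf$labels[k],
          class = ifelse(runs$value > 0L, "enhanced", "weakened"),
          onset_s = tms[ana_idx[runs$start]],
          offset_s = tms[ana_idx[runs$end]] + dt,
          effect_size = vapply(seq_len(nrow(runs)), function(i)
            mean(x[runs$start[i]:runs$end[i]]) - mean(base), 0))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("edge_dynamics", class(out))
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  out
}

#' Aggregate a directed network to scalp regions
#'
#' Maps every channel to a `{left, right, mid} x {frontal, central, temporal,
#' parietal, occipital}` region via [channel_regions()] and averages theta over
#' all directed channel pairs between two regions (self-pairs excluded).
#'
#' @param band_adtf An [integrate_band()] result with 10/20 channel labels.
#' @return A tibble (class `region_network`) with `time_s`, `source_region`,
#'   `sink_region`, `theta`.
#' @export
aggregate_regions <- function(band_adtf) {
  reg <- channel_regions(band_adtf$labels)
  long <- tidy.band_adtf(band_adtf)
  out <- long |>
    dplyr::left_join(dplyr::select(reg, channel, source_region = "region"),
                     by = c(source = "channel")) |>
    dplyr::left_join(dplyr::select(reg, channel, sink_region = "region"),
                     by = c(sink = "channel")) |>
    dplyr::group_by(.data$time_s, .data$source_region, .data$sink_region) |>
    dplyr::summarise(theta = mean(.data$theta), .groups = "drop")
  class(out) <- c("region_network", class(out))
  out
}

#' Partition nodes into modules by modularity maximization
#'
#' Symmetrizes the time-averaged coupling over the window
#' (`(theta_jk + theta_kj)/2`, diagonal removed) and runs deterministic greedy
#' (agglomerative) modularity maximization on the weighted undirected graph.
#' A graph with no edges returns singleton modules with modularity 0.
#'
#' @param band_adtf An [integrate_band()] result.
#' @param window Length-2 seconds; theta is averaged over times inside it.
#'   Default: the whole epoch.
#' @return A `module_partition`: `$membership` tibble (`node`, `module`) and
#'   `$q_mod` (modularity of the returned partition).
#' @export
detect_modules <- function(band_adtf, window = NULL) {
  tms <- band_adtf$times
  if (is.null(window)) window <- range(tms)
  sel <- which(tms >= window[1] & tms <= window[2])
  if (length(sel) == 0L) abort("empty module window")
  W <- apply(band_adtf$theta[, , sel, drop = FALSE], c(1, 2), mean)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  n <- nrow(W)
  if (all(W == 0)) {
    membership <- seq_len(n)
    q <- 0
  } else {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    cl <- igraph::cluster_fast_greedy(g)
    qual <- function(m) igraph::modularity(g, m, weights = igraph::E(g)$weight)
    # the greedy dendrogram can miss the trivial optima; compare against them
    cands <- list(as.integer(igraph::membership(cl)), rep(1L, n), seq_len(n))
    qs <- vapply(cands, qual, 0)
    best <- which.max(qs)
    membership <- cands[[best]]
    q <- qs[best]
  }
  structure(list(membership = tibble::tibble(node = band_adtf$labels,
                                             module = membership),
                 q_mod = q, window = window),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d module(s), Q_mod = %.4f\n",
              length(unique(x$membership$module)), x$q_mod))
  invisible(x)
}

#' @export
#' @rdname detect_modules
#' @param x A `module_partition`.
#' @param ... Unused.
tidy.module_partition <- function(x, ...) x$membership

#' Rand index between two partitions
#'
#' Fraction of node pairs on which two partitions agree (same/different
#' module). Used to score recovered against planted partitions.
#'
#' @param a,b Integer or factor membership vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  pairs <- utils::combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
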