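# Time-varying MVAR coefficient schedules: the generative counterpart of the
# TV-MVAAR estimator. Piecewise-constant coefficient matrices with optional
# linear ramps at segment boundaries; every segment must be stable.

companion_spectral_radius <- function(A) {
  p <- length(A)
  n <- nrow(A[[1]])
  comp <- matrix(0, n * p, n * p)
  comp[seq_len(n), ] <- do.call(cbind, A)
  if (p > 1) {
    comp[cbind(n + seq_len(n * (p - 1)), seq_len(n * (p - 1)))] <- 1
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

edge_df <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(tibble::tibble(source = integer(), sink = integer(),
                          lag = integer(), weight = numeric()))
  }
  if (!is.data.frame(x)) {
    x <- purrr::map_dfr(x, function(e) {
      e <- as.list(e)
      names(e) <- c("source", "sink", "lag", "weight")[seq_along(e)]
      tibble::as_tibble(e)
    })
  }
  stopifnot(all(c("source", "sink", "lag", "weight") %in% names(x)))
  tibble::as_tibble(x)
}

#' Build a piecewise time-varying MVAR coefficient schedule
#'
#' Defines ground-truth dynamics for the simulator: a set of base directed
#' couplings (source -> sink at a given lag) that hold everywhere, plus timed
#' perturbations that override an edge's weight inside a window. Weight
#' changes are instantaneous (`"step"`) or linearly ramped over `ramp_s`
#' starting at each boundary (`"ramp"`). Every constant segment must be stable
#' (companion-matrix spectral radius < 1).
#'
#' @param n_nodes Number of nodes (channels).
#' @param order Model order p (number of lags).
#' @param base_edges Data frame (or list of vectors) with columns
#'   `source`, `sink`, `lag`, `weight`. `source -> sink` places the weight in
#'   row `sink`, column `source` of the lag matrix. Self-edges give nodes their
#'   own spectral content.
#' @param perturbations Data frame with columns `source`, `sink`, `lag`,
#'   `weight`, `start`, `end` (seconds): the edge takes `weight` on
#'   `[start, end)`. Windows for the same edge must not overlap.
#' @param t_start,t_end Schedule time span in seconds (may be negative; in
#'   event-locked use, 0 is the event).
#' @param transition `"step"` or `"ramp"`.
#' @param ramp_s Ramp duration in seconds (used when `transition = "ramp"`).
#' @return A `coef_schedule` object: segments tiling `[t_start, t_end]`, each
#'   with its list of p coefficient matrices.
#' @export
#' @examples
#' sched <- build_coefficient_schedule(
#'   3, 1,
#'   base_edges = data.frame(source = c(1, 2, 3, 1), sink = c(1, 2, 3, 2),
#'                           lag = 1, weight = c(0.5, 0.5, 0.5, 0.4)),
#'   perturbations = data.frame(source = 1, sink = 2, lag = 1, weight = 0,
#'                              start = 0.076, end = 0.45),
#'   t_start = -0.5, t_end = 1
#' )
build_coefficient_schedule <- function(n_nodes, order, base_edges = NULL,
                                       perturbations = NULL,
                                       t_start = -0.5, t_end = 1,
                                       transition = c("step", "ramp"),
                                       ramp_s = 0.05) {
  transition <- match.arg(transition)
  stopifnot(n_nodes >= 1, order >= 1, t_end > t_start)
  base <- edge_df(base_edges)
  pert <- edge_df(perturbations)
  if (nrow(pert) > 0L) {
    stopifnot(all(c("start", "end") %in% names(pert)), all(pert$end > pert$start))
  }
  chk <- dplyr::bind_rows(base, pert[c("source", "sink", "lag", "weight")])
  if (nrow(chk) > 0L &&
      (any(chk$source < 1 | chk$source > n_nodes) ||
       any(chk$sink < 1 | chk$sink > n_nodes) ||
       any(chk$lag < 1 | chk$lag > order))) {
    abort("edge references a node or lag outside the model")
  }
  if (nrow(pert) > 1L) {
    key <- paste(pert$source, pert$sink, pert$lag)
    for (k in unique(key)) {
      w <- pert[key == k, ]
      w <- w[order(w$start), ]
      if (nrow(w) > 1L && any(w$start[-1] < w$end[-nrow(w)])) {
        abort(sprintf("overlapping perturbations on edge %s", k))
      }
    }
  }

  cuts <- if (nrow(pert) > 0L) c(pert$start, pert$end) else numeric()
  breaks <- sort(unique(c(t_start, t_end, cuts[cuts > t_start & cuts < t_end])))
  mats_at <- function(tm) {
    A <- replicate(order, matrix(0, n_nodes, n_nodes), simplify = FALSE)
    if (nrow(base) > 0L) {
      for (r in seq_len(nrow(base))) {
        A[[base$lag[r]]][base$sink[r], base$source[r]] <- base$weight[r]
      }
    }
    if (nrow(pert) > 0L) {
      act <- pert$start <= tm & tm < pert$end
      for (r in which(act)) {
        A[[pert$lag[r]]][pert$sink[r], pert$source[r]] <- pert$weight[r]
      }
    }
    A
  }
  segments <- purrr::map(seq_len(length(breaks) - 1L), function(i) {
    A <- mats_at(breaks[i])
    rho <- companion_spectral_radius(A)
    if (rho >= 1) {
      abort(sprintf(
        "unstable segment %d ([%.4g, %.4g] s): companion spectral radius %.4f >= 1",
        i, breaks[i], breaks[i + 1L], rho))
    }
    list(start = breaks[i], end = breaks[i + 1L], A = A)
  })
  structure(list(n_nodes = n_nodes, order = order, segments = segments,
                 transition = transition, ramp_s = ramp_s,
                 t_start = t_start, t_end = t_end,
                 base_edges = base, perturbations = pert),
            class = "coef_schedule")
}

#' @export
print.coef_schedule <- function(x, ...) {
  cat(sprintf("<coef_schedule> %d nodes, order %d, %d segment(s) on [%.4g, %.4g] s, %s transitions\n",
              x$n_nodes, x$order, length(x$segments), x$t_start, x$t_end, x$transition))
  invisible(x)
}

#' Evaluate a coefficient schedule
#'
#' @param schedule A `coef_schedule`.
#' @param t Time in seconds (scalar). Times outside the span clamp to the
#'   nearest segment.
#' @return List of p coefficient matrices A_1..A_p at time `t`.
#' @export
schedule_at <- function(schedule, t) {
  segs <- schedule$segments
  starts <- vapply(segs, `[[`, 0, "start")
  i <- findInterval(t, starts, rightmost.closed = FALSE)
  i <- max(1L, min(i, length(segs)))
  A <- segs[[i]]$A
  if (schedule$transition == "ramp" && i > 1L && schedule$ramp_s > 0) {
    dt <- t - segs[[i]]$start
    if (dt < schedule$ramp_s) {
      w <- dt / schedule$ramp_s
      prev <- segs[[i - 1L]]$A
      A <- purrr::map2(prev, A, function(a0, a1) (1 - w) * a0 + w * a1)
    }
  }
  A
}

# Stacked coefficient matrix [A_1 ... A_p] (n x n*p) per sample time; returns a
# list with per-sample segment ids and the unique stacked matrices, so the
# simulator avoids re-evaluating the schedule inside its sample loop.
schedule_phi_lookup <- function(schedule, times) {
  segs <- schedule$segments
  starts <- vapply(segs, `[[`, 0, "start")
  idx <- pmax(1L, pmin(findInterval(times, starts), length(segs)))
  phis <- purrr::map(segs, function(s) do.call(cbind, s$A))
  ramp <- schedule$transition == "ramp" && schedule$ramp_s > 0
  get_phi <- function(k) {
    i <- idx[k]
    if (ramp && i > 1L) {
      dt <- times[k] - segs[[i]]$start
      if (dt < schedule$ramp_s) {
        w <- dt / schedule$ramp_s
        return((1 - w) * phis[[i - 1L]] + w * phis[[i]])
      }
    }
    phis[[i]]
  }
  list(idx = idx, phis = phis, get = get_phi)
}
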