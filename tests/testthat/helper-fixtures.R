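# Shared builders for ground-truthed fixtures. Everything is generated in
# code at test time; seeds are fixed per test.

# stationary scheme: self-dynamics on every node plus the given cross edges
sched_with_edges <- function(n, cross = NULL, diag_w = 0.5,
                             t_start = -0.5, t_end = 1, order = 1,
                             perturbations = NULL) {
  base <- data.frame(source = seq_len(n), sink = seq_len(n), lag = 1,
                     weight = diag_w)
  if (!is.null(cross)) base <- rbind(base, cross)
  build_coefficient_schedule(n, order, base, perturbations,
                             t_start = t_start, t_end = t_end)
}

# the weakened-then-enhanced pattern: edge 1 -> 2 drops 0.4 -> 0 on
# [0.076, 0.45] s, then rises to 0.6 on [0.45, 1.0] s
sched_weaken_enhance <- function() {
  sched_with_edges(
    3,
    cross = data.frame(source = 1, sink = 2, lag = 1, weight = 0.4),
    perturbations = data.frame(source = 1, sink = 2, lag = 1,
                               weight = c(0, 0.6),
                               start = c(0.076, 0.45), end = c(0.45, 1.0))
  )
}

# planted two-block schedule (blocks 1:4 and 5:8) at within/between ratio 3
sched_two_blocks <- function(w_in = 0.18, ratio = 3, diag_w = 0.3) {
  blocks <- list(1:4, 5:8)
  base <- data.frame(source = 1:8, sink = 1:8, lag = 1, weight = diag_w)
  for (b in blocks) {
    for (i in b) for (j in b) {
      if (i != j) base <- rbind(base, data.frame(source = i, sink = j,
                                                 lag = 1, weight = w_in))
    }
  }
  base <- rbind(base, data.frame(source = c(1, 5), sink = c(5, 1), lag = 1,
                                 weight = w_in / ratio))
  build_coefficient_schedule(8, 1, base, t_start = 0, t_end = 1.5)
}

# simulate -> fit -> band-integrated ADTF in one step
band_from_sched <- function(sched, n_trials, seed, order = 1, uc = 0.01,
                            fs = 32, band = c(1, 15)) {
  ep <- simulate_tvmvar(sched, fs = fs, n_trials = n_trials, seed = seed)
  fit <- fit_tvmvar(ep, order = order, uc = uc)
  integrate_band(adtf_normalize(transfer_function(fit)), band)
}

# hand-built band_adtf around a theta array (sink x source x time)
make_band_adtf <- function(theta, fs = 32, times = NULL, labels = NULL,
                           band = c(1, 15)) {
  n <- dim(theta)[1]
  if (is.null(times)) times <- seq(-0.5 + 1 / fs, by = 1 / fs,
                                   length.out = dim(theta)[3])
  if (is.null(labels)) labels <- montage_1020_32()[seq_len(n)]
  structure(list(theta = theta, band = band, times = times, labels = labels,
                 fs = fs), class = "band_adtf")
}

# independent brute-force scan for same-parity triplet completions
scan_triplets <- function(digits) {
  hits <- integer()
  for (i in seq_along(digits)) {
    if (i >= 3 &&
        digits[i] %% 2 == digits[i - 1] %% 2 &&
        digits[i - 1] %% 2 == digits[i - 2] %% 2) {
      hits <- c(hits, i)
    }
  }
  hits
}
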