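# Attention-task stimulus streams and simulated behavior. Three task kinds:
# visual (watch digits 0-9, no targets), selective (respond to "0"),
# sustained (respond to the third of three consecutive same-parity digits,
# digits 1-9). Target counts are exact by construction and re-verifiable by
# brute-force scans.

# completions of same-parity triplets (1-based index of the third digit)
triplet_completions <- function(digits) {
  if (length(digits) < 3L) return(integer())
  par <- digits %% 2L
  idx <- 3:length(digits)
  idx[par[idx] == par[idx - 1L] & par[idx - 1L] == par[idx - 2L]]
}

sample_target_positions <- function(n_stimuli, n_targets, min_spacing, min_pos) {
  if (n_targets == 0L) return(integer())
  if (min_pos + (n_targets - 1L) * min_spacing > n_stimuli) {
    abort("infeasible target constraints: too many targets for the block length and spacing")
  }
  # exact gap construction: draw unconstrained sorted positions in a shrunk
  # index space, then re-expand so consecutive targets are >= min_spacing
  # apart (uniform over all valid placements)
  shrink <- n_stimuli - (n_targets - 1L) * (min_spacing - 1L)
  x <- sort(sample(min_pos:shrink, n_targets))
  x + (seq_len(n_targets) - 1L) * (min_spacing - 1L)
}

# Parity sequence with exactly the planted same-parity-triplet completions:
# positions t-2,t-1,t share the target parity; t-3 and t+1 (when present) take
# the opposite parity; free positions are drawn but forced to flip whenever a
# run of three same-parity digits would arise outside a target.
sustained_parities <- function(n, targets) {
  par <- rep(NA_integer_, n)
  for (t in targets) {
    p <- sample(0:1, 1L)
    par[(t - 2L):t] <- p
    if (t - 3L >= 1L) par[t - 3L] <- 1L - p
    if (t + 1L <= n) par[t + 1L] <- 1L - p
  }
  for (k in seq_len(n)) {
    if (!is.na(par[k])) next
    cand <- c(0L, 1L)
    if (k >= 3L && !is.na(par[k - 1L]) && !is.na(par[k - 2L]) &&
        par[k - 1L] == par[k - 2L]) {
      cand <- setdiff(cand, par[k - 1L])
    }
    if (k >= 2L && k < n && !is.na(par[k + 1L]) && !is.na(par[k - 1L]) &&
        par[k - 1L] == par[k + 1L]) {
      # drawing that parity would complete a run of three ending at the forced
      # neighbour k + 1
      cand <- setdiff(cand, par[k + 1L])
    }
    par[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  par
}

#' Generate an attention-task digit stream
#'
#' Digits at a constant onset-to-onset interval (`soa`), organized in blocks
#' with a rest gap between blocks. Task kinds: `"visual"` (digits 0-9 uniform,
#' nothing marked), `"selective"` (exactly `targets_per_block` digit-0 targets
#' per block, no accidental zeros elsewhere), `"sustained"` (digits 1-9 with
#' exactly `targets_per_block` same-parity-triplet completions per block and
#' none elsewhere). Targets are separated by at least `min_spacing` stimuli.
#'
#' @param task_kind `"visual"`, `"selective"` or `"sustained"`.
#' @param n_blocks Number of blocks.
#' @param stimuli_per_block Stimuli per block (study design: 200).
#' @param targets_per_block Targets per block (study design: 8; ignored for
#'   `"visual"`).
#' @param soa Onset-to-onset interval in seconds (study design: 0.6).
#' @param min_spacing Minimum stimuli between consecutive targets.
#' @param rest_s Rest gap between blocks in seconds.
#' @param seed Integer seed.
#' @return A tibble with columns `block`, `index`, `onset_s`, `digit`,
#'   `is_target`, `task_kind`.
#' @export
#' @examples
#' s <- generate_stimulus_stream("selective", n_blocks = 1, seed = 1)
#' sum(s$digit == 0)
generate_stimulus_stream <- function(task_kind = c("visual", "selective", "sustained"),
                                     n_blocks = 4, stimuli_per_block = 200,
                                     targets_per_block = 8, soa = 0.6,
                                     min_spacing = 10, rest_s = 60, seed) {
  task_kind <- match.arg(task_kind)
  stopifnot(n_blocks >= 1, stimuli_per_block >= 1, soa > 0,
            targets_per_block >= 0)
  with_seed_(seed, {
    blocks <- purrr::map(seq_len(n_blocks), function(b) {
      N <- stimuli_per_block
      if (task_kind == "visual") {
        digits <- sample(0:9, N, replace = TRUE)
        is_target <- rep(FALSE, N)
      } else if (task_kind == "selective") {
        pos <- sample_target_positions(N, targets_per_block, min_spacing, 1L)
        digits <- sample(1:9, N, replace = TRUE)
        digits[pos] <- 0L
        is_target <- digits == 0L
      } else {
        pos <- sample_target_positions(N, targets_per_block, min_spacing, 3L)
        for (a in seq_len(100L)) {
          par <- sustained_parities(N, pos)
          digits <- ifelse(par == 1L,
                           sample(c(1L, 3L, 5L, 7L, 9L), N, replace = TRUE),
                           sample(c(2L, 4L, 6L, 8L), N, replace = TRUE))
          if (identical(triplet_completions(digits), as.integer(pos))) break
          if (a == 100L) abort("could not realize the planted triplet structure")
        }
        is_target <- seq_len(N) %in% pos
      }
      block_t0 <- (b - 1L) * (stimuli_per_block * soa + rest_s)
      tibble::tibble(block = b, index = seq_len(N),
                     onset_s = block_t0 + (seq_len(N) - 1L) * soa,
                     digit = as.integer(digits), is_target = is_target,
                     task_kind = task_kind)
    })
    dplyr::bind_rows(blocks)
  })
}

#' Simulate behavioral responses to a stimulus stream
#'
#' Each target draws a hit with probability `hit_rate`; hits get a reaction
#' time from a normal truncated at zero. Per-block summaries (correct-response
#' rate, mean RT over hits) are attached.
#'
#' @param stream A tibble from [generate_stimulus_stream()].
#' @param hit_rate Probability of responding to a target, in `[0, 1]`.
#' @param rt_mean,rt_sd Reaction-time mean and SD in ms (> 0).
#' @param seed Integer seed.
#' @return A `behavior_log`: list with `$responses` (one row per target:
#'   `block`, `index`, `onset_s`, `responded`, `rt_ms`) and `$blocks`
#'   (`block`, `n_targets`, `rate`, `mean_rt_ms`).
#' @export
simulate_behavior <- function(stream, hit_rate, rt_mean = 450, rt_sd = 100,
                              seed) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, rt_mean > 0, rt_sd > 0)
  targ <- dplyr::filter(stream, .data$is_target)
  res <- with_seed_(seed, {
    responded <- runif(nrow(targ)) < hit_rate
    rt <- rep(NA_real_, nrow(targ))
    for (i in which(responded)) {
      repeat {
        r <- rnorm(1, rt_mean, rt_sd)
        if (r > 0) break
      }
      rt[i] <- r
    }
    tibble::tibble(block = targ$block, index = targ$index,
                   onset_s = targ$onset_s, responded = responded, rt_ms = rt)
  })
  all_blocks <- sort(unique(stream$block))
  blocks <- res |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(n_targets = dplyr::n(),
                     rate = mean(.data$responded),
                     mean_rt_ms = if (any(.data$responded))
                       mean(.data$rt_ms[.data$responded]) else NA_real_,
                     .groups = "drop")
  blocks <- tibble::tibble(block = all_blocks) |>
    dplyr::left_join(blocks, by = "block") |>
    dplyr::mutate(n_targets = dplyr::coalesce(.data$n_targets, 0L),
                  rate = dplyr::coalesce(.data$rate, 0))
  structure(list(responses = res, blocks = blocks, hit_rate = hit_rate),
            class = "behavior_log")
}

#' @export
print.behavior_log <- function(x, ...) {
  cat(sprintf("<behavior_log> %d targets in %d block(s); overall rate %.3f\n",
              nrow(x$responses), nrow(x$blocks),
              mean(x$responses$responded)))
  invisible(x)
}

#' @export
#' @rdname simulate_behavior
#' @param x A `behavior_log`.
#' @param ... Unused.
tidy.behavior_log <- function(x, ...) x$responses

#' Read / write behavioral logs as TSV
#'
#' Per-target response tables (`block`, `index`, `onset_s`, `responded`,
#' `rt_ms`); block summaries are rebuilt on read.
#'
#' @param log A `behavior_log`.
#' @param path File path.
#' @return `read_behavior_log()`: a `behavior_log`.
#' @export
write_behavior_log <- function(log, path) {
  utils::write.table(log$responses, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path) {
  res <- tibble::as_tibble(utils::read.delim(path))
  res$responded <- as.logical(res$responded)
  blocks <- res |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(n_targets = dplyr::n(),
                     rate = mean(.data$responded),
                     mean_rt_ms = if (any(.data$responded))
                       mean(.data$rt_ms[.data$responded]) else NA_real_,
                     .groups = "drop")
  structure(list(responses = res, blocks = blocks, hit_rate = NA_real_),
            class = "behavior_log")
}

#' @export
#' @rdname simulate_behavior
glance.behavior_log <- function(x, ...) {
  tibble::tibble(n_blocks = nrow(x$blocks),
                 n_targets = nrow(x$responses),
                 rate = mean(x$responses$responded),
                 mean_rt_ms = mean(x$responses$rt_ms, na.rm = TRUE))
}
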