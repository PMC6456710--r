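# End-to-end orchestration: read -> epoch -> decimate -> (optional artifact
# interpolation) -> TV-MVAR fit -> ADTF -> band integration -> outflow ->
# surrogate threshold -> key nodes -> edge dynamics -> regions -> modules.
# Every run is deterministic in (config, seed) and every table carries the
# config hash.

#' Default pipeline configuration
#'
#' @param input Path to the input recording (or `NULL` when a recording object
#'   is passed to [run_pipeline()] directly).
#' @param format Input format, see [read_recording()].
#' @param events Path to an event table ([read_events()]) or a tibble.
#' @param pre,post Epoch window in seconds.
#' @param target_fs Analysis rate in Hz.
#' @param artifact_window Optional length-2 ms window for
#'   [interpolate_artifact()]; `NULL` disables the stage.
#' @param order Model order, or an integer vector of candidates (then
#'   [select_model_order()] picks).
#' @param uc Kalman update coefficient.
#' @param band Integration band in Hz.
#' @param alpha Level for thresholds and edge dynamics.
#' @param n_surrogates Surrogate count for [surrogate_threshold()].
#' @param baseline_window Baseline window in seconds for
#'   [classify_edge_dynamics()].
#' @param seed Integer seed.
#' @param out_dir Output directory; `NULL` skips writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, format = "auto", events = NULL,
                            pre = 0.5, post = 1.0, target_fs = 32,
                            artifact_window = NULL, order = 5L, uc = 0.01,
                            band = c(1, 15), alpha = 0.05,
                            n_surrogates = 200L,
                            baseline_window = c(-0.5, -0.05), seed = 1L,
                            out_dir = NULL) {
  cfg <- list(input = input, format = format, events = events, pre = pre,
              post = post, target_fs = target_fs,
              artifact_window = artifact_window, order = order, uc = uc,
              band = band, alpha = alpha, n_surrogates = n_surrogates,
              baseline_window = baseline_window, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$pre < 0 || cfg$post < 0 || cfg$pre + cfg$post <= 0) {
    abort("config: invalid epoch window")
  }
  if (cfg$target_fs <= 0) abort("config: target_fs must be > 0")
  if (length(cfg$band) != 2L || cfg$band[1] >= cfg$band[2]) {
    abort("config: band must be (f1, f2) with f1 < f2")
  }
  if (cfg$band[2] > cfg$target_fs / 2) {
    abort(sprintf("config: band upper edge %g Hz exceeds the Nyquist %g Hz of the %g-Hz analysis base",
                  cfg$band[2], cfg$target_fs / 2, cfg$target_fs))
  }
  if (cfg$uc <= 0 || cfg$uc >= 1) abort("config: uc must be in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha > 1) abort("config: alpha must be in (0, 1]")
  if (cfg$baseline_window[2] > 0) abort("config: baseline window must end at or before 0")
  invisible(cfg)
}

write_table_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full time-varying network pipeline
#'
#' Executes every stage on one recording and returns (and optionally writes)
#' the full result bundle. Identical config and seed give identical results;
#' on a stage failure the error names the stage and already-finished outputs
#' are preserved in `out_dir`.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param recording Optional [eeg_recording()] overriding `config$input`.
#' @param events Optional events tibble overriding `config$events`.
#' @return A `tvarnet_result` bundle: `config`, `config_hash`, `epochs` (dims
#'   only), `fit` glance, `band_adtf`, `outflow`, `key_nodes`,
#'   `edge_dynamics`, `regions`, `modules`, `log`.
#' @export
run_pipeline <- function(config, recording = NULL, events = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  hash <- rlang::hash(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!is.null(out_dir)) {
    yaml::write_yaml(c(unclass(config), list(config_hash = hash)),
                     file.path(out_dir, "config.yaml"))
  }

  rec <- stage("read", {
    if (!is.null(recording)) recording else read_recording(config$input, config$format)
  })
  ev <- stage("events", {
    if (!is.null(events)) events
    else if (is.character(config$events)) read_events(config$events)
    else if (!is.null(config$events)) tibble::as_tibble(config$events)
    else attr(rec, "events") %||% abort("no events given")
  })
  note("read: %d channels, %.1f s, %d events", nrow(rec$data),
       ncol(rec$data) / rec$fs, nrow(ev))

  epochs <- stage("epoch", extract_epochs(rec, ev, config$pre, config$post))
  dropped <- attr(epochs, "dropped")
  note("epoch: %d trials x %d samples, %d dropped", n_trials(epochs),
       n_samples(epochs), nrow(dropped))
  epochs <- stage("decimate", decimate_epochs(epochs, config$target_fs))
  note("decimate: %d samples @ %g Hz", n_samples(epochs), epochs$fs)
  if (!is.null(config$artifact_window)) {
    epochs <- stage("artifact", interpolate_artifact(epochs, config$artifact_window))
    note("artifact: window [%g, %g] ms interpolated", config$artifact_window[1],
         config$artifact_window[2])
  }

  order <- config$order
  order_table <- NULL
  if (length(order) > 1L) {
    sel <- stage("order", select_model_order(epochs, order, config$uc))
    order <- sel$order
    order_table <- sel$criteria
    note("order: selected p = %d by AIC", order)
  }
  fit <- stage("fit", fit_tvmvar(epochs, order = order, uc = config$uc))
  if (length(fit$log) > 0) note("fit: %d regularization event(s)", length(fit$log))
  ba <- stage("adtf", {
    integrate_band(adtf_normalize(transfer_function(fit)), config$band)
  })
  outflow <- stage("outflow", total_outflow(ba))
  thr <- stage("threshold", surrogate_threshold(
    epochs, order = order, uc = config$uc, band = config$band,
    n_surrogates = config$n_surrogates, alpha = config$alpha,
    seed = config$seed))
  presence <- stage("binarize", binarize_edges(ba, thr))
  keys <- stage("key_nodes", key_node_trajectory(presence, ba))
  dyn <- stage("dynamics", classify_edge_dynamics(
    ba, baseline_window = config$baseline_window, alpha = config$alpha))
  regions <- stage("regions", aggregate_regions(ba))
  modules <- stage("modules", detect_modules(ba, window = c(0, max(ba$times))))
  note("modules: %d module(s), Q_mod = %.4f",
       length(unique(modules$membership$module)), modules$q_mod)

  res <- structure(list(config = config, config_hash = hash,
                        n_trials = n_trials(epochs), fit = fit,
                        order_table = order_table, band_adtf = ba,
                        outflow = outflow, thresholds = thr,
                        presence = presence, key_nodes = keys,
                        edge_dynamics = dyn, regions = regions,
                        modules = modules, dropped = dropped, log = log),
                   class = "tvarnet_result")
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

#' Write a result bundle as tab-delimited tables
#'
#' Writes `outflow.tsv`, `band_adtf.tsv`, `key_nodes.tsv`, `conversions.tsv`,
#' `edge_dynamics.tsv`, `regions.tsv`, `modules.tsv` and `run_log.txt`, each
#' headed by the config hash.
#'
#' @param res A `tvarnet_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- res$config_hash
  write_table_with_hash(res$outflow, file.path(dir, "outflow.tsv"), h)
  write_table_with_hash(generics::tidy(res$band_adtf),
                        file.path(dir, "band_adtf.tsv"), h)
  write_table_with_hash(res$key_nodes$trajectory,
                        file.path(dir, "key_nodes.tsv"), h)
  write_table_with_hash(res$key_nodes$conversions,
                        file.path(dir, "conversions.tsv"), h)
  write_table_with_hash(res$edge_dynamics,
                        file.path(dir, "edge_dynamics.tsv"), h)
  write_table_with_hash(res$regions, file.path(dir, "regions.tsv"), h)
  write_table_with_hash(res$modules$membership,
                        file.path(dir, "modules.tsv"), h)
  writeLines(c(sprintf("# config_hash: %s", h), res$log),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.tvarnet_result <- function(x, ...) {
  cat(sprintf("<tvarnet_result> %s\n", x$config_hash))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' @export
#' @rdname run_pipeline
#' @param x A `tvarnet_result`.
#' @param ... Unused.
glance.tvarnet_result <- function(x, ...) {
  tibble::tibble(config_hash = x$config_hash, n_trials = x$n_trials,
                 order = x$fit$order, uc = x$fit$uc,
                 band_lo = x$config$band[1], band_hi = x$config$band[2],
                 n_modules = length(unique(x$modules$membership$module)),
                 q_mod = x$modules$q_mod,
                 n_conversions = nrow(x$key_nodes$conversions))
}

paired_permutation_p <- function(d, n_resample = 10000L, seed = 1L) {
  n <- length(d)
  obs <- mean(d)
  if (n <= 15L) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d / n)
    mean(stats >= abs(obs) - 1e-12)
  } else {
    with_seed_(seed, {
      stats <- vapply(seq_len(n_resample), function(i) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE)))
      }, 0)
      (sum(stats >= abs(obs) - 1e-12) + 1) / (n_resample + 1)
    })
  }
}

#' Compare two behavioral logs
#'
#' Paired, per-block comparison of correct-response rate and mean reaction
#' time between two conditions, with a sign-flip permutation test on the
#' paired differences (exhaustive over all 2^n flips when n <= 15, else
#' 10,000 seeded resamples). Significance is flagged at p < 0.05.
#'
#' @param log_a,log_b `behavior_log` objects (see [simulate_behavior()]) with
#'   the same number of blocks, paired by block.
#' @param seed Integer seed for the resampled case.
#' @return A tibble (class `behavior_comparison`) with one row per measure:
#'   `measure`, `mean_a`, `mean_b`, `difference` (a - b), `p_value`,
#'   `significant`.
#' @export
compare_behavior <- function(log_a, log_b, seed = 1L) {
  stopifnot(inherits(log_a, "behavior_log"), inherits(log_b, "behavior_log"))
  a <- log_a$blocks; b <- log_b$blocks
  if (nrow(a) != nrow(b)) abort("logs have different numbers of blocks")
  if (nrow(a) < 2L) abort("need at least 2 paired blocks")
  measures <- list(
    rate = list(a = a$rate, b = b$rate),
    mean_rt_ms = list(a = a$mean_rt_ms, b = b$mean_rt_ms)
  )
  rows <- purrr::imap(measures, function(m, name) {
    ok <- stats::complete.cases(m$a, m$b)
    if (sum(ok) < 2L) {
      return(tibble::tibble(measure = name, mean_a = mean(m$a, na.rm = TRUE),
                            mean_b = mean(m$b, na.rm = TRUE),
                            difference = NA_real_, p_value = NA_real_,
                            significant = NA))
    }
    d <- m$a[ok] - m$b[ok]
    p <- paired_permutation_p(d, seed = seed)
    tibble::tibble(measure = name, mean_a = mean(m$a[ok]),
                   mean_b = mean(m$b[ok]), difference = mean(d),
                   p_value = p, significant = p < 0.05)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("behavior_comparison", class(out))
  out
}
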