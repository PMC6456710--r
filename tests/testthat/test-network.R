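test_that("binarization obeys thresholds exactly", {
  th <- array(0.5, dim = c(3, 3, 2))
  ba <- make_band_adtf(th)
  expect_equal(sum(binarize_edges(ba, 1.0)$present), 0L)          # empty
  expect_equal(sum(binarize_edges(ba, 0)$present), 3 * 2 * 2)     # complete
  # hand matrix with a single supra-threshold entry, brute-force check
  th2 <- array(0.1, dim = c(3, 3, 1))
  th2[2, 1, 1] <- 0.9
  pres <- binarize_edges(make_band_adtf(th2), 0.5)
  brute <- th2[, , 1] > 0.5
  diag(brute) <- FALSE
  expect_identical(pres$present[, , 1], brute)
})

test_that("raising thresholds never adds an edge", {
  withr::with_seed(5, {
    th <- array(runif(4 * 4 * 6), dim = c(4, 4, 6))
    ba <- make_band_adtf(th)
    lo <- binarize_edges(ba, 0.3)
    hi <- binarize_edges(ba, 0.6)
    expect_true(all(lo$present | !hi$present))
  })
})

test_that("key-node extraction matches brute-force degree counting", {
  # star graph, constant hub
  th <- array(0, dim = c(4, 4, 5))
  th[2:4, 1, ] <- 0.8
  ba <- make_band_adtf(th)
  kt <- key_node_trajectory(binarize_edges(ba, 0.5), ba)
  expect_true(all(kt$trajectory$key_node == "Fp1"))
  expect_equal(nrow(kt$conversions), 0L)
  # hub switches from node 1 to node 2 at sample 3
  th2 <- array(0, dim = c(4, 4, 5))
  th2[2:4, 1, 1:2] <- 0.8
  th2[c(1, 3, 4), 2, 3:5] <- 0.8
  ba2 <- make_band_adtf(th2)
  kt2 <- key_node_trajectory(binarize_edges(ba2, 0.5), ba2)
  expect_equal(nrow(kt2$conversions), 1L)
  expect_equal(kt2$conversions$time_s, ba2$times[3])
  expect_equal(kt2$conversions$from, "Fp1")
  expect_equal(kt2$conversions$to, "Fp2")
  # random graphs vs brute force
  withr::with_seed(66, {
    for (rep in 1:100) {
      n <- sample(3:6, 1)
      th3 <- array(runif(n * n), dim = c(n, n, 1))
      ba3 <- make_band_adtf(th3)
      pres <- binarize_edges(ba3, 0.5)
      kt3 <- key_node_trajectory(pres, ba3)
      M <- pres$present[, , 1]
      degs <- colSums(M) + rowSums(M)
      if (all(degs == 0)) {
        expect_true(is.na(kt3$trajectory$key_node[1]))
      } else {
        expect_equal(kt3$trajectory$degree[1], max(degs))
        best <- which(degs == max(degs))
        expect_true(kt3$trajectory$key_node[1] %in% ba3$labels[best])
      }
    }
  })
})

test_that("tie-breaking prefers the larger outflow, then channel order", {
  th <- array(0, dim = c(4, 4, 1))
  th[2, 1, 1] <- 0.8   # 1 -> 2
  th[4, 3, 1] <- 0.9   # 3 -> 4 (same degrees, larger outflow for node 3)
  ba <- make_band_adtf(th)
  kt <- key_node_trajectory(binarize_edges(ba, 0.5), ba)
  expect_equal(kt$trajectory$key_node, "F7")   # node 3
})

test_that("edge dynamics recover a planted weaken-then-enhance pattern", {
  ba <- band_from_sched(sched_weaken_enhance(), n_trials = 200, seed = 7)
  dyn <- classify_edge_dynamics(ba)
  e <- dplyr::filter(dyn, source == "Fp1", sink == "Fp2", class != "unchanged")
  expect_equal(e$class, c("weakened", "enhanced"))
  expect_lt(abs(e$onset_s[1] - 0.076), 0.1)
  expect_lt(abs(e$onset_s[2] - 0.45), 0.1)
  expect_lt(e$effect_size[1], 0)
  expect_gt(e$effect_size[2], 0)
  expect_true(all(e$onset_s < e$offset_s))
})

test_that("flat and degenerate couplings classify as documented", {
  # slight baseline jitter, no post-event change: unchanged
  withr::with_seed(8, {
    th <- array(0.3 + rnorm(3 * 3 * 48, sd = 1e-4), dim = c(3, 3, 48))
  })
  ba <- make_band_adtf(th, times = (-16:31) / 32)
  dyn <- classify_edge_dynamics(ba)
  expect_true(all(dyn$class == "unchanged"))
  # strictly constant baseline: zero variance, edge skipped and flagged
  th0 <- array(0.3, dim = c(3, 3, 48))
  ba0 <- make_band_adtf(th0, times = (-16:31) / 32)
  dyn0 <- classify_edge_dynamics(ba0)
  expect_equal(nrow(dyn0), 0L)
  expect_length(attr(dyn0, "skipped"), 6L)
  # baseline-only data: no analysis window
  ba_pre <- make_band_adtf(th[, , 1:16], times = (-16:-1) / 32)
  expect_error(classify_edge_dynamics(ba_pre), "no analysis samples")
})

test_that("region aggregation follows the 10/20 conventions", {
  reg <- channel_regions(c("F3", "F4", "Cz", "T7", "PO8", "Fp1"))
  expect_equal(reg$region, c("left frontal", "right frontal", "mid central",
                             "left temporal", "right occipital",
                             "left frontal"))
  expect_error(channel_regions(c("F3", "XX9")), "XX9")
  # uniform theta: every region pair equals the constant
  th <- array(0.25, dim = c(4, 4, 2))
  ba <- make_band_adtf(th, labels = c("F3", "F4", "P3", "P4"))
  rn <- aggregate_regions(ba)
  expect_true(all(abs(rn$theta - 0.25) < 1e-12))
  # hand-built values: region means equal brute-force averages
  th2 <- array(0, dim = c(4, 4, 1))
  th2[3, 1, 1] <- 0.2   # F3 -> P3
  th2[3, 2, 1] <- 0.6   # F4 -> P3
  ba2 <- make_band_adtf(th2, labels = c("F3", "F4", "P3", "P4"))
  rn2 <- aggregate_regions(ba2)
  got <- dplyr::filter(rn2, source_region == "left frontal",
                       sink_region == "left parietal")
  expect_equal(got$theta, 0.2)   # single pair F3 -> P3
})

test_that("module detection recovers planted structure and handles edge cases", {
  # two 4-node cliques joined weakly: exactly the 2 planted modules
  W <- matrix(0.02, 8, 8)
  W[1:4, 1:4] <- 0.6
  W[5:8, 5:8] <- 0.6
  diag(W) <- 0
  ba <- make_band_adtf(array(W, dim = c(8, 8, 1)))
  mp <- detect_modules(ba)
  expect_equal(length(unique(mp$membership$module)), 2L)
  expect_equal(rand_index(mp$membership$module, rep(1:2, each = 4)), 1)
  expect_gt(mp$q_mod, 0.3)
  # complete uniform graph: one module, Q = 0
  bu <- make_band_adtf(array(0.5, dim = c(5, 5, 1)))
  mu <- detect_modules(bu)
  expect_equal(length(unique(mu$membership$module)), 1L)
  expect_lt(abs(mu$q_mod), 1e-12)
  # empty graph: singletons, Q = 0
  be <- make_band_adtf(array(0, dim = c(5, 5, 1)))
  me <- detect_modules(be)
  expect_equal(length(unique(me$membership$module)), 5L)
  expect_equal(me$q_mod, 0)
})

test_that("module recovery from fitted data beats Rand 0.9 at ratio 3", {
  sched <- sched_two_blocks()
  ri <- vapply(1:5, function(s) {
    ba <- band_from_sched(sched, n_trials = 60, seed = 300 + s)
    Tn <- dim(ba$theta)[3]
    mp <- detect_modules(ba, window = c(ba$times[ceiling(Tn / 2)],
                                        max(ba$times)))
    rand_index(mp$membership$module, rep(1:2, each = 4))
  }, 0)
  expect_gte(mean(ri), 0.9)
})

test_that("surrogate thresholds are deterministic and honor alpha = 1", {
  sched <- sched_with_edges(3)
  ep <- simulate_tvmvar(sched, fs = 32, n_trials = 20, seed = 88)
  t1 <- surrogate_threshold(ep, order = 1, n_surrogates = 20, seed = 12)
  t2 <- surrogate_threshold(ep, order = 1, n_surrogates = 20, seed = 12)
  expect_identical(t1$value, t2$value)
  t3 <- surrogate_threshold(ep, order = 1, n_surrogates = 20, seed = 13)
  expect_false(identical(t1$value, t3$value))
  ta <- surrogate_threshold(ep, order = 1, n_surrogates = 20, alpha = 1,
                            seed = 12)
  expect_equal(max(ta$value), 0)
  ba <- band_from_sched(sched, n_trials = 20, seed = 88)
  expect_equal(sum(!binarize_edges(ba, ta)$present[, , 1]), 3L)  # diagonal only
  few <- simulate_tvmvar(sched, fs = 32, n_trials = 5, seed = 1)
  expect_error(surrogate_threshold(few, n_surrogates = 20, seed = 1),
               "at least 10 trials")
})
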