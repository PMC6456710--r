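test_that("the tracker recovers stationary coefficients from many trials", {
  sched <- sched_with_edges(2, data.frame(source = 1, sink = 2, lag = 1,
                                          weight = 0.4))
  ep <- simulate_tvmvar(sched, fs = 32, n_trials = 100, seed = 42)
  fit <- fit_tvmvar(ep, order = 1, uc = 0.001)
  Tn <- dim(fit$A)[4]
  late <- ceiling(2 * Tn / 3):Tn
  A_true <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  expect_lt(mean(abs(apply(fit$A[, , 1, late], c(1, 2), mean) - A_true)), 0.1)
})

test_that("zero input leaves the state at its zero initialization", {
  ep <- eeg_epochs(array(0, dim = c(5, 2, 48)), fs = 32,
                   times = (-16:31) / 32)
  fit <- fit_tvmvar(ep, order = 2, uc = 0.01)
  expect_equal(max(abs(fit$A)), 0)
})

test_that("a step change is tracked within 8 samples at 200 trials", {
  sched <- sched_with_edges(
    2, data.frame(source = 1, sink = 2, lag = 1, weight = 0.4),
    perturbations = data.frame(source = 1, sink = 2, lag = 1, weight = 0,
                               start = 0, end = 1))
  ep <- simulate_tvmvar(sched, fs = 32, n_trials = 200, seed = 17)
  fit <- fit_tvmvar(ep, order = 1, uc = 0.01)
  w <- fit$A[2, 1, 1, ]
  crossing <- fit$times[which(fit$times >= 0 & w < 0.2)[1]]
  expect_lt(crossing, 8 / 32)
})

test_that("per-trial-average mode agrees with multi-trial on strong dynamics", {
  sched <- sched_with_edges(2, data.frame(source = 1, sink = 2, lag = 1,
                                          weight = 0.4))
  ep <- simulate_tvmvar(sched, fs = 32, n_trials = 30, seed = 19)
  f1 <- fit_tvmvar(ep, order = 1, uc = 0.01)
  f2 <- fit_tvmvar(ep, order = 1, uc = 0.05, mode = "per-trial-average")
  Tn <- dim(f1$A)[4]
  late <- ceiling(2 * Tn / 3):Tn
  expect_lt(abs(mean(f1$A[2, 1, 1, late]) - mean(f2$A[2, 1, 1, late])), 0.2)
  expect_s3_class(glance(f1), "tbl_df")
  expect_equal(nrow(tidy(f1)), 2 * 2 * 1 * Tn)
})

test_that("degenerate fits are rejected", {
  ep <- eeg_epochs(array(rnorm(5 * 2 * 6), dim = c(5, 2, 6)), fs = 32,
                   times = (0:5) / 32)
  expect_error(fit_tvmvar(ep, order = 6), "beyond the model order")
  expect_error(fit_tvmvar(ep, order = 1, uc = 0), "uc")
})

test_that("AIC order selection recovers the generating order", {
  # order-2 dynamics: lag-2 oscillator terms on both nodes plus a cross edge
  base <- data.frame(
    source = c(1, 2, 1, 2, 1),
    sink = c(1, 2, 1, 2, 2),
    lag = c(1, 1, 2, 2, 1),
    weight = c(0.9, 0.9, -0.6, -0.6, 0.5))
  sched <- build_coefficient_schedule(2, 2, base, t_start = 0, t_end = 1.5)
  hits <- vapply(seq_len(50), function(s) {
    ep <- simulate_tvmvar(sched, fs = 32, n_trials = 40, seed = 100 + s)
    select_model_order(ep, candidates = 1:6, uc = 0.01)$order == 2L
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("white noise selects order 1 and single candidates pass through", {
  sched <- build_coefficient_schedule(2, 1, t_start = 0, t_end = 1.5)
  ep <- simulate_tvmvar(sched, fs = 32, n_trials = 40, seed = 23)
  sel <- select_model_order(ep, candidates = 1:4, uc = 0.01)
  expect_equal(sel$order, 1L)
  expect_equal(select_model_order(ep, candidates = 3L)$order, 3L)
})
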