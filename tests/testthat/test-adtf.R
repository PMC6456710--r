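const_fit <- function(A, fs = 32, Tn = 4) {
  # wrap constant coefficient matrices as a fit object
  n <- nrow(A[[1]])
  p <- length(A)
  arr <- array(0, dim = c(n, n, p, Tn))
  for (i in seq_len(p)) arr[, , i, ] <- A[[i]]
  list(A = arr, fs = fs, times = seq_len(Tn) / fs,
       labels = montage_1020_32()[seq_len(n)], order = p)
}

test_that("a zero model has the identity transfer function", {
  tf <- transfer_function(const_fit(list(matrix(0, 2, 2))))
  expect_true(all(abs(tf$H[1, 1, , ] - 1) < 1e-14))
  expect_true(all(abs(tf$H[2, 2, , ] - 1) < 1e-14))
  expect_true(all(abs(tf$H[1, 2, , ]) == 0))
  expect_true(all(abs(tf$H[2, 1, , ]) == 0))
  ad <- adtf_normalize(tf)
  expect_equal(ad$gamma2[1, 1, 1, 1], 1)
  expect_equal(ad$gamma2[1, 2, 1, 1], 0)
})

test_that("the scalar AR(1) transfer gain matches the closed form", {
  tf <- transfer_function(const_fit(list(matrix(0.5, 1, 1))), freqs = c(0, 4, 8))
  # |H(f)|^2 = 1 / |1 - 0.5 exp(-j 2 pi f / fs)|^2; at f = 0 this is 4
  expect_equal(Mod(tf$H[1, 1, 1, 1])^2, 4)
  f <- 4
  expect_equal(Mod(tf$H[1, 1, 2, 1])^2,
               1 / Mod(1 - 0.5 * exp(-2i * pi * f / 32))^2)
})

test_that("unidirectional coupling gives an exactly zero reverse path", {
  # x -> y only: A lower-triangular => H lower-triangular => H_xy = 0
  A <- list(matrix(c(0.5, 0.4, 0, 0.3), 2, 2))
  tf <- transfer_function(const_fit(A))
  expect_equal(max(abs(tf$H[1, 2, , ])), 0)
  ad <- adtf_normalize(tf)
  expect_equal(max(ad$gamma2[1, 2, , ]), 0)
  expect_true(all(ad$gamma2[2, 1, , ] > 0))
})

test_that("every sink row of the ADTF sums to one", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      A <- list(matrix(runif(9, -0.3, 0.3), 3, 3))
      while (max(Mod(eigen(A[[1]], only.values = TRUE)$values)) >= 0.95) {
        A <- list(matrix(runif(9, -0.3, 0.3), 3, 3))
      }
      ad <- adtf_normalize(transfer_function(const_fit(A)))
      sums <- apply(ad$gamma2, c(1, 3, 4), sum)
      expect_lt(max(abs(sums - 1)), 1e-9)
    }
  })
})

test_that("band integration averages the grid frequencies in the band", {
  ad <- adtf_normalize(transfer_function(const_fit(list(matrix(0, 2, 2)))))
  # gamma2 constant in f: integral equals the constant
  b <- integrate_band(ad, c(1, 15))
  expect_equal(b$theta[1, 1, 1], 1)
  expect_equal(b$theta[1, 2, 1], 0)
  # hand-built tensor: two grid frequencies with values 0.2 and 0.4
  ad2 <- structure(list(
    gamma2 = array(c(0.2, 0.4)[rep(1:2, each = 4)], dim = c(2, 2, 2, 1)),
    freqs = c(2, 3), times = 0, labels = c("F3", "F4"), fs = 32),
    class = "adtf_tensor")
  expect_equal(integrate_band(ad2, c(1, 15))$theta[1, 1, 1], 0.3)
  expect_equal(integrate_band(ad2, c(3, 3.5))$theta[1, 1, 1], 0.4)
  expect_error(integrate_band(ad2, c(10, 15)), "no grid frequencies")
})

test_that("total outflow implements the normalized sum over sinks", {
  # n = 3, theta_(.j) = (0.6, 0.3) for node 1 at one time point
  th <- array(0, dim = c(3, 3, 1))
  th[2, 1, 1] <- 0.6
  th[3, 1, 1] <- 0.3
  q <- total_outflow(make_band_adtf(th))
  expect_equal(q$outflow[q$node == "Fp1"], 0.45)
  expect_equal(q$outflow[q$node == "Fp2"], 0)
  # constant off-diagonal c gives outflow exactly c
  th2 <- array(0.2, dim = c(4, 4, 2))
  q2 <- total_outflow(make_band_adtf(th2))
  expect_true(all(abs(q2$outflow - 0.2) < 1e-12))
  expect_error(total_outflow(make_band_adtf(array(0, dim = c(1, 1, 2)))),
               "at least 2")
})

test_that("outflow equals the brute-force definition on random tensors", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      Tn <- sample(1:5, 1)
      th <- array(runif(n * n * Tn), dim = c(n, n, Tn))
      q <- total_outflow(make_band_adtf(th))
      uts <- unique(q$time_s)
      for (t in seq_len(Tn)) {
        for (j in seq_len(n)) {
          brute <- sum(th[setdiff(seq_len(n), j), j, t]) / (n - 1)
          got <- q$outflow[q$time_s == uts[t] &
                             q$node == montage_1020_32()[j]]
          expect_equal(got, brute, tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("the adaptive ADTF converges to the closed-form DTF", {
  cross <- data.frame(source = c(1, 2), sink = c(2, 3), lag = 1,
                      weight = c(0.4, 0.3))
  sched <- sched_with_edges(3, cross)
  ba <- band_from_sched(sched, n_trials = 100, seed = 202)
  Tn <- dim(ba$theta)[3]
  late <- apply(ba$theta[, , ceiling(2 * Tn / 3):Tn], c(1, 2), mean)
  A_true <- schedule_at(sched, 0)
  ref <- dtf_from_coefficients(A_true, 1:15, 32, band = c(1, 15))
  expect_lt(max(abs(late - ref)), 0.05)
})
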