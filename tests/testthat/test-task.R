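test_that("selective streams carry exactly the planted zero targets", {
  s <- generate_stimulus_stream("selective", n_blocks = 1,
                                stimuli_per_block = 200,
                                targets_per_block = 8, soa = 0.6, seed = 31)
  expect_equal(nrow(s), 200L)
  expect_equal(max(s$onset_s) - min(s$onset_s), 119.4)
  expect_equal(sum(s$digit == 0), 8L)               # no accidental zeros
  expect_equal(which(s$digit == 0), which(s$is_target))
  expect_true(all(diff(which(s$is_target)) >= 10))
  expect_equal(diff(s$onset_s), rep(0.6, 199))
})

test_that("sustained streams have exactly the planted triplet completions", {
  for (seed in 41:45) {
    s <- generate_stimulus_stream("sustained", n_blocks = 2,
                                  stimuli_per_block = 200,
                                  targets_per_block = 8, seed = seed)
    for (b in 1:2) {
      d <- s$digit[s$block == b]
      hits <- scan_triplets(d)                      # independent brute force
      expect_length(hits, 8L)
      expect_equal(hits, which(s$is_target[s$block == b]))
      expect_true(all(d >= 1 & d <= 9))
    }
  }
})

test_that("visual streams mark no targets and use all ten digits", {
  s <- generate_stimulus_stream("visual", n_blocks = 1, seed = 51)
  expect_false(any(s$is_target))
  expect_setequal(unique(s$digit), 0:9)
  s0 <- generate_stimulus_stream("visual", n_blocks = 1,
                                 targets_per_block = 0, seed = 51)
  expect_false(any(s0$is_target))
})

test_that("infeasible target constraints are rejected", {
  expect_error(generate_stimulus_stream("selective", n_blocks = 1,
                                        stimuli_per_block = 30,
                                        targets_per_block = 8,
                                        min_spacing = 10, seed = 1),
               "infeasible")
})

test_that("streams are deterministic in the seed", {
  a <- generate_stimulus_stream("sustained", n_blocks = 1, seed = 61)
  b <- generate_stimulus_stream("sustained", n_blocks = 1, seed = 61)
  expect_identical(a, b)
})

test_that("behavior simulation matches its response model", {
  s <- generate_stimulus_stream("selective", n_blocks = 2, seed = 71)
  sure <- simulate_behavior(s, hit_rate = 1, seed = 1)
  expect_equal(sure$blocks$rate, c(1, 1))
  expect_true(all(sure$responses$rt_ms > 0))
  none <- simulate_behavior(s, hit_rate = 0, seed = 1)
  expect_equal(none$blocks$rate, c(0, 0))
  expect_true(all(is.na(none$responses$rt_ms)))
})

test_that("behavior logs round-trip through TSV with summaries rebuilt", {
  s <- generate_stimulus_stream("selective", n_blocks = 3, seed = 91)
  log_ <- simulate_behavior(s, 0.7, seed = 92)
  path <- tempfile(fileext = ".tsv")
  write_behavior_log(log_, path)
  back <- read_behavior_log(path)
  expect_equal(back$responses$responded, log_$responses$responded)
  expect_equal(back$blocks$rate, log_$blocks$rate)
  expect_equal(back$blocks$mean_rt_ms, log_$blocks$mean_rt_ms)
})

test_that("hit rates converge to the binomial expectation", {
  s <- generate_stimulus_stream("selective", n_blocks = 1000,
                                stimuli_per_block = 100,
                                targets_per_block = 8, seed = 81)
  log_ <- simulate_behavior(s, hit_rate = 0.8, seed = 82)
  expect_gt(mean(log_$blocks$rate), 0.79)
  expect_lt(mean(log_$blocks$rate), 0.81)
})
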