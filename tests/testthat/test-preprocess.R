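sine_recording <- function(freq = 2, fs = 1024, dur = 30, n = 2, amp = 10) {
  t <- (seq_len(fs * dur) - 1) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq * t), n), n, byrow = TRUE)
  eeg_recording(data, fs = fs, labels = montage_1020_32()[seq_len(n)])
}

test_that("epoch windows are index-exact and 1.5 s at 1024 Hz is 1536 samples", {
  rec <- sine_recording()
  ev <- place_tms_events(30, 4, 2)
  ep <- extract_epochs(rec, ev, pre = 0.5, post = 1.0, demean = FALSE)
  expect_equal(n_samples(ep), 1536L)
  expect_equal(ep$times[1], -0.5)
  expect_equal(ep$times[which.min(abs(ep$times))], 0)
  # sample k (0-based) of trial r equals recording sample event_idx - pre*fs + k
  for (r in c(1L, 3L)) {
    idx0 <- round(ev$time_s[r] * rec$fs) + 1L
    expect_identical(ep$data[r, 1, ], rec$data[1, (idx0 - 512):(idx0 + 1023)])
  }
})

test_that("boundary-clipped events are dropped and reported", {
  rec <- sine_recording(dur = 10)
  ev <- tibble::tibble(time_s = c(0.1, 2, 5, 9.8), kind = "tms")
  ep <- extract_epochs(rec, ev, 0.5, 1.0)
  expect_equal(n_trials(ep), 2L)
  expect_equal(attr(ep, "dropped")$time_s, c(0.1, 9.8))
  expect_error(extract_epochs(rec, tibble::tibble(time_s = 0.01), 0.5, 1),
               "no event")
})

test_that("trial count equals events minus dropped on a 120-s session", {
  rec <- sine_recording(dur = 120)
  ev <- place_tms_events(120, 4, 0.5)
  ep <- extract_epochs(rec, ev, 0.5, 1.0)
  expect_equal(n_trials(ep), 30L)
  expect_equal(nrow(attr(ep, "dropped")), 0L)
})

test_that("decimation to 32 Hz keeps 48 samples, time 0 and the passband", {
  rec <- sine_recording(freq = 2, amp = 10)
  ev <- place_tms_events(30, 4, 2)
  ep <- extract_epochs(rec, ev, 0.5, 1.0, demean = FALSE)
  dec <- decimate_epochs(ep, 32)
  expect_equal(n_samples(dec), 48L)
  expect_equal(dec$fs, 32)
  expect_true(0 %in% dec$times)
  # 2-Hz sinusoid amplitude preserved within 1%
  expect_lt(abs(max(dec$data[1, 1, ]) - 10) / 10, 0.01)
})

test_that("decimation preserves constant channels to machine precision", {
  data <- array(7.25, dim = c(2, 2, 1536))
  ep <- eeg_epochs(data, fs = 1024, times = (-512:1023) / 1024)
  dec <- decimate_epochs(ep, 32)
  expect_equal(max(abs(dec$data - 7.25)), 0, tolerance = 1e-12)
})

test_that("invalid decimation factors are rejected", {
  ep <- eeg_epochs(array(0, dim = c(1, 1, 48)), fs = 32, times = (-16:31) / 32)
  expect_error(decimate_epochs(ep, 32), "below")
  expect_error(decimate_epochs(ep, 12.5), "integer multiple")
})

test_that("artifact interpolation restores a clean sinusoid", {
  rec <- sine_recording(freq = 3, dur = 30)
  ev <- place_tms_events(30, 4, 2)
  clean <- decimate_epochs(extract_epochs(rec, ev, 0.5, 1.0, demean = FALSE), 128)
  dirty <- inject_tms_artifact(clean, amplitude = 500, duration_ms = 10)
  fixed <- interpolate_artifact(dirty, c(0, 10))
  err <- sqrt(mean((fixed$data - clean$data)^2))
  expect_lt(err, 0.05 * sqrt(mean(clean$data^2)))
})

test_that("degenerate artifact windows behave as documented", {
  ep <- eeg_epochs(array(0, dim = c(1, 1, 48)), fs = 32, times = (-16:31) / 32)
  expect_identical(interpolate_artifact(ep, c(0, 0)), ep)   # zero width
  dirty <- ep
  dirty$data[1, 1, 17] <- 100
  fixed <- interpolate_artifact(dirty, c(0, 10))
  expect_equal(max(abs(fixed$data)), 0)                      # all-zero epoch
  expect_error(interpolate_artifact(ep, c(2000, 3000)), "outside")
})
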