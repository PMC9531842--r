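test_that("protocol timelines tile the requested duration with alternating states", {
  tl <- generate_protocol(breathing_protocol())
  expect_equal(sum(tl$end_s - tl$start_s), 3600)
  expect_equal(tl$start_s[-1], tl$end_s[-nrow(tl)])  # contiguous
  expect_true(all(abs(diff(tl$state)) == 1))         # states alternate
  expect_equal(tl$start_s[1], 0)

  # 60 s, 31 bpm, no apnea: a single breathing segment with 31 breath cycles
  p <- breathing_protocol(apnea_durations = numeric(0),
                          breathing_segment_durations = 60,
                          total_duration = 60)
  tl1 <- generate_protocol(p)
  expect_equal(nrow(tl1), 1L)
  expect_equal(tl1$state, 1L)
  expect_equal(attr(tl1, "breath_freq_hz") * 60, 31)

  # degenerate schedule: a single 30 s apnea segment
  pa <- breathing_protocol(breathing_segment_durations = numeric(0),
                           apnea_durations = 30, total_duration = 30)
  tla <- generate_protocol(pa)
  expect_equal(nrow(tla), 1L)
  expect_equal(tla$state, 0L)
})

test_that("invalid protocol durations are rejected", {
  expect_error(breathing_protocol(apnea_durations = c(30, -5)), "positive")
  expect_error(breathing_protocol(total_duration = 0), "positive")
  expect_error(breathing_protocol(breaths_per_minute = -1), "positive")
})

test_that("breathing phase is sinusoidal at the breath rate and zero in apnea", {
  tl <- generate_protocol(breathing_protocol(total_duration = 200))
  t_b <- seq(0.05, 100, by = 0.05)             # inside the first breathing segment
  f_b <- 31 / 60
  expect_equal(timeline_phase(tl, t_b), sin(2 * pi * f_b * t_b))
  expect_equal(timeline_phase(tl, c(125, 130, 140)), c(0, 0, 0))  # apnea
})

test_that("interrogation count tracks the effective per-tag rate", {
  tl <- generate_protocol(breathing_protocol(total_duration = 120))
  st <- simulate_interrogations(tl, rfid_config(), seed = 3)
  expect_lt(abs(nrow(st) - 28 * 120) / (28 * 120), 0.05)
  expect_true(all(diff(st$timestamp_s) > 0))
  expect_true(all(st$channel_mhz >= 902 & st$channel_mhz <= 928))

  # one minute at 28 Hz: about 1680 records
  tl1 <- generate_protocol(breathing_protocol(
    apnea_durations = numeric(0), breathing_segment_durations = 60,
    total_duration = 60))
  st1 <- simulate_interrogations(tl1, rfid_config(), seed = 3)
  expect_lt(abs(nrow(st1) - 1680) / 1680, 0.05)

  # Poisson arrivals are also close to the nominal rate
  stp <- simulate_interrogations(tl, rfid_config(arrival = "poisson"), seed = 3)
  expect_lt(abs(nrow(stp) - 28 * 120) / (28 * 120), 0.05)
})

test_that("with no noise, one channel and apnea the received power is constant", {
  tl <- generate_protocol(breathing_protocol(
    breathing_segment_durations = numeric(0), apnea_durations = 60,
    total_duration = 60))
  cfg <- rfid_config(noise_sd_db = 0, n_channels = 1)
  st <- simulate_interrogations(tl, cfg, seed = 1)
  expect_equal(diff(range(st$rssi_dbm)), 0)
})

test_that("noise-free single-channel breathing gives a spectral peak at the breath rate", {
  tl <- generate_protocol(breathing_protocol(
    apnea_durations = numeric(0), breathing_segment_durations = 120,
    total_duration = 120))
  cfg <- rfid_config(noise_sd_db = 0, n_channels = 1)
  st <- simulate_interrogations(tl, cfg, seed = 1)
  # resample onto a uniform grid at the nominal rate for the FFT
  grid <- seq(0, 120 - 1 / 28, by = 1 / 28)
  x <- stats::approx(st$timestamp_s, st$rssi_dbm, xout = grid, rule = 2)$y
  x <- x - mean(x)
  spec <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
  freq <- (seq_along(spec)) / (length(x) / 28)
  expect_lt(abs(freq[which.max(spec)] - 31 / 60), 0.02)
})

test_that("simulation is reproducible under a seed and varies across seeds", {
  tl <- generate_protocol(breathing_protocol(total_duration = 30))
  a <- simulate_interrogations(tl, rfid_config(), seed = 11)
  b <- simulate_interrogations(tl, rfid_config(), seed = 11)
  c <- simulate_interrogations(tl, rfid_config(), seed = 12)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$rssi_dbm, c$rssi_dbm)))
})

test_that("interrogation CSV round-trips and rejects malformed rows", {
  tl <- generate_protocol(breathing_protocol(total_duration = 10))
  st <- simulate_interrogations(tl, rfid_config(), seed = 1)[1:100, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_interrogations_csv(st, path)
  back <- read_interrogations_csv(path)
  expect_equal(back, st, tolerance = 1e-12, ignore_attr = TRUE)

  # empty stream: header-only file, reads back empty
  write_interrogations_csv(st[0, ], path)
  expect_equal(readLines(path), "timestamp_s,channel_mhz,rssi_dbm")
  expect_equal(nrow(read_interrogations_csv(path)), 0L)

  # malformed RSSI: error naming the offending line
  writeLines(c("timestamp_s,channel_mhz,rssi_dbm",
               "0.1,915.2,-61.2", "0.2,915.7,oops"), path)
  expect_error(read_interrogations_csv(path), "line 3.*oops")
})
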