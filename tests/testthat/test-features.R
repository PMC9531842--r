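test_that("zeta matches direct evaluation of the link-budget rearrangement", {
  # cancellation identity: P_Rx chosen so every term cancels
  lam <- 2.998e8 / 915e6
  ctx <- rcs_context(p_tx_w = 1, g_reader = 1, lambda_m = lam)
  expect_equal(compute_zeta(1 * 1 * (lam / (4 * pi))^4, ctx), 1)

  # direct evaluation oracle (c = 2.998e8 m/s, f = 915 MHz, P_Rx = 1e-6 W)
  oracle <- 1 * 1^2 / 1e-6 * (lam / (4 * pi))^4
  expect_equal(compute_zeta(1e-6, ctx), oracle)
  expect_equal(round(oracle, 3), 0.462)

  # zeta is inversely proportional to received power
  expect_equal(compute_zeta(2e-6, ctx), compute_zeta(1e-6, ctx) / 2)

  # unit consistency: both powers in mW instead of W leaves zeta unchanged
  ctx_mw <- rcs_context(p_tx_w = 1000, g_reader = 1, lambda_m = lam)
  expect_equal(compute_zeta(1e-3, ctx_mw), compute_zeta(1e-6, ctx))

  expect_error(compute_zeta(0, ctx), "positive")
  expect_error(compute_zeta(-1e-6, ctx), "positive")
})

test_that("the channel-hop residual matches its closed form", {
  expect_equal(deoscillation_residual(915), -40 * log10(915 / 914.5))
  expect_equal(round(deoscillation_residual(915), 5), -0.00950)
  # vanishes at high frequency
  expect_lt(abs(deoscillation_residual(1e9)), 1e-8)
  # in-band magnitude brackets the printed value
  band <- abs(deoscillation_residual(seq(902, 928, by = 0.5)))
  expect_true(all(band > 0.0093 & band < 0.0097))
  expect_lt(min(band), 0.00941)
  expect_gt(max(band), 0.00941)
  expect_error(deoscillation_residual(0.4), "0.5 MHz")
  expect_equal(deoscillate(-61, 915), -61 - deoscillation_residual(915))
})

test_that("rssi_from_min is a trailing-window excess over the minimum", {
  expect_equal(rssi_from_min(rep(-60, 10), 4), rep(0, 10))
  expect_equal(rssi_from_min(c(-63, -60, -61), 3), c(0, 3, 2))
  x <- c(5, 3, 4, 1, 2)
  out <- rssi_from_min(x, 2)
  expect_equal(out, c(0, 0, 1, 0, 1))
  expect_true(all(rssi_from_min(rnorm(50), 7) >= 0))
  # translation invariance
  y <- rnorm(30)
  expect_equal(rssi_from_min(y + 100, 5), rssi_from_min(y, 5))
  expect_equal(rssi_from_min(numeric(0), 3), numeric(0))
})

test_that("windows aggregate exactly 1-s spans with majority labels", {
  # 84 samples at exactly 28 Hz -> 3 windows of 28 samples
  tl <- generate_protocol(breathing_protocol(
    apnea_durations = numeric(0), breathing_segment_durations = 3,
    total_duration = 3))
  ts <- (0:83) / 28
  feats <- data.frame(timestamp_s = ts, prx_deosc = seq_along(ts),
                      rssi_from_min = 1)
  w <- build_windows(feats, tl)
  expect_equal(nrow(w$X), 3L)
  expect_equal(w$X[, "prx_deosc"], c(mean(1:28), mean(29:56), mean(57:84)))
  expect_equal(w$y, c(1L, 1L, 1L))

  # majority labelling across a segment boundary (0.6 s apnea in [2, 3))
  tl2 <- generate_protocol(breathing_protocol(
    breathing_segment_durations = 2.4, apnea_durations = 0.6,
    total_duration = 3))
  w2 <- build_windows(feats, tl2)
  expect_equal(w2$y, c(1L, 1L, 0L))

  # empty stream: zero windows
  w0 <- build_windows(feats[0, ], tl)
  expect_equal(nrow(w0$X), 0L)

  # windows with no samples are dropped with a warning
  feats_gap <- feats[feats$timestamp_s < 1 | feats$timestamp_s >= 2, ]
  expect_warning(wg <- build_windows(feats_gap, tl), "empty window")
  expect_equal(nrow(wg$X), 2L)
})

test_that("standard-score scaling uses population sigma and inverts exactly", {
  sc <- fit_scaler(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(sc$mu, 2, ignore_attr = TRUE)
  expect_equal(sc$sigma, sqrt(2 / 3), ignore_attr = TRUE)
  scaled <- apply_scaler(matrix(c(1, 2, 3), ncol = 1), sc)
  expect_equal(drop(scaled), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(scaled), 0)
  expect_equal(sqrt(mean(scaled^2)), 1)

  # idempotence on already-standardized input
  sc2 <- fit_scaler(scaled)
  expect_equal(apply_scaler(scaled, sc2), scaled, tolerance = 1e-12)

  # round trip
  set.seed(1)
  X <- matrix(rnorm(40, 5, 3), ncol = 2)
  sc3 <- fit_scaler(X)
  expect_equal(inverse_scaler(apply_scaler(X, sc3), sc3), X, tolerance = 1e-9)

  expect_error(fit_scaler(matrix(rep(4, 6), ncol = 2)), "zero-variance")
})

test_that("clean_and_split filters NaN and produces disjoint exhaustive partitions", {
  set.seed(2)
  X <- matrix(rnorm(200), ncol = 2)
  X[c(3, 50), 1] <- NaN
  ds <- as_windowed(X, rep(c(0L, 1L), 50))
  sp <- clean_and_split(ds, seed = 9)
  n_clean <- 98
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), n_clean)
  expect_equal(nrow(sp$test$X), ceiling(0.25 * n_clean))
  expect_false(any(is.na(sp$train$X)) || any(is.na(sp$test$X)))
  # disjoint and exhaustive in time stamps
  expect_length(intersect(sp$train$t0, sp$test$t0), 0)
  expect_setequal(c(sp$train$t0, sp$test$t0), ds$t0[-c(3, 50)])

  # N = 100 -> 75/25; N = 4 -> 3/1
  ds100 <- as_windowed(matrix(rnorm(200), ncol = 2), rep(0:1, 50))
  sp100 <- clean_and_split(ds100, seed = 1)
  expect_equal(c(nrow(sp100$train$X), nrow(sp100$test$X)), c(75, 25))
  ds4 <- as_windowed(matrix(rnorm(8), ncol = 2), c(0, 1, 0, 1))
  sp4 <- clean_and_split(ds4, seed = 1)
  expect_equal(c(nrow(sp4$train$X), nrow(sp4$test$X)), c(3, 1))

  # reproducible under a fixed seed
  spa <- clean_and_split(ds100, seed = 42)
  spb <- clean_and_split(ds100, seed = 42)
  expect_identical(spa$test$t0, spb$test$t0)

  # chronological split holds out the tail
  spc <- clean_and_split(ds100, seed = 1, chronological = TRUE)
  expect_equal(spc$test$t0, ds100$t0[76:100])

  # all-NaN dataset errors
  Xbad <- matrix(NaN, 4, 2)
  expect_error(clean_and_split(as_windowed(Xbad, rep(0L, 4))), "NaN")
})

test_that("scaler is fitted on the training partition only", {
  set.seed(3)
  ds <- as_windowed(matrix(rnorm(200, 10, 2), ncol = 2), rep(0:1, 50))
  sp <- clean_and_split(ds, seed = 5)
  expect_equal(colMeans(sp$train$X), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(max(abs(colMeans(sp$test$X))), 1e-6)
})

test_that("feature and label CSVs round-trip as a pair", {
  dir <- withr::local_tempdir()
  feats <- data.frame(timestamp_s = c(0.1, 0.2), prx_deosc = c(-9.5, -9.6),
                      rssi_from_min = c(0, 0.1))
  labs <- data.frame(timestamp_s = c(0.1, 0.2), state = c(1L, 0L))
  write_feature_csvs(feats, labs, dir)
  back <- read_feature_csvs(dir)
  expect_equal(back$features, feats, tolerance = 1e-12)
  expect_equal(back$labels$state, labs$state)
})

test_that("the zeta feature is free of the channel-hop sawtooth", {
  tl <- generate_protocol(breathing_protocol(
    breathing_segment_durations = numeric(0), apnea_durations = 30,
    total_duration = 30))
  st <- simulate_interrogations(tl, rfid_config(noise_sd_db = 0), seed = 1)
  fz <- compute_features(st, method = "zeta")
  fr <- compute_features(st, method = "residual")
  expect_lt(diff(range(fz$prx_deosc)), 1e-9)  # hop dependence cancels
  expect_gt(diff(range(fr$prx_deosc)), 0.1)   # raw RSSI keeps the sawtooth
})
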