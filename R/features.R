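#' Link-budget context for the zeta wearer-state feature
#'
#' Interrogator-side quantities of the radar-cross-section relation needed to
#' isolate the wearer-state terms (tag gain, distance, return loss) from an
#' observed received power.
#'
#' @param p_tx_w Transmit power in W.
#' @param g_reader Reader antenna gain (linear).
#' @param lambda_m Interrogation wavelength in m.
#' @return An object of class `rcs_context`.
#' @export
rcs_context <- function(p_tx_w, g_reader, lambda_m) {
  if (any(c(p_tx_w, g_reader, lambda_m) <= 0)) {
    stop("all rcs_context fields must be positive", call. = FALSE)
  }
  structure(list(p_tx_w = p_tx_w, g_reader = g_reader, lambda_m = lambda_m),
            class = "rcs_context")
}

#' Wearer-state feature zeta from received power
#'
#' Rearranges the RCS link budget so that the wearer-state terms sit on one
#' side: \deqn{\zeta = G_{tag}^{-2} r^4 R^{-1}
#'   = P_{Tx} G_{reader}^2 P_{Rx}^{-1} (\lambda/4\pi)^4.}
#' Both powers must be expressed in the same linear unit (W here); the value
#' is dimensionless up to the r^4 length scale.
#'
#' @param p_rx_w Received power in W (positive), same unit as `ctx$p_tx_w`.
#' @param ctx An [rcs_context()].
#' @return zeta, strictly positive.
#' @examples
#' ctx <- rcs_context(p_tx_w = 1, g_reader = 1, lambda_m = 2.998e8 / 915e6)
#' compute_zeta(1e-6, ctx)
#' @export
compute_zeta <- function(p_rx_w, ctx) {
  stopifnot(inherits(ctx, "rcs_context"))
  if (any(p_rx_w <= 0)) {
    stop("received power must be positive", call. = FALSE)
  }
  ctx$p_tx_w * ctx$g_reader^2 / p_rx_w * (ctx$lambda_m / (4 * pi))^4
}

#' Channel-hop residual term
#'
#' The sawtooth artifact that channel hopping imprints on observed RSSI:
#' \deqn{\delta(f) = -10 \log_{10}\left(f^4 / (f - 0.5\,\mathrm{MHz})^4\right)}
#' evaluated at the channel frequency `f` in MHz (one 0.5 MHz hop step).
#' Within the 902-928 MHz band the magnitude is about 0.0094 dB.
#'
#' @param channel_mhz Channel frequency in MHz (> 0.5).
#' @return delta in dB (negative in-band).
#' @export
deoscillation_residual <- function(channel_mhz) {
  if (any(channel_mhz <= 0.5)) {
    stop("channel frequency must exceed 0.5 MHz", call. = FALSE)
  }
  -10 * log10(channel_mhz^4 / (channel_mhz - 0.5)^4)
}

#' De-oscillated received signal strength (Feature 1)
#'
#' Removes the channel-hop residual term from an observed RSSI, leaving the
#' wearer-state (breathing) modulation to dominate the series.
#'
#' @param rssi_dbm Observed RSSI in dBm.
#' @param channel_mhz Channel frequency of the observation in MHz.
#' @return De-oscillated RSSI in dBm.
#' @export
deoscillate <- function(rssi_dbm, channel_mhz) {
  rssi_dbm - deoscillation_residual(channel_mhz)
}

#' RSSI above the recent minimum (Feature 2)
#'
#' For each sample, the difference between the current RSSI and the minimum
#' observed over a trailing (causal) window of `window_n` samples including
#' the current one. Always non-negative and invariant to adding a constant
#' to the series.
#'
#' @param series Numeric RSSI series in dB.
#' @param window_n Trailing window length in samples (>= 1); the default 28
#'   spans about one second at the effective interrogation rate.
#' @return Numeric vector the same length as `series`.
#' @examples
#' rssi_from_min(c(-63, -60, -61), window_n = 3)
#' @export
rssi_from_min <- function(series, window_n = 28) {
  if (window_n < 1) stop("`window_n` must be >= 1", call. = FALSE)
  n <- length(series)
  if (n == 0) return(numeric(0))
  mins <- vapply(seq_len(n), function(i) {
    min(series[max(1, i - window_n + 1):i])
  }, numeric(1))
  series - mins
}

#' Per-interrogation feature table
#'
#' Computes the two classifier features for every interrogation record.
#' Feature 1 (`prx_deosc`) is the de-oscillated reflected signal strength;
#' with `method = "zeta"` (default) it is the log-domain zeta feature
#' `10 log10(zeta)`, whose `lambda^4` term cancels the channel-hop
#' dependence of the received power exactly, leaving the wearer-state
#' modulation (interrogator constants drop out after standardization); with
#' `method = "residual"` it is the observed RSSI minus the per-hop residual
#' term [deoscillation_residual()]. Feature 2 (`rssi_from_min`) is the
#' Feature 1 value above its trailing-window minimum.
#'
#' @param stream Interrogation data frame (`timestamp_s`, `channel_mhz`,
#'   `rssi_dbm`).
#' @param window_n Trailing window for [rssi_from_min()].
#' @param method Feature 1 variant, `"zeta"` or `"residual"`.
#' @return Data frame `timestamp_s`, `prx_deosc`, `rssi_from_min`.
#' @export
compute_features <- function(stream, window_n = 28,
                             method = c("zeta", "residual")) {
  stopifnot(all(c("timestamp_s", "channel_mhz", "rssi_dbm") %in% names(stream)))
  method <- match.arg(method)
  if (method == "zeta") {
    lambda <- SPEED_OF_LIGHT / (stream$channel_mhz * 1e6)
    ctx <- rcs_context(p_tx_w = 1, g_reader = 1, lambda_m = lambda)
    f1 <- 10 * log10(compute_zeta(dbm_to_w(stream$rssi_dbm), ctx))
  } else {
    f1 <- deoscillate(stream$rssi_dbm, stream$channel_mhz)
  }
  data.frame(
    timestamp_s = stream$timestamp_s,
    prx_deosc = f1,
    rssi_from_min = rssi_from_min(f1, window_n)
  )
}

#' Reduce per-sample features to labelled one-second windows
#'
#' Tiles the record span with half-open windows `[t, t + window_s)` with no
#' overlap, reduces each window to the per-feature mean, and labels it with
#' the majority ground-truth state over the window interval (exact ties
#' resolve to 0, the safety-critical non-breathing class). Windows containing
#' no samples are dropped with a warning.
#'
#' @param features Data frame from [compute_features()], time-sorted.
#' @param timeline A `resp_timeline`.
#' @param window_s Window length in seconds.
#' @return A `windowed_dataset`: list with matrix `X` (n x 2, columns
#'   `prx_deosc`, `rssi_from_min`), integer labels `y`, window start times
#'   `t0`, and `window_s`.
#' @export
build_windows <- function(features, timeline, window_s = 1) {
  stopifnot(all(c("timestamp_s", "prx_deosc", "rssi_from_min") %in% names(features)))
  if (nrow(features) == 0) {
    return(new_windowed_dataset(matrix(numeric(0), 0, 2,
                                       dimnames = list(NULL, c("prx_deosc", "rssi_from_min"))),
                                integer(0), numeric(0), window_s))
  }
  if (is.unsorted(features$timestamp_s)) {
    stop("feature samples must be time-sorted", call. = FALSE)
  }
  t_end <- max(timeline$end_s)
  starts <- seq(0, t_end - window_s + 1e-12, by = window_s)
  idx <- findInterval(features$timestamp_s, c(starts, t_end))
  keep <- idx >= 1 & features$timestamp_s < t_end

  X <- matrix(NA_real_, nrow = length(starts), ncol = 2,
              dimnames = list(NULL, c("prx_deosc", "rssi_from_min")))
  counts <- tabulate(idx[keep], nbins = length(starts))
  f1 <- rowsum(features$prx_deosc[keep], idx[keep])
  f2 <- rowsum(features$rssi_from_min[keep], idx[keep])
  got <- as.integer(rownames(f1))
  X[got, 1] <- f1[, 1] / counts[got]
  X[got, 2] <- f2[, 1] / counts[got]

  y <- vapply(starts, function(s) window_majority_state(timeline, s, s + window_s),
              integer(1))

  empty <- counts == 0
  if (any(empty)) {
    warning(sum(empty), " empty window(s) dropped", call. = FALSE)
  }
  new_windowed_dataset(X[!empty, , drop = FALSE], y[!empty], starts[!empty], window_s)
}

# Majority ground-truth state over [t0, t1); ties resolve to 0 (apnea).
window_majority_state <- function(timeline, t0, t1) {
  ov_start <- pmax(timeline$start_s, t0)
  ov_end <- pmin(timeline$end_s, t1)
  ov <- pmax(ov_end - ov_start, 0)
  breathing <- sum(ov[timeline$state == 1L])
  apnea <- sum(ov[timeline$state == 0L])
  if (breathing > apnea) 1L else 0L
}

new_windowed_dataset <- function(X, y, t0, window_s, provenance = NA_character_) {
  structure(
    list(X = X, y = as.integer(y), t0 = t0, window_s = window_s,
         provenance = provenance),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat("Windowed dataset:", nrow(x$X), "windows of", x$window_s, "s;",
      sum(x$y == 1L), "breathing /", sum(x$y == 0L), "apnea")
  if (!is.na(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Standard-score scaler
#'
#' `fit_scaler()` computes per-feature mean and population standard deviation
#' (divide by n); `apply_scaler()` maps `x` to `(x - mu) / sigma` and
#' `inverse_scaler()` undoes it.
#'
#' @param X Numeric matrix (samples x features).
#' @param scaler A `scaler_params` object.
#' @return `fit_scaler()`: a `scaler_params` list with `mu` and `sigma`;
#'   the others: a transformed matrix.
#' @examples
#' sc <- fit_scaler(matrix(c(1, 2, 3), ncol = 1))
#' apply_scaler(matrix(c(1, 2, 3), ncol = 1), sc)
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sigma <= 0)) {
    stop("cannot standardize a zero-variance feature (column ",
         paste(which(sigma <= 0), collapse = ", "), ")", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma), class = "scaler_params")
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "scaler_params"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$mu), 2, scaler$sigma, "/")
}

#' @rdname fit_scaler
#' @export
inverse_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "scaler_params"))
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$sigma, "*"), 2, scaler$mu, "+")
}

#' Clean, split and standardize a windowed dataset
#'
#' Drops windows with any NaN/NA feature, splits the remainder into train and
#' test partitions (test size `ceiling(test_fraction * N)`), fits the
#' standard-score scaler on the training partition only and applies it to
#' both. The split is random under `seed` by default; `chronological = TRUE`
#' instead holds out the final fraction in time order.
#'
#' @param dataset A `windowed_dataset`.
#' @param test_fraction Fraction held out for testing.
#' @param seed Integer seed for the random split.
#' @param chronological Use a chronological split instead of a random one.
#' @return List with `train`, `test` (both `windowed_dataset`, standardized)
#'   and the fitted `scaler`.
#' @export
clean_and_split <- function(dataset, test_fraction = 0.25, seed = 1L,
                            chronological = FALSE) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  ok <- stats::complete.cases(dataset$X) & is.finite(rowSums(dataset$X))
  X <- dataset$X[ok, , drop = FALSE]
  y <- dataset$y[ok]
  t0 <- dataset$t0[ok]
  n <- nrow(X)
  if (n == 0) stop("no complete windows remain after NaN filtering", call. = FALSE)
  n_test <- ceiling(test_fraction * n)
  if (n_test >= n) stop("test fraction leaves no training data", call. = FALSE)

  if (chronological) {
    test_idx <- seq(n - n_test + 1L, n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    test_idx <- sort(sample.int(n, n_test))
  }
  train_idx <- setdiff(seq_len(n), test_idx)

  scaler <- fit_scaler(X[train_idx, , drop = FALSE])
  train <- new_windowed_dataset(apply_scaler(X[train_idx, , drop = FALSE], scaler),
                                y[train_idx], t0[train_idx], dataset$window_s,
                                provenance = "train")
  test <- new_windowed_dataset(apply_scaler(X[test_idx, , drop = FALSE], scaler),
                               y[test_idx], t0[test_idx], dataset$window_s,
                               provenance = "test")
  list(train = train, test = test, scaler = scaler)
}

#' Write / read the feature and label CSV pair
#'
#' Features and labels travel as two CSV files: `features.csv` with header
#' `timestamp_s,prx_deosc,rssi_from_min` and `labels.csv` with header
#' `timestamp_s,state`.
#'
#' @param features Data frame from [compute_features()].
#' @param labels Data frame with `timestamp_s` and binary `state`.
#' @param dir Output directory (created if missing).
#' @return `write_feature_csvs()`: the directory, invisibly;
#'   `read_feature_csvs()`: list with `features` and `labels`.
#' @export
write_feature_csvs <- function(features, labels, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(format(features, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(format(labels, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_feature_csvs
#' @export
read_feature_csvs <- function(dir) {
  f <- utils::read.csv(file.path(dir, "features.csv"))
  l <- utils::read.csv(file.path(dir, "labels.csv"))
  stopifnot(identical(names(f), c("timestamp_s", "prx_deosc", "rssi_from_min")),
            identical(names(l), c("timestamp_s", "state")))
  list(features = f, labels = l)
}
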