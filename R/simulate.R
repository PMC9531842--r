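#' RFID interrogator/link configuration
#'
#' Parameters of the interrogation link used by the radar-cross-section
#' forward model: the reader polls at `interrogation_rate_total` Hz but each
#' tag is effectively sampled at `effective_rate_per_tag` Hz, hopping over
#' `n_channels` equally spaced channels in the `band_mhz` ISM band.
#'
#' Received power follows the RCS link budget
#' \deqn{P_{Rx} = P_{Tx} G_{reader}^2 G_{tag}^2 R (\lambda / 4 \pi r)^4}
#' where breathing modulates the tag gain and return loss sinusoidally at the
#' breath rate with depth `modulation_depth`.
#'
#' @param interrogation_rate_total Aggregate polling rate, Hz.
#' @param effective_rate_per_tag Effective successful-interrogation rate for
#'   the monitored tag, Hz.
#' @param n_channels Number of hop channels.
#' @param band_mhz Length-2 band limits in MHz.
#' @param p_tx_w Transmit power in W.
#' @param g_reader Reader antenna gain (dimensionless, linear).
#' @param g_tag Nominal tag antenna gain (dimensionless, linear).
#' @param return_loss Nominal return-loss fraction R (dimensionless, linear).
#' @param nominal_r_m Interrogator-tag distance in m (1 ft by default).
#' @param noise_sd_db Standard deviation of additive Gaussian noise on the
#'   dBm-scale RSSI.
#' @param modulation_depth Fractional sinusoidal modulation of tag gain and
#'   return loss during breathing.
#' @param arrival One of `"jittered"` (uniform grid with per-slot jitter) or
#'   `"poisson"`.
#' @return An object of class `rfid_config`.
#' @export
rfid_config <- function(interrogation_rate_total = 90,
                        effective_rate_per_tag = 28,
                        n_channels = 50,
                        band_mhz = c(902, 928),
                        p_tx_w = 1,
                        g_reader = 4,
                        g_tag = 1.6,
                        return_loss = 0.05,
                        nominal_r_m = 0.305,
                        noise_sd_db = 0.1,
                        modulation_depth = 0.05,
                        arrival = c("jittered", "poisson")) {
  arrival <- match.arg(arrival)
  if (effective_rate_per_tag > interrogation_rate_total) {
    stop("`effective_rate_per_tag` cannot exceed `interrogation_rate_total`",
         call. = FALSE)
  }
  if (n_channels < 1) stop("`n_channels` must be >= 1", call. = FALSE)
  if (p_tx_w <= 0) stop("`p_tx_w` must be positive", call. = FALSE)
  if (length(band_mhz) != 2 || band_mhz[1] >= band_mhz[2]) {
    stop("`band_mhz` must be an increasing length-2 interval", call. = FALSE)
  }
  if (noise_sd_db < 0) stop("`noise_sd_db` must be >= 0", call. = FALSE)
  if (modulation_depth < 0 || modulation_depth >= 1) {
    stop("`modulation_depth` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      interrogation_rate_total = interrogation_rate_total,
      effective_rate_per_tag = effective_rate_per_tag,
      n_channels = as.integer(n_channels),
      band_mhz = as.numeric(band_mhz),
      p_tx_w = p_tx_w, g_reader = g_reader, g_tag = g_tag,
      return_loss = return_loss, nominal_r_m = nominal_r_m,
      noise_sd_db = noise_sd_db, modulation_depth = modulation_depth,
      arrival = arrival
    ),
    class = "rfid_config"
  )
}

#' Hop-channel center frequencies
#'
#' `n` equally spaced channel centers spanning the band, in MHz.
#'
#' @param cfg An [rfid_config()].
#' @return Numeric vector of length `cfg$n_channels`.
#' @export
channel_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "rfid_config"))
  width <- diff(cfg$band_mhz) / cfg$n_channels
  cfg$band_mhz[1] + (seq_len(cfg$n_channels) - 0.5) * width
}

#' Convert linear power in W to dBm
#' @param p_w Power in W (positive).
#' @return Power in dBm.
#' @export
w_to_dbm <- function(p_w) {
  if (any(p_w <= 0)) stop("power must be positive to convert to dBm", call. = FALSE)
  10 * log10(p_w / 1e-3)
}

#' Convert dBm to linear power in W
#' @param p_dbm Power in dBm.
#' @return Power in W.
#' @export
dbm_to_w <- function(p_dbm) 1e-3 * 10^(p_dbm / 10)

SPEED_OF_LIGHT <- 2.998e8  # m/s

#' Simulate an RFID interrogation stream over a breathing timeline
#'
#' Forward model: interrogation times arrive at the effective per-tag rate
#' (jittered-uniform by default, Poisson optionally), the reader hops
#' round-robin over the channel plan (one interrogation per dwell), and the
#' received power of each poll is computed from the RCS link budget with the
#' current channel's wavelength. During breathing segments the tag gain and
#' return loss are modulated as `G0 (1 + m sin(2 pi f_b t))` (and analogously
#' for R); during apnea the modulation amplitude is zero so RSSI varies only
#' with channel hop and noise. Gaussian noise of sd `noise_sd_db` is added on
#' the dBm scale.
#'
#' @param timeline A `resp_timeline` from [generate_protocol()].
#' @param cfg An [rfid_config()].
#' @param seed Integer seed controlling arrival jitter and noise.
#' @return A data frame with columns `timestamp_s`, `channel_mhz`,
#'   `rssi_dbm`; timestamps strictly increasing.
#' @examples
#' tl <- generate_protocol(breathing_protocol(total_duration = 60))
#' str(simulate_interrogations(tl, rfid_config(), seed = 1))
#' @export
simulate_interrogations <- function(timeline, cfg = rfid_config(), seed = 1L) {
  stopifnot(inherits(timeline, "resp_timeline"), inherits(cfg, "rfid_config"))
  total <- max(timeline$end_s)
  rate <- cfg$effective_rate_per_tag

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  if (cfg$arrival == "jittered") {
    n <- floor(total * rate)
    ts <- (seq_len(n) - 1) / rate + stats::runif(n, 0, 1 / rate)
  } else {
    # Poisson arrivals: exponential gaps, truncated at total duration
    n_max <- ceiling(total * rate + 10 * sqrt(total * rate)) + 10
    gaps <- stats::rexp(n_max, rate)
    ts <- cumsum(gaps)
    ts <- ts[ts < total]
  }
  ts <- ts[ts < total]
  n <- length(ts)

  freqs <- channel_frequencies(cfg)
  chan <- freqs[((seq_len(n) - 1) %% cfg$n_channels) + 1]
  lambda <- SPEED_OF_LIGHT / (chan * 1e6)

  mod <- cfg$modulation_depth * timeline_phase(timeline, ts)
  g_tag <- cfg$g_tag * (1 + mod)
  r_loss <- cfg$return_loss * (1 + mod)

  p_rx_w <- cfg$p_tx_w * cfg$g_reader^2 * g_tag^2 * r_loss *
    (lambda / (4 * pi * cfg$nominal_r_m))^4
  rssi <- w_to_dbm(p_rx_w)
  if (cfg$noise_sd_db > 0) rssi <- rssi + stats::rnorm(n, 0, cfg$noise_sd_db)

  data.frame(timestamp_s = ts, channel_mhz = chan, rssi_dbm = rssi)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read interrogation streams as CSV
#'
#' Plain comma-separated text with header `timestamp_s,channel_mhz,rssi_dbm`,
#' at full double precision. `read_interrogations_csv()` validates that every
#' row parses to numbers and reports the first offending line on failure.
#'
#' @param stream Data frame as returned by [simulate_interrogations()].
#' @param path File path.
#' @return `write_interrogations_csv()` returns `path` invisibly;
#'   `read_interrogations_csv()` returns the stream data frame.
#' @export
write_interrogations_csv <- function(stream, path) {
  stopifnot(all(c("timestamp_s", "channel_mhz", "rssi_dbm") %in% names(stream)))
  utils::write.csv(
    format(stream[c("timestamp_s", "channel_mhz", "rssi_dbm")],
           digits = 15, trim = TRUE, scientific = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_interrogations_csv
#' @export
read_interrogations_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character")
  expected <- c("timestamp_s", "channel_mhz", "rssi_dbm")
  if (!identical(names(df), expected)) {
    stop("malformed header: expected ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  out <- df
  for (col in expected) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("malformed value in column '%s' at line %d: '%s'",
                   col, bad[1] + 1L, df[[col]][bad[1]]), call. = FALSE)
    }
    out[[col]] <- vals
  }
  out
}
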