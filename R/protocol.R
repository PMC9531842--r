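#' Breathing protocol for a programmable infant mannequin
#'
#' Describes the ground-truth schedule the mannequin follows: sinusoidal
#' chest-wall breathing at a fixed rate, interleaved with apnea pauses of
#' fixed durations, alternating until `total_duration` is filled. The default
#' protocol breathes at 31 breaths/min and pauses for 30, 45 and 60 s.
#'
#' @param breaths_per_minute Breathing rate during breathing segments, in
#'   breaths per minute.
#' @param apnea_durations Apnea pause lengths in seconds, cycled in order.
#' @param breathing_segment_durations Breathing segment lengths in seconds,
#'   cycled in order between apnea pauses.
#' @param total_duration Total schedule length in seconds.
#' @return An object of class `breathing_protocol`.
#' @examples
#' breathing_protocol(total_duration = 600)
#' @export
breathing_protocol <- function(breaths_per_minute = 31,
                               apnea_durations = c(30, 45, 60),
                               breathing_segment_durations = c(120, 120, 120),
                               total_duration = 3600) {
  if (!is.numeric(breaths_per_minute) || length(breaths_per_minute) != 1 ||
      breaths_per_minute <= 0) {
    stop("`breaths_per_minute` must be a single positive number", call. = FALSE)
  }
  if (length(apnea_durations) > 0 && any(apnea_durations <= 0)) {
    stop("all `apnea_durations` must be positive", call. = FALSE)
  }
  if (length(breathing_segment_durations) > 0 &&
      any(breathing_segment_durations <= 0)) {
    stop("all `breathing_segment_durations` must be positive", call. = FALSE)
  }
  if (!is.numeric(total_duration) || total_duration <= 0) {
    stop("`total_duration` must be positive", call. = FALSE)
  }
  structure(
    list(
      breaths_per_minute = breaths_per_minute,
      apnea_durations = as.numeric(apnea_durations),
      breathing_segment_durations = as.numeric(breathing_segment_durations),
      total_duration = as.numeric(total_duration)
    ),
    class = "breathing_protocol"
  )
}

#' @export
print.breathing_protocol <- function(x, ...) {
  cat("Breathing protocol:\n")
  cat("  rate:          ", x$breaths_per_minute, "breaths/min\n")
  cat("  apnea pauses:  ", paste(x$apnea_durations, collapse = ", "), "s\n")
  cat("  breathing segs:", paste(x$breathing_segment_durations, collapse = ", "), "s\n")
  cat("  total:         ", x$total_duration, "s\n")
  invisible(x)
}

#' Expand a breathing protocol into a ground-truth timeline
#'
#' Alternates breathing and apnea segments (starting with breathing, cycling
#' each duration list) until the schedule exactly tiles
#' `[0, total_duration]`; the final segment is truncated if needed. During
#' breathing segments the chest displacement follows a sinusoid at
#' `breaths_per_minute`, with phase zero at the segment start.
#'
#' @param protocol A [breathing_protocol()].
#' @param seed Unused (the timeline is deterministic); accepted so all
#'   generator stages share one calling convention.
#' @return A `resp_timeline`: data frame with columns `start_s`, `end_s`,
#'   `state` (1 breathing, 0 apnea) and attribute `breath_freq_hz`.
#' @examples
#' tl <- generate_protocol(breathing_protocol(total_duration = 600))
#' sum(tl$end_s - tl$start_s)  # 600
#' @export
generate_protocol <- function(protocol, seed = NULL) {
  stopifnot(inherits(protocol, "breathing_protocol"))
  total <- protocol$total_duration
  b_durs <- protocol$breathing_segment_durations
  a_durs <- protocol$apnea_durations
  if (length(b_durs) == 0 && length(a_durs) == 0) {
    stop("protocol defines no segments", call. = FALSE)
  }

  start <- numeric(0)
  end <- numeric(0)
  state <- integer(0)
  t <- 0
  bi <- 0L
  ai <- 0L
  # degenerate protocols: only apnea or only breathing
  breathing_next <- length(b_durs) > 0
  while (t < total - 1e-9) {
    if (breathing_next && length(b_durs) > 0) {
      bi <- bi + 1L
      dur <- b_durs[((bi - 1L) %% length(b_durs)) + 1L]
      s <- 1L
    } else {
      ai <- ai + 1L
      dur <- a_durs[((ai - 1L) %% length(a_durs)) + 1L]
      s <- 0L
    }
    seg_end <- min(t + dur, total)
    start <- c(start, t)
    end <- c(end, seg_end)
    state <- c(state, s)
    t <- seg_end
    if (length(b_durs) > 0 && length(a_durs) > 0) {
      breathing_next <- !breathing_next
    }
  }

  tl <- data.frame(start_s = start, end_s = end, state = state)
  attr(tl, "breath_freq_hz") <- protocol$breaths_per_minute / 60
  class(tl) <- c("resp_timeline", "data.frame")
  tl
}

#' Ground-truth breathing state at given times
#'
#' @param timeline A `resp_timeline` from [generate_protocol()].
#' @param t Numeric vector of times in seconds.
#' @return Integer vector: 1 breathing, 0 apnea, at each `t`.
#' @export
timeline_state <- function(timeline, t) {
  stopifnot(inherits(timeline, "resp_timeline"))
  idx <- findInterval(t, timeline$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(timeline)] <- nrow(timeline)
  as.integer(timeline$state[idx])
}

#' Chest-displacement phase during breathing
#'
#' Returns sin(2 pi f_b (t - segment start)) inside breathing segments and 0
#' during apnea: the modulation that breathing imprints on the tag antenna.
#'
#' @inheritParams timeline_state
#' @return Numeric vector in `[-1, 1]`.
#' @export
timeline_phase <- function(timeline, t) {
  stopifnot(inherits(timeline, "resp_timeline"))
  f_b <- attr(timeline, "breath_freq_hz")
  idx <- findInterval(t, timeline$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(timeline)] <- nrow(timeline)
  breathing <- timeline$state[idx] == 1L
  out <- numeric(length(t))
  out[breathing] <- sin(2 * pi * f_b * (t[breathing] - timeline$start_s[idx[breathing]]))
  out
}
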