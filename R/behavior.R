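#' Align the video clock to the audio clock
#'
#' Video-scored behaviour and audio events are synchronised through
#' recognisable anchor events (e.g. songs) identified on both clocks. With
#' one anchor a constant offset is applied; with two or more, a
#' least-squares affine map `audio = intercept + slope * video` is fitted,
#' which also absorbs clock drift.
#'
#' @param anchor_pairs A tibble/data frame with columns `video_s` and
#'   `audio_s` (matched event times on each clock).
#' @param max_residual_s Warn when any anchor residual exceeds this
#'   (default 0.5 s — inconsistent anchors).
#' @return A list of class `clock_map`: `intercept`, `slope`, `residuals`,
#'   and `transform(t)`, a function mapping video seconds to audio seconds.
#' @export
#' @examples
#' m <- align_streams(data.frame(video_s = 10, audio_s = 12.5))
#' m$transform(60)  # 62.5
align_streams <- function(anchor_pairs, max_residual_s = 0.5) {
  need <- c("video_s", "audio_s")
  if (!all(need %in% names(anchor_pairs)) || nrow(anchor_pairs) < 1) {
    abort("`anchor_pairs` needs >= 1 row with columns video_s, audio_s.")
  }
  v <- anchor_pairs$video_s
  a <- anchor_pairs$audio_s
  if (length(v) == 1L) {
    slope <- 1
    intercept <- a - v
  } else {
    fit <- stats::lm(a ~ v)
    intercept <- unname(stats::coef(fit)[1])
    slope <- unname(stats::coef(fit)[2])
  }
  res <- a - (intercept + slope * v)
  if (any(abs(res) > max_residual_s)) {
    warn(sprintf("anchor residuals up to %.3f s exceed %.2f s; check anchors.",
                 max(abs(res)), max_residual_s))
  }
  structure(list(intercept = intercept, slope = slope, residuals = res,
                 transform = function(t) intercept + slope * t),
            class = "clock_map")
}

#' Apply a clock map to a behaviour track
#'
#' @param track A `behavior_track` (or any tibble with `start_s`, `stop_s`).
#' @param map A `clock_map` from [align_streams()].
#' @return The track with `start_s`, `stop_s` mapped onto the audio clock.
#' @export
transform_track <- function(track, map) {
  track$start_s <- map$transform(track$start_s)
  track$stop_s <- map$transform(track$stop_s)
  track
}

#' Time spent clumping
#'
#' Total seconds of physical contact ("Clumping") and its proportion of the
#' scored time.
#'
#' @param track A behaviour-interval tibble with `state`, `start_s`,
#'   `stop_s`.
#' @param scored_total_s Total scored time (s); defaults to the track's
#'   `scored_total_s` attribute, else the track's coverage.
#' @param state State name counted as physical contact (default
#'   `"Clumping"`).
#' @return A list with `seconds`, `proportion`, and `percent`.
#' @export
#' @examples
#' trk <- tibble::tibble(state = "Clumping", start_s = 0, stop_s = 919)
#' clumping_proportion(trk, scored_total_s = 3600)$percent  # 25.5
clumping_proportion <- function(track, scored_total_s = NULL,
                                state = "Clumping") {
  if (is.null(scored_total_s)) {
    scored_total_s <- attr(track, "scored_total_s") %||%
      sum(track$stop_s - track$start_s)
  }
  check_number(scored_total_s, "scored_total_s", lower = 1e-12)
  secs <- sum(pmax(track$stop_s - track$start_s, 0)[track$state == state])
  list(seconds = secs, proportion = secs / scored_total_s,
       percent = 100 * secs / scored_total_s)
}

#' Calling rate within each behaviour state
#'
#' For every behaviour state, the number of call onsets falling inside that
#' state's intervals divided by the state's total duration (calls/s). An
#' onset on an interval boundary belongs to the interval whose half-open
#' `[start, stop)` range contains it. States with zero total duration get
#' `NA`, not 0. Events outside the scored intervals are ignored; their
#' count is reported.
#'
#' @param events A tibble with an `onset_s` column (pre-aligned to the
#'   behaviour clock), optionally filtered to one call type.
#' @param track A behaviour-interval tibble (`state`, `start_s`, `stop_s`)
#'   with non-overlapping intervals.
#' @param states States to report; defaults to those present in `track`.
#' @return A tibble `state`, `n_calls`, `state_s`, `rate_per_s`, with
#'   attribute `n_outside` (events outside all intervals).
#' @export
rate_by_state <- function(events, track, states = NULL) {
  states <- states %||% unique(track$state)
  ord <- order(track$start_s)
  starts <- track$start_s[ord]
  stops <- track$stop_s[ord]
  lab <- track$state[ord]
  idx <- findInterval(events$onset_s, starts)
  inside <- idx >= 1L & events$onset_s < stops[pmax(idx, 1L)]
  ev_state <- ifelse(inside, lab[pmax(idx, 1L)], NA_character_)

  out <- tibble(state = states) |>
    mutate(
      n_calls = vapply(states, function(s) sum(ev_state == s, na.rm = TRUE),
                       numeric(1), USE.NAMES = FALSE),
      state_s = vapply(states, function(s)
        sum((stops - starts)[lab == s]), numeric(1), USE.NAMES = FALSE),
      rate_per_s = if_else(.data$state_s > 0,
                           .data$n_calls / .data$state_s, NA_real_)
    )
  attr(out, "n_outside") <- sum(!inside)
  out
}
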