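#' Segment vocalizations from a continuous recording
#'
#' Detects calls as maximal runs where the smoothed dB amplitude envelope
#' exceeds a threshold. The envelope is a moving-RMS (window `env_win_s`)
#' expressed in dB relative to full scale (dBFS). Runs separated by less
#' than `min_gap_s` are merged; runs shorter than `min_dur_s` are discarded.
#'
#' @param wave Numeric mono waveform, nominally in \code{[-1, 1]}.
#' @param sample_rate Samples per second.
#' @param threshold_db Envelope threshold in dBFS (e.g. -35).
#' @param min_dur_s Minimum segment duration (s).
#' @param min_gap_s Gaps shorter than this are merged (s).
#' @param env_win_s Moving-RMS window (s); default 5 ms.
#'
#' @return A tibble of class `segments` with columns `segment_id`,
#'   `onset_s`, `offset_s`, `duration_s`, and `peak_db` (maximum envelope
#'   within the segment, dBFS). Zero rows for silence.
#' @export
segment_vocalizations <- function(wave, sample_rate,
                                  threshold_db = -35,
                                  min_dur_s = 0.02,
                                  min_gap_s = 0.02,
                                  env_win_s = 0.005) {
  if (any(!is.finite(wave))) abort("`wave` must be finite.")
  env_db <- envelope_db(wave, sample_rate, env_win_s)
  active <- env_db > threshold_db
  runs <- active_runs(active)
  if (nrow(runs) == 0) return(empty_segments())

  # merge runs separated by short gaps
  gap <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) / sample_rate
  grp <- cumsum(c(0, gap >= min_gap_s))
  runs <- tibble(start = tapply(runs$start, grp, min),
                 end = tapply(runs$end, grp, max))

  out <- tibble(
    onset_s = (runs$start - 1L) / sample_rate,
    offset_s = runs$end / sample_rate
  ) |>
    mutate(duration_s = .data$offset_s - .data$onset_s) |>
    filter(.data$duration_s >= min_dur_s)
  out$peak_db <- vapply(seq_len(nrow(out)), function(i) {
    idx <- max(1L, floor(out$onset_s[i] * sample_rate)):
      min(length(env_db), ceiling(out$offset_s[i] * sample_rate))
    max(env_db[idx])
  }, numeric(1))
  out <- mutate(out, segment_id = dplyr::row_number(), .before = 1)
  class(out) <- c("segments", class(out))
  out
}

envelope_db <- function(wave, sample_rate, env_win_s) {
  win <- max(1L, round(env_win_s * sample_rate))
  kernel <- rep(1 / win, win)
  ms <- stats::filter(wave^2, kernel, sides = 2)
  ms[is.na(ms)] <- 0
  10 * log10(pmax(as.numeric(ms), 1e-12))
}

active_runs <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

empty_segments <- function() {
  out <- tibble(segment_id = integer(), onset_s = numeric(),
                offset_s = numeric(), duration_s = numeric(),
                peak_db = numeric())
  class(out) <- c("segments", class(out))
  out
}

#' Extract the waveform slice of each segment
#'
#' @param segments A `segments` tibble from [segment_vocalizations()].
#' @param wave,sample_rate The source waveform.
#' @return A list of numeric waveform slices, one per segment.
#' @export
segment_waves <- function(segments, wave, sample_rate) {
  lapply(seq_len(nrow(segments)), function(i) {
    a <- max(1L, floor(segments$onset_s[i] * sample_rate) + 1L)
    b <- min(length(wave), ceiling(segments$offset_s[i] * sample_rate))
    wave[a:b]
  })
}
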