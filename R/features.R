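#' Spectro-temporal features of a single call
#'
#' Computes the ten acoustic parameters used for call typing, from a
#' short-time Fourier magnitude spectrogram (Hann window) plus the raw
#' waveform:
#'
#' * `duration_s` — segment duration;
#' * `mean_freq_hz` — amplitude-weighted spectral centroid, averaged over
#'   frames, and `mean_freq_sd_hz`, the SD of the per-frame centroids;
#' * `mode_freq_hz` — mean over frames of the per-frame peak (arg-max)
#'   frequency, and `mode_freq_sd_hz`, its SD;
#' * `first_peak_hz` — mean per-frame frequency of the lowest-frequency
#'   local spectral maximum whose magnitude exceeds `peak_floor` times the
#'   frame maximum (a proxy for the fundamental), and `first_peak_sd_hz`;
#' * `zero_crossing_rate_per_s` — waveform sign changes per second (the raw
#'   count is returned as `zero_crossings`);
#' * `max_positive_peak`, `min_negative_peak` — raw amplitude extrema.
#'
#' Frequency SDs are taken across spectrogram frames. A constant
#' (degenerate) signal yields zero frequencies and `degenerate = TRUE`.
#'
#' @param wave Numeric waveform slice of one call.
#' @param sample_rate Samples per second.
#' @param window STFT window length in samples (default 512).
#' @param overlap Fractional window overlap (default 0.75).
#' @param peak_floor Fraction of the frame maximum a local spectral maximum
#'   must reach to count as the "first peak" (default 0.1).
#'
#' @return A one-row tibble with the fields above.
#' @export
#' @examples
#' sr <- 44100
#' tone <- sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / sr))
#' extract_features(tone, sr)
extract_features <- function(wave, sample_rate, window = 512,
                             overlap = 0.75, peak_floor = 0.1) {
  duration_s <- length(wave) / sample_rate
  zc <- sum(diff(sign(wave[wave != 0])) != 0)
  degenerate <- max(wave) - min(wave) < 1e-12
  if (length(wave) < 2 * window * (1 - overlap) + window) {
    # zero-pad very short calls so at least two STFT frames exist;
    # duration and zero crossings above use the unpadded call
    wave <- c(wave, numeric(window * 2))
  }

  if (degenerate) {
    warn("degenerate (constant) signal; frequency features set to 0.")
    freqs <- list(mean = 0, mean_sd = 0, mode = 0, mode_sd = 0,
                  first = 0, first_sd = 0)
  } else {
    sp <- signal::specgram(wave, n = window, Fs = sample_rate,
                           window = signal::hanning(window),
                           overlap = round(overlap * window))
    mag <- abs(sp$S)
    f <- as.numeric(sp$f)
    centroid <- colSums(mag * f) / pmax(colSums(mag), 1e-30)
    peak_f <- f[apply(mag, 2, which.max)]
    first_f <- apply(mag, 2, function(m) {
      floor_amp <- peak_floor * max(m)
      k <- length(m)
      is_max <- m >= floor_amp &
        m >= c(-Inf, m[-k]) & m >= c(m[-1], -Inf)
      if (!any(is_max)) return(NA_real_)
      f[which(is_max)[1]]
    })
    first_f <- first_f[is.finite(first_f)]
    sd0 <- function(x) if (length(x) > 1) sd(x) else 0
    freqs <- list(mean = mean(centroid), mean_sd = sd0(centroid),
                  mode = mean(peak_f), mode_sd = sd0(peak_f),
                  first = if (length(first_f)) mean(first_f) else 0,
                  first_sd = sd0(first_f))
  }

  tibble(
    duration_s = duration_s,
    mean_freq_hz = freqs$mean,
    mean_freq_sd_hz = freqs$mean_sd,
    mode_freq_hz = freqs$mode,
    mode_freq_sd_hz = freqs$mode_sd,
    first_peak_hz = freqs$first,
    first_peak_sd_hz = freqs$first_sd,
    zero_crossing_rate_per_s = zc / duration_s,
    zero_crossings = zc,
    max_positive_peak = max(wave, 0),
    min_negative_peak = min(wave, 0),
    degenerate = degenerate
  )
}

#' Feature table for a set of segments
#'
#' Applies [extract_features()] to every segment slice of a recording and
#' binds the results with the segment metadata.
#'
#' @param segments A `segments` tibble.
#' @param wave,sample_rate Source waveform.
#' @inheritParams extract_features
#' @return A tibble: segment columns plus one feature column set per row.
#' @export
extract_features_table <- function(segments, wave, sample_rate,
                                   window = 512, overlap = 0.75,
                                   peak_floor = 0.1) {
  slices <- segment_waves(segments, wave, sample_rate)
  feats <- purrr::map(slices, extract_features, sample_rate = sample_rate,
                      window = window, overlap = overlap,
                      peak_floor = peak_floor)
  dplyr::bind_cols(
    select(segments, "segment_id", "onset_s", "offset_s", "peak_db"),
    bind_rows(feats) |> select(-"duration_s"),
    tibble(duration_s = segments$duration_s)
  )
}
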