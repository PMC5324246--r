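#' Tonal call templates for synthetic audio
#'
#' Builds one short tonal waveform per call type: a sinusoid (optionally a
#' linear chirp) with a Hann amplitude envelope, enough to give call types
#' distinguishable spectro-temporal features without modelling real zebra
#' finch acoustics.
#'
#' @param types Character vector of call-type names.
#' @param freq_hz Carrier frequency per type (recycled).
#' @param duration_s Template duration per type (recycled).
#' @param chirp_hz Linear frequency sweep added over the call (recycled;
#'   0 = pure tone).
#' @param sample_rate Samples per second.
#' @return Named list of numeric waveforms in \code{[-1, 1]}.
#' @export
call_templates <- function(types,
                           freq_hz = 500 * 2^(seq_along(types) - 1),
                           duration_s = 0.09,
                           chirp_hz = 0,
                           sample_rate = 44100) {
  freq_hz <- rep_len(freq_hz, length(types))
  duration_s <- rep_len(duration_s, length(types))
  chirp_hz <- rep_len(chirp_hz, length(types))
  out <- lapply(seq_along(types), function(i) {
    t <- seq(0, duration_s[i], by = 1 / sample_rate)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_along(t) / length(t))
    env * sin(2 * pi * (freq_hz[i] * t + chirp_hz[i] * t^2 / (2 * duration_s[i])))
  })
  setNames(out, types)
}

#' Render per-bird audio channels from an event table
#'
#' Emulates a backpack-microphone recording: each bird's channel is the sum
#' of its own calls at `own_gain` and of the partner's calls attenuated to
#' `partner_gain` (acoustic leak), placed at their onsets, plus optional
#' white noise. Overlapping placements are summed. The mixed channel is
#' peak-normalized to `peak` to avoid clipping; the applied scale factor is
#' returned so amplitudes remain interpretable.
#'
#' @param events A `pair_events` tibble (or any tibble with `bird`,
#'   `onset_s`, `call_type`).
#' @param templates Named list of waveforms, one per call type
#'   (see [call_templates()]).
#' @param sample_rate Samples per second (default 44100).
#' @param own_gain,partner_gain Linear gains; must satisfy
#'   `own_gain > partner_gain >= 0`.
#' @param noise_sd Standard deviation of additive white noise (0 = off).
#' @param duration_s Channel length in seconds; defaults to the simulation
#'   duration attached to `events`, else last onset + 1 s.
#' @param seed RNG seed for the noise.
#' @return Named list with elements `F` and `M`, each a list holding
#'   `wave` (numeric), `sample_rate`, and `scale` (the normalization factor
#'   applied).
#' @export
render_audio <- function(events, templates, sample_rate = 44100,
                         own_gain = 1, partner_gain = 0.1,
                         noise_sd = 0, duration_s = NULL, seed = 1L) {
  if (!own_gain > partner_gain || partner_gain < 0) {
    abort("gains must satisfy own_gain > partner_gain >= 0.")
  }
  missing_t <- setdiff(unique(events$call_type), names(templates))
  if (length(missing_t)) {
    abort(paste0("no template for call type(s): ",
                 paste(missing_t, collapse = ", ")))
  }
  if (is.null(duration_s)) {
    cfg <- attr(events, "config")
    duration_s <- if (!is.null(cfg)) cfg$duration_s else
      if (nrow(events)) max(events$onset_s) + 1 else 1
  }
  n <- ceiling(duration_s * sample_rate) + max(0L, lengths(templates))
  seeds <- split_seed(seed, 2L)

  mix_channel <- function(own_bird, chan_seed) {
    wave <- numeric(n)
    for (i in seq_len(nrow(events))) {
      tpl <- templates[[events$call_type[i]]]
      g <- if (events$bird[i] == own_bird) own_gain else partner_gain
      if (g == 0) next
      at <- floor(events$onset_s[i] * sample_rate) + 1L
      idx <- at:(at + length(tpl) - 1L)
      wave[idx] <- wave[idx] + g * tpl
    }
    if (noise_sd > 0) {
      wave <- wave + withr::with_seed(chan_seed, rnorm(n, sd = noise_sd))
    }
    peak <- max(abs(wave), 1e-12)
    scale <- if (peak > 0.99) 0.99 / peak else 1
    list(wave = wave * scale, sample_rate = sample_rate, scale = scale)
  }
  list(F = mix_channel("F", seeds[1]), M = mix_channel("M", seeds[2]))
}

#' Minimal WAV read/write (PCM 16-bit mono)
#'
#' Lightweight RIFF/WAVE I/O for the synthetic channels this package
#' renders: single-channel 16-bit PCM only.
#'
#' @param wave Numeric vector in \code{[-1, 1]}.
#' @param path Output/input file path.
#' @param sample_rate Samples per second.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns a
#'   list with `wave` (numeric in \code{[-1, 1]}) and `sample_rate`.
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) abort("not a RIFF/WAVE file.")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) abort("not a RIFF/WAVE file.")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) abort("no data chunk found.")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono PCM supported.")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2L, size = 2, endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
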