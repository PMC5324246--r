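#' Read and write call-event tables
#'
#' Event CSVs have one row per call with columns `bird_id`, `onset_s`,
#' `duration_s`, `call_type`, and optionally `is_answer`, `trigger_index`,
#' plus any grouping columns (`pair_id`, `day`, ...). On reading, the
#' `bird_id` column is renamed to `bird`; validation failures name the
#' file, row and column.
#'
#' @param path CSV file path.
#' @param events An event tibble (e.g. from [simulate_pair_calling()]).
#' @return `read_events()`: a validated event tibble sorted by onset;
#'   `write_events()`: `path`, invisibly.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  if ("bird_id" %in% names(ev)) ev <- rename(ev, bird = "bird_id")
  for (col in c("bird", "onset_s")) {
    if (!col %in% names(ev)) {
      abort(sprintf("%s: missing required column `%s`.", path, col))
    }
  }
  bad <- which(!is.finite(ev$onset_s))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric or missing onset_s at row %d (column onset_s).",
                  path, bad[1]))
  }
  if (!"duration_s" %in% names(ev)) ev$duration_s <- NA_real_
  if (!"call_type" %in% names(ev)) ev$call_type <- NA_character_
  arrange(ev, .data$onset_s)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  out <- as_tibble(events)
  if ("bird" %in% names(out)) out <- rename(out, bird_id = "bird")
  if ("trigger_id" %in% names(out)) {
    out <- rename(out, trigger_index = "trigger_id")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write behaviour-interval tables
#'
#' Behaviour CSVs have columns `state`, `start_s`, `stop_s` (the layout of
#' common event-logger exports), plus optional grouping columns.
#'
#' @param path CSV file path.
#' @param track A behaviour-interval tibble.
#' @return `read_behavior()`: a validated interval tibble;
#'   `write_behavior()`: `path`, invisibly.
#' @export
read_behavior <- function(path) {
  trk <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("state", "start_s", "stop_s")) {
    if (!col %in% names(trk)) {
      abort(sprintf("%s: missing required column `%s`.", path, col))
    }
  }
  bad <- which(!is.finite(trk$start_s) | !is.finite(trk$stop_s) |
                 trk$stop_s <= trk$start_s)
  if (length(bad)) {
    abort(sprintf("%s: invalid interval at row %d (columns start_s/stop_s).",
                  path, bad[1]))
  }
  trk
}

#' @rdname read_behavior
#' @export
write_behavior <- function(track, path) {
  readr::write_csv(as_tibble(track), path)
  invisible(path)
}
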