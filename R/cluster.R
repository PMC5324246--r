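#' Cluster calls into type categories
#'
#' Model-based clustering of the spectro-temporal feature vectors into `k`
#' call-type categories: a Gaussian mixture with unconstrained covariances
#' fitted to z-scored features (via \pkg{mclust}). Segments whose maximum
#' cluster posterior falls below `unassigned_below` are labelled
#' `"Unassigned"`, mirroring the small residual category of calls that
#' cannot be typed. Hard labels plus per-segment posteriors are returned so
#' the assignment can be exported, manually refined in a label file, and
#' re-ingested with [apply_labels()].
#'
#' @param features A data frame / tibble of numeric feature columns (one
#'   row per segment). Non-numeric columns are ignored; constant columns
#'   are dropped before z-scoring.
#' @param k Number of clusters, `2 <= k <= nrow(features)`.
#' @param seed Integer RNG seed (clustering is then deterministic).
#' @param unassigned_below Posterior threshold under which a segment is
#'   labelled Unassigned (default 0.6).
#'
#' @return A tibble with `cluster` (integer), `label` (`"C1"`, ..., or
#'   `"Unassigned"`), `posterior` (max posterior), and one `p_C<i>` column
#'   per cluster.
#' @export
cluster_calls <- function(features, k, seed = 1L, unassigned_below = 0.6) {
  num <- features[vapply(features, is.numeric, logical(1))]
  num <- num[, !names(num) %in% c("segment_id", "onset_s", "offset_s"),
             drop = FALSE]
  n <- nrow(num)
  if (!is.numeric(k) || k < 2 || k > n) {
    abort(sprintf("`k` must satisfy 2 <= k <= %d.", n))
  }
  keep <- vapply(num, function(x) sd(x) > 1e-12, logical(1))
  if (!any(keep)) {
    # all rows identical: one effective cluster
    warn("all feature rows identical; returning a single degenerate cluster.")
    return(tibble(cluster = rep(1L, n), label = "C1",
                  posterior = rep(1, n), degenerate = TRUE))
  }
  z <- scale(as.matrix(num[keep]))

  # richest covariance structure the sample size supports; BIC picks
  model_names <- if (ncol(z) > 1) c("VVV", "VVI", "VEI", "VII", "EII") else "V"
  fit <- withr::with_seed(as.integer(seed), suppressWarnings(
    mclust::Mclust(z, G = k, modelNames = model_names, verbose = FALSE)))
  if (is.null(fit)) {
    # too few segments for any mixture: fall back to k-means hard labels
    warn("mixture fit failed; falling back to k-means (posteriors are 0/1).")
    km <- withr::with_seed(as.integer(seed),
                           stats::kmeans(z, centers = k, nstart = 10))
    post <- matrix(0, nrow = n, ncol = k)
    post[cbind(seq_len(n), km$cluster)] <- 1
    fit <- list(classification = km$cluster, z = post)
  }
  post <- fit$z
  maxp <- apply(post, 1, max)
  lab <- paste0("C", fit$classification)
  lab[maxp < unassigned_below] <- "Unassigned"
  out <- tibble(cluster = as.integer(fit$classification),
                label = lab, posterior = maxp, degenerate = FALSE)
  colnames(post) <- paste0("p_C", seq_len(ncol(post)))
  dplyr::bind_cols(out, as_tibble(post))
}

#' Apply an edited label file to a segment table
#'
#' The manual-refinement step: cluster labels exported to CSV
#' (`segment_id,label`), edited by eye, are re-ingested verbatim.
#'
#' @param segments A tibble containing a `segment_id` column.
#' @param labels A tibble (or CSV path) with columns `segment_id`, `label`.
#' @return `segments` with a `label` column (overwritten if present).
#' @export
apply_labels <- function(segments, labels) {
  if (is.character(labels)) {
    labels <- readr::read_csv(labels, show_col_types = FALSE)
  }
  if (!all(c("segment_id", "label") %in% names(labels))) {
    abort("`labels` must have columns `segment_id` and `label`.")
  }
  segments$label <- NULL
  left_join(segments, select(labels, "segment_id", "label"),
            by = "segment_id")
}

#' Remove non-focal (partner-leak) detections
#'
#' On a backpack recording the bird's own calls dominate; occasional calls
#' of other birds picked up by the microphone are recognisable by their
#' much lower intensity. Segments whose peak amplitude lies more than
#' `intensity_margin_db` below the mode of the channel's own-call peak
#' amplitudes are removed.
#'
#' @param segments A tibble with a `peak_db` column (dBFS, as produced by
#'   [segment_vocalizations()]).
#' @param intensity_margin_db Margin below the own-call amplitude mode
#'   beyond which a segment is considered non-focal (default 10; `Inf`
#'   removes nothing).
#' @return `segments` with a logical `focal` column; attribute
#'   `"mode_peak_db"` records the estimated own-call amplitude mode.
#' @export
remove_nonfocal <- function(segments, intensity_margin_db = 10) {
  if (nrow(segments) == 0) {
    segments$focal <- logical(0)
    return(segments)
  }
  if (!"peak_db" %in% names(segments)) {
    abort("`segments` must carry a `peak_db` column.")
  }
  mode_db <- density_mode(segments$peak_db)
  segments$focal <- segments$peak_db >= mode_db - intensity_margin_db
  attr(segments, "mode_peak_db") <- mode_db
  segments
}

# amplitude mode via kernel density; falls back to median for tiny n
density_mode <- function(x) {
  if (length(x) < 3 || sd(x) < 1e-12) return(median(x))
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Number of songs from syllable counts
#'
#' Male zebra finches embed song syllables among their calls; the number of
#' songs is estimated by dividing the total number of song syllables by the
#' male's average number of syllables per song.
#'
#' @param total_song_syllables Total syllables attributed to song.
#' @param mean_syllables_per_song The male's average syllables per song
#'   (> 0).
#' @return A list with `songs` (unrounded quotient) and `songs_rounded`.
#' @export
#' @examples
#' count_songs(47, 5)  # 9.4 songs, rounds to 9
count_songs <- function(total_song_syllables, mean_syllables_per_song) {
  check_number(total_song_syllables, "total_song_syllables", lower = 0)
  if (!is.numeric(mean_syllables_per_song) ||
      mean_syllables_per_song <= 0) {
    abort("`mean_syllables_per_song` must be > 0.")
  }
  q <- total_song_syllables / mean_syllables_per_song
  list(songs = q, songs_rounded = round(q))
}

#' Call-type proportions per bird and day
#'
#' Proportion of each call type relative to the bird and day, so the
#' proportions for one bird on one day sum to 1. Unassigned is a category
#' of its own. Bird-days with no events are absent from the output (they
#' carry no proportions).
#'
#' @param events A tibble with columns `bird` (or `bird_id`), `call_type`,
#'   and optionally `day` (a single implicit day is assumed if missing).
#' @return A tibble `bird`, `day`, `call_type`, `n`, `proportion`.
#' @export
call_type_proportions <- function(events) {
  if (nrow(events) == 0) {
    abort("`events` is empty: no bird-day has any call to proportion.")
  }
  if (!"bird" %in% names(events) && "bird_id" %in% names(events)) {
    events <- rename(events, bird = "bird_id")
  }
  if (!"day" %in% names(events)) events$day <- 1L
  events |>
    count(.data$bird, .data$day, .data$call_type, name = "n") |>
    group_by(.data$bird, .data$day) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
}
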