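#' Count answer and answered calls
#'
#' Partner calls within half a second after a focal call are *answers*;
#' partner calls within half a second before a focal call are *answered*
#' (the focal bird answered them). Formally, with lag = partner − focal:
#' answers have lag in `(0, window_s]`, answered have lag in
#' `[-window_s, 0)`; an exact tie (lag 0) counts as answered.
#'
#' By default each partner call is assigned to its nearest focal call only
#' (`dedupe = TRUE`), so no partner call is counted twice and
#' `n_answers + n_answered` never exceeds the number of partner calls.
#' `dedupe = FALSE` counts every (focal, partner) pair within the window —
#' the literal all-pairs reading.
#'
#' @param focal_onsets,partner_onsets Numeric onset vectors (seconds, same
#'   clock).
#' @param window_s Answer window (s), default 0.5.
#' @param dedupe Assign each partner call to its nearest focal call only
#'   (default `TRUE`).
#' @return A list with `n_answers`, `n_answered`.
#' @export
#' @examples
#' count_answers(c(1.0), c(1.3))  # one answer
#' count_answers(c(1.0), c(0.7))  # one answered
count_answers <- function(focal_onsets, partner_onsets, window_s = 0.5,
                          dedupe = TRUE) {
  check_number(window_s, "window_s", lower = 1e-12)
  focal <- sort(as.numeric(focal_onsets))
  partner <- sort(as.numeric(partner_onsets))
  if (!length(focal) || !length(partner)) {
    return(list(n_answers = 0L, n_answered = 0L))
  }
  if (dedupe) {
    # nearest focal call for each partner call
    pos <- findInterval(partner, focal)
    left <- focal[pmax(pos, 1L)]
    right <- focal[pmin(pos + 1L, length(focal))]
    d_left <- ifelse(pos >= 1L, partner - left, Inf)
    d_right <- ifelse(pos < length(focal), right - partner, Inf)
    # lag of partner relative to its nearest focal: partner after its
    # nearest focal -> +d_left (answer side); before -> -d_right (answered);
    # a tie at lag 0 gives +0 and is counted as answered below
    nearest_lag <- ifelse(d_left <= d_right, d_left, -d_right)
    n_answers <- sum(nearest_lag > 0 & nearest_lag <= window_s)
    n_answered <- sum(nearest_lag <= 0 & nearest_lag >= -window_s)
  } else {
    lags <- pair_lags(focal, partner, window_s)
    n_answers <- sum(lags > 0 & lags <= window_s)
    n_answered <- sum(lags <= 0 & lags >= -window_s)
  }
  list(n_answers = as.integer(n_answers), n_answered = as.integer(n_answered))
}

#' Directionality index of a vocal exchange
#'
#' `(n_answers - n_answered) / (n_answers + n_answered)`: 0 when partner
#' and focal answer each other equally often; with the female as focal,
#' positive when the male answers more, negative when the female answers
#' more. Bounded in \code{[-1, 1]}. When both counts are zero the index is
#' undefined and returned as `NA` (with attribute `undefined = TRUE`),
#' never as 0.
#'
#' @param n_answers,n_answered Non-negative counts (see [count_answers()]).
#' @param display Multiply by 100 (the conventional reporting scale)?
#'   Default `FALSE`.
#' @return The index (numeric scalar; `NA` if undefined).
#' @export
#' @examples
#' directionality_index(10, 10)  # 0: symmetric exchange
#' directionality_index(3, 1)    # 0.5
directionality_index <- function(n_answers, n_answered, display = FALSE) {
  check_number(n_answers, "n_answers", lower = 0)
  check_number(n_answered, "n_answered", lower = 0)
  tot <- n_answers + n_answered
  if (tot == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d <- (n_answers - n_answered) / tot
  if (display) d * 100 else d
}

#' Proportion of focal calls that overlap partner calls
#'
#' The fraction of focal calls whose `[onset, onset + duration)` interval
#' intersects at least one partner call interval. Antiphonal exchange is
#' characterised by a low overlap rate.
#'
#' @param focal,partner Tibbles (or data frames) with `onset_s` and
#'   `duration_s` columns.
#' @return Proportion in \code{[0, 1]}; `NaN` when there are no focal
#'   calls.
#' @export
overlap_rate <- function(focal, partner) {
  for (nm in c("onset_s", "duration_s")) {
    if (!nm %in% names(focal) || !nm %in% names(partner)) {
      abort(paste0("`", nm, "` column required on both streams; overlap is ",
                   "undefined for onset-only data (supply durations)."))
    }
  }
  if (any(is.na(focal$duration_s)) || any(is.na(partner$duration_s))) {
    abort("missing durations: overlap is undefined for onset-only data.")
  }
  if (nrow(focal) == 0) return(NaN)
  if (nrow(partner) == 0) return(0)
  ord <- order(partner$onset_s)
  p_on <- partner$onset_s[ord]
  p_off <- p_on + partner$duration_s[ord]
  # focal i overlaps some partner iff any partner with onset < focal end
  # has end > focal onset; use running max of partner ends
  run_max_off <- cummax(p_off)
  f_on <- focal$onset_s
  f_off <- f_on + focal$duration_s
  k <- findInterval(f_off, p_on, left.open = TRUE)  # partners starting before focal end
  hit <- k >= 1L & run_max_off[pmax(k, 1L)] > f_on
  mean(hit)
}
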