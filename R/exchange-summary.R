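#' Summarise the vocal exchange of one pair-recording
#'
#' One-stop summary for a pair of event streams: answer/answered counts,
#' directionality index (raw and x100 display scale), per-bird answer
#' proportions, overlap rate, and the antiphony flag from the correlogram
#' and its Poisson limits. The female is the focal individual by default
#' (lags are measured relative to her calls); `focal = "M"` swaps roles.
#'
#' @param events A `pair_events` tibble (columns `bird`, `onset_s`,
#'   `duration_s`; see [simulate_pair_calling()] or [read_events()]).
#' @param focal `"F"` (default) or `"M"`.
#' @param call_type Optional call type (e.g. `"Stack"`) to condition both
#'   streams on; `NULL` uses all calls.
#' @param window_s Answer window (s).
#' @param alpha Significance level for the Poisson limits.
#' @param dedupe Passed to [count_answers()].
#' @return A one-row tibble: `n_focal`, `n_partner`, `n_answers`,
#'   `n_answered`, `directionality`, `directionality_display`,
#'   `answer_prop_focal`, `answer_prop_partner`, `overlap`,
#'   `is_antiphonal`, `peak_latency_s`, `baseline_lambda`.
#' @export
summarise_exchange <- function(events, focal = c("F", "M"),
                               call_type = NULL, window_s = 0.5,
                               alpha = 0.05, dedupe = TRUE) {
  focal <- match.arg(focal)
  partner <- setdiff(c("F", "M"), focal)
  if (!is.null(call_type)) {
    wanted <- call_type
    events <- filter(events, .data$call_type %in% wanted)
  }
  fe <- filter(events, .data$bird == focal)
  pe <- filter(events, .data$bird == partner)

  ans <- count_answers(fe$onset_s, pe$onset_s, window_s, dedupe = dedupe)
  d <- directionality_index(ans$n_answers, ans$n_answered)
  cg <- cross_correlogram(fe$onset_s, pe$onset_s)
  det <- if (nrow(fe) && nrow(pe)) {
    detect_antiphony(cg, alpha = alpha, answer_window_s = window_s)
  } else list(is_antiphonal = FALSE, peak_latency_s = NA_real_,
              limits = list(lambda = NA_real_))
  ov <- if (nrow(fe) && all(is.finite(fe$duration_s)) &&
            all(is.finite(pe$duration_s))) overlap_rate(fe, pe) else NA_real_

  tibble(
    focal = focal,
    n_focal = nrow(fe), n_partner = nrow(pe),
    n_answers = ans$n_answers, n_answered = ans$n_answered,
    directionality = as.numeric(d),
    directionality_display = as.numeric(d) * 100,
    # answers by the partner / partner's own total; answered = focal answers
    answer_prop_partner = if (nrow(pe)) ans$n_answers / nrow(pe) else NA_real_,
    answer_prop_focal = if (nrow(fe)) ans$n_answered / nrow(fe) else NA_real_,
    overlap = ov,
    is_antiphonal = det$is_antiphonal,
    peak_latency_s = det$peak_latency_s,
    baseline_lambda = det$limits$lambda
  )
}
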