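#' Simulate a behaviour-state interval track
#'
#' Produces an exhaustive, non-overlapping sequence of behaviour-state
#' intervals covering `[0, total_s)`, as produced by video scoring of a pair
#' (relative-position states "Clumping", "Close", "Distance" by default).
#' The track is a semi-Markov alternation: dwell times are exponential with
#' the state's mean, and the next state is chosen uniformly among the other
#' states (a state never follows itself).
#'
#' @param states Character vector of state names (non-empty).
#' @param mean_dwell_s Mean dwell time (s) per state; recycled to
#'   `length(states)`. All must be > 0.
#' @param total_s Total scored time (s).
#' @param seed Integer RNG seed.
#'
#' @return A tibble of class `behavior_track` with columns `state`,
#'   `start_s`, `stop_s` (half-open intervals `[start_s, stop_s)`), and
#'   attribute `scored_total_s`.
#' @export
#' @examples
#' simulate_behavior_track(c("Clumping", "Close", "Distance"),
#'                         mean_dwell_s = c(60, 30, 90),
#'                         total_s = 600, seed = 7)
simulate_behavior_track <- function(states, mean_dwell_s, total_s, seed = 1L) {
  if (length(states) == 0) abort("`states` must be a non-empty vector.")
  mean_dwell_s <- rep_len(mean_dwell_s, length(states))
  if (any(!is.finite(mean_dwell_s)) || any(mean_dwell_s <= 0)) {
    abort("`mean_dwell_s` must be finite and > 0.")
  }
  check_number(total_s, "total_s", lower = 1e-12)
  if (length(states) == 1L) {
    # nothing to alternate with: the whole window is one interval
    track <- tibble(state = states, start_s = 0, stop_s = total_s)
    class(track) <- c("behavior_track", class(track))
    attr(track, "scored_total_s") <- total_s
    return(track)
  }

  withr::with_seed(as.integer(seed), {
    cur <- if (length(states) == 1L) 1L else sample.int(length(states), 1L)
    t0 <- 0
    rows <- list()
    while (t0 < total_s) {
      dwell <- rexp(1L, rate = 1 / mean_dwell_s[cur])
      t1 <- min(t0 + dwell, total_s)
      rows[[length(rows) + 1L]] <- tibble(
        state = states[cur], start_s = t0, stop_s = t1)
      t0 <- t1
      if (length(states) > 1L) {
        others <- setdiff(seq_along(states), cur)
        cur <- others[sample.int(length(others), 1L)]
      }
    }
    track <- bind_rows(rows)
    class(track) <- c("behavior_track", class(track))
    attr(track, "scored_total_s") <- total_s
    track
  })
}
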