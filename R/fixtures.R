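#' Generate a synthetic study cohort
#'
#' Builds an on-disk-ready synthetic dataset emulating a pair-bonding
#' study: 8 newly introduced and 4 established pairs, each recorded on
#' days 1, 3, 5 and 7. Three presets encode the qualitative scenarios:
#'
#' * `"new_pair_convergence"` — new pairs start with a strongly
#'   asymmetric exchange (one bird answers far more, alternating direction
#'   across pairs) and converge towards symmetry by day 7; established
#'   pairs answer symmetrically throughout. New pairs barely clump at
#'   first; established pairs clump from day 1.
#' * `"established_pair"` — every pair answers symmetrically on every
#'   day.
#' * `"uncoupled_null"` — no coupling at all (answer probabilities 0):
#'   both birds call independently at baseline.
#'
#' @param preset One of the three preset names.
#' @param seed Integer master seed (one sub-seed per pair-day stream).
#' @param n_new,n_established Number of new / established pairs.
#' @param days Recording days.
#' @param duration_s Length of each simulated recording (s).
#' @param base_rate Baseline calling rate per bird (calls/s).
#' @return A list of class `exchange_fixture`: `events` (all calls, with
#'   `pair_id`, `experience`, `day` columns), `behavior` (state intervals
#'   per pair-day), `preset`, `seed`.
#' @export
make_fixture <- function(preset = c("new_pair_convergence",
                                    "established_pair",
                                    "uncoupled_null"),
                         seed = 1L,
                         n_new = 8, n_established = 4,
                         days = c(1, 3, 5, 7),
                         duration_s = 600,
                         base_rate = 0.17) {
  preset <- match.arg(preset)
  pairs <- tibble(
    pair_id = sprintf("P%02d", seq_len(n_new + n_established)),
    experience = rep(c("new", "established"), c(n_new, n_established))
  )
  grid <- tidyr::expand_grid(pairs, day = days)
  seeds <- split_seed(seed, 2L * nrow(grid))

  # answer probabilities per scenario; asymmetry direction alternates by pair
  p_answers <- function(experience, day, pair_index) {
    if (preset == "uncoupled_null") return(c(0, 0))
    if (preset == "established_pair" || experience == "established") {
      return(c(0.3, 0.3))
    }
    # new pairs converging: asymmetry 1 -> 0.1 across the week
    a <- 1 - 0.9 * (day - min(days)) / max(max(days) - min(days), 1)
    hi <- 0.3 + 0.2 * a
    lo <- 0.3 - 0.2 * a
    if (pair_index %% 2 == 0) c(hi, lo) else c(lo, hi)
  }
  dwell_clump <- function(experience, day) {
    if (experience == "established") return(120)
    5 + 115 * (day - min(days)) / max(max(days) - min(days), 1)
  }

  ev <- purrr::pmap(
    list(grid$pair_id, grid$experience, grid$day, seq_len(nrow(grid))),
    function(pid, exp_, day, i) {
      p <- p_answers(exp_, day, match(pid, pairs$pair_id))
      cfg <- sim_config(duration_s = duration_s,
                        base_rate_f = base_rate, base_rate_m = base_rate,
                        p_answer_f = p[1], p_answer_m = p[2],
                        seed = seeds[2 * i - 1])
      mutate(simulate_pair_calling(cfg),
             pair_id = pid, experience = exp_, day = day)
    }) |> bind_rows()

  beh <- purrr::pmap(
    list(grid$pair_id, grid$experience, grid$day, seq_len(nrow(grid))),
    function(pid, exp_, day, i) {
      trk <- simulate_behavior_track(
        c("Clumping", "Close", "Distance"),
        mean_dwell_s = c(dwell_clump(exp_, day), 40, 80),
        total_s = duration_s, seed = seeds[2 * i])
      mutate(trk, pair_id = pid, experience = exp_, day = day)
    }) |> bind_rows()

  structure(list(events = ev, behavior = beh, preset = preset,
                 seed = as.integer(seed), duration_s = duration_s,
                 days = days),
            class = "exchange_fixture")
}

#' Pair-day summary table of a fixture (or any cohort event table)
#'
#' Computes, per pair-day, the exchange summary conditioned on the stack
#' call (the headline call type of antiphonal exchange) and the clumping
#' time budget — the input expected by [run_exchange_models()].
#'
#' @param fixture An `exchange_fixture`, or a list with `events` and
#'   `behavior` tibbles carrying `pair_id`, `experience`, `day` columns.
#' @param call_type Call type conditioning the exchange (default
#'   `"Stack"`; `NULL` for all calls).
#' @param alpha Significance level for the antiphony detection (passed to
#'   [summarise_exchange()]).
#' @return A tibble with one row per pair-day: exchange summary columns
#'   plus `clumping_s`, `scored_s`, `male_stacks`, `female_stacks`,
#'   `male_answers`, `female_answers`, `male_answer_prop`,
#'   `female_answer_prop`.
#' @export
summarise_pair_days <- function(fixture, call_type = "Stack",
                                alpha = 0.05) {
  ev <- fixture$events
  beh <- fixture$behavior
  if (!"pair_id" %in% names(ev)) ev$pair_id <- "P01"
  if (!"experience" %in% names(ev)) ev$experience <- "unknown"
  if (!"day" %in% names(ev)) ev$day <- 1L
  keys <- dplyr::distinct(ev, .data$pair_id, .data$experience, .data$day)
  purrr::pmap(keys, function(pair_id, experience, day) {
    e <- ev[ev$pair_id == pair_id & ev$day == day, ]
    b <- if (!is.null(beh)) {
      if ("pair_id" %in% names(beh)) {
        beh[beh$pair_id == pair_id & beh$day == day, ]
      } else beh
    }
    if (!is.null(b) && nrow(b)) {
      scored_s <- max(b$stop_s)
      cl <- clumping_proportion(b, scored_total_s = scored_s)
    } else {
      scored_s <- NA_real_
      cl <- list(seconds = NA_real_, percent = NA_real_)
    }
    s <- summarise_exchange(e, call_type = call_type, alpha = alpha)
    stacks <- if (is.null(call_type)) e else
      e[e$call_type %in% call_type, ]
    tibble(
      pair_id = pair_id, experience = experience, day = day,
      clumping_s = cl$seconds, clumping_pct = cl$percent,
      scored_s = scored_s,
      female_stacks = sum(stacks$bird == "F"),
      male_stacks = sum(stacks$bird == "M"),
      male_answers = s$n_answers, female_answers = s$n_answered,
      male_answer_prop = s$answer_prop_partner,
      female_answer_prop = s$answer_prop_focal,
      directionality = s$directionality_display,
      is_antiphonal = s$is_antiphonal,
      overlap = s$overlap
    )
  }) |> bind_rows()
}
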