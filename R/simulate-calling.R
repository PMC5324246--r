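#' Simulate a coupled pair of calling point processes
#'
#' Generates one pair-recording of antiphonal calling with known ground
#' truth. Each bird calls at baseline as a homogeneous Poisson process of
#' its configured rate; every call of one bird is independently answered by
#' the partner with probability `p_answer_<partner>` at a latency drawn from
#' a Gamma distribution truncated to the answer window (0, 0.5] s. Answer
#' calls do not themselves trigger answers unless `chain_answers = TRUE`.
#' Call onsets closer than `refractory_s` to the same bird's previous kept
#' onset are dropped (earliest onset wins); answers whose triggering call was
#' dropped are removed as well, so the truth columns stay consistent.
#'
#' @param config A [sim_config()] object.
#'
#' @return A tibble of class `pair_events`, one row per call, time-sorted,
#'   with columns:
#'   \describe{
#'     \item{bird}{`"F"` or `"M"`.}
#'     \item{event_id}{Unique event identifier.}
#'     \item{onset_s, duration_s}{Call onset and duration in seconds.}
#'     \item{call_type}{Label drawn from the configured repertoire.}
#'     \item{is_answer}{Ground truth: `TRUE` for calls generated as answers.}
#'     \item{trigger_id}{For answers, the `event_id` of the partner call
#'       that triggered them; `NA` for baseline calls.}
#'   }
#'   The generating `sim_config` is attached as attribute `"config"`.
#' @export
#' @examples
#' ev <- simulate_pair_calling(sim_config(duration_s = 120, seed = 42))
#' dplyr::count(ev, bird, is_answer)
simulate_pair_calling <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a `sim_config` object; see `sim_config()`.")
  }
  seeds <- split_seed(config$seed, 6L)
  base_f <- poisson_onsets(config$base_rate_f, config$duration_s, seeds[1])
  base_m <- poisson_onsets(config$base_rate_m, config$duration_s, seeds[2])

  events <- tibble(
    bird = rep(c("F", "M"), c(length(base_f), length(base_m))),
    onset_s = c(base_f, base_m),
    is_answer = FALSE,
    trigger_id = NA_character_
  )
  events$event_id <- sprintf("%s%06d", events$bird, seq_len(nrow(events)))

  # answers, generation by generation (one generation unless chaining)
  new_gen <- events
  gen_seed <- seeds[3]
  repeat {
    ans <- draw_answers(new_gen, config, gen_seed)
    gen_seed <- as.integer((as.numeric(gen_seed) + 1) %% 2147483646)
    if (nrow(ans) == 0) break
    ans$event_id <- sprintf("%s%06d", ans$bird,
                            nrow(events) + seq_len(nrow(ans)))
    events <- bind_rows(events, ans)
    if (!config$chain_answers) break
    new_gen <- ans
  }

  events <- enforce_refractory(events, config$refractory_s)
  events <- label_calls(events, config, seeds[4])
  events <- events |>
    arrange(.data$onset_s, .data$bird) |>
    select("bird", "event_id", "onset_s", "duration_s", "call_type",
           "is_answer", "trigger_id")
  class(events) <- c("pair_events", class(events))
  attr(events, "config") <- config
  events
}

# homogeneous Poisson onsets on [0, duration]
poisson_onsets <- function(rate, duration, seed) {
  withr::with_seed(seed, {
    n <- rpois(1L, rate * duration)
    sort(runif(n, 0, duration))
  })
}

# one generation of answers to `triggers`
draw_answers <- function(triggers, config, seed) {
  withr::with_seed(seed, {
    out <- lapply(c(F_ans = "F", M_ans = "M"), function(answerer) {
      trig <- triggers[triggers$bird != answerer, ]
      p <- if (answerer == "F") config$p_answer_f else config$p_answer_m
      hit <- runif(nrow(trig)) < p
      trig <- trig[hit, ]
      lat <- rtrunc_gamma(nrow(trig), config$latency_shape,
                          config$latency_scale, config$latency_max_s)
      tibble(
        bird = rep(answerer, nrow(trig)),
        onset_s = trig$onset_s + lat,
        is_answer = TRUE,
        trigger_id = trig$event_id
      )
    })
    ans <- bind_rows(out)
    ans[ans$onset_s <= config$duration_s, ]
  })
}

# Gamma truncated to (0, upper] by inverse-CDF; strictly positive support
rtrunc_gamma <- function(n, shape, scale, upper) {
  if (n == 0) return(numeric(0))
  cap <- stats::pgamma(upper, shape = shape, scale = scale)
  u <- runif(n, min = .Machine$double.eps, max = cap)
  stats::qgamma(u, shape = shape, scale = scale)
}

# Drop events within refractory_s of the same bird's previous kept onset
# (earliest kept), then cascade-drop answers whose trigger disappeared.
enforce_refractory <- function(events, refractory_s) {
  keep_bird <- function(df) {
    df <- df[order(df$onset_s), ]
    keep <- rep(TRUE, nrow(df))
    last <- -Inf
    for (i in seq_len(nrow(df))) {
      if (df$onset_s[i] - last < refractory_s) keep[i] <- FALSE
      else last <- df$onset_s[i]
    }
    df[keep, ]
  }
  if (refractory_s > 0 && nrow(events) > 0) {
    events <- bind_rows(lapply(split(events, events$bird), keep_bird))
  }
  repeat {
    dangling <- !is.na(events$trigger_id) &
      !(events$trigger_id %in% events$event_id)
    if (!any(dangling)) break
    events <- events[!dangling, ]
  }
  events
}

label_calls <- function(events, config, seed) {
  withr::with_seed(seed, {
    types <- names(config$repertoire)
    events$call_type <- if (nrow(events) == 0) character(0) else
      sample(types, nrow(events), replace = TRUE, prob = config$repertoire)
    events$duration_s <- unname(config$call_duration_s[events$call_type])
    events
  })
}

#' @export
print.pair_events <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<pair_events> %d calls (%d F, %d M) over %g s\n",
              nrow(x), sum(x$bird == "F"), sum(x$bird == "M"),
              if (is.null(cfg)) NA_real_ else cfg$duration_s))
  NextMethod()
}
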