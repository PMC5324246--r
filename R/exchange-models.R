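#' Run the standard antiphony model battery
#'
#' Fits the package's canonical set of ML linear mixed models on a
#' pair-day summary table and summarises each by flat-prior posterior
#' simulation:
#'
#' 1. `clumping_s ~ experience * day + (1 | pair_id)` — time in physical
#'    contact by pair experience and day;
#' 2. `abs(directionality) ~ experience * day + (1 | pair_id)` — the
#'    absolute directionality index (distance from symmetry, direction
#'    ignored), with derived p's for the day-1 vs day-7 change within each
#'    experience group and the new vs established contrast per day;
#' 3. `sqrt(calling rate) ~ relative position + (1 | day) + (1 | pair_id)`
#'    — where birds call most, fitted when `rates_by_state` is supplied;
#' 4. `male_stacks ~ female_stacks` and `male_answers ~ female_answers`,
#'    each with `(1 | day) + (1 | experience / pair_id)` — do partners
#'    match total calling, or matching of answers only;
#' 5. `z(answer proportion) ~ z(clumping_s)` with the same random
#'    structure, per sex, plus a rerun excluding zero-clumping days.
#'
#' Models whose replication is insufficient (fewer than 2 pairs or 2 days,
#' or a constant response) are refused explicitly and listed in
#' `$skipped`, not silently dropped.
#'
#' @param pair_days One row per pair-day with columns `pair_id`,
#'   `experience` (`"new"` / `"established"`), `day`, `clumping_s`,
#'   `directionality` (display scale or raw — only its absolute value and
#'   z-scores are used), `male_stacks`, `female_stacks`, `male_answers`,
#'   `female_answers`, `male_answer_prop`, `female_answer_prop`. Missing
#'   columns skip the dependent models.
#' @param rates_by_state Optional long tibble `pair_id`, `day`, `state`,
#'   `rate_per_s` for model 3.
#' @param n_draws Posterior draws per model (default 10000).
#' @param seed Integer seed; one sub-seed per model.
#' @return A list of class `exchange_models`: `models` (named `ap_lmm`
#'   list), `coefficients` (tidy table with credible intervals),
#'   `contrasts` (derived p's for the directionality model), `skipped`.
#' @export
run_exchange_models <- function(pair_days, rates_by_state = NULL,
                                n_draws = 10000, seed = 1L) {
  pd <- as_tibble(pair_days)
  need <- c("pair_id", "day")
  if (!all(need %in% names(pd))) {
    abort("`pair_days` needs at least `pair_id` and `day` columns.")
  }
  pd$pair_id <- factor(pd$pair_id)
  pd$day <- factor(pd$day)
  if ("experience" %in% names(pd)) pd$experience <- factor(pd$experience)

  models <- list()
  skipped <- character()
  refuse <- function(name, why) {
    skipped[[length(skipped) + 1L]] <<- sprintf("%s: %s", name, why)
  }
  replicated <- nlevels(pd$pair_id) >= 2 && nlevels(pd$day) >= 2

  try_fit <- function(name, formula, data, transform = "identity") {
    resp <- all.vars(formula)[1]
    if (!all(all.vars(formula) %in% names(data))) {
      refuse(name, "required columns missing"); return(invisible(NULL))
    }
    # pair-days where the quantity is undefined (e.g. no exchange at all)
    # are excluded from that model
    data <- data[complete.cases(data[all.vars(formula)]), ]
    if (!replicated || nrow(data) < 4) {
      refuse(name, "needs >= 2 pairs and >= 2 days"); return(invisible(NULL))
    }
    if (sd(data[[resp]], na.rm = TRUE) %in% c(0, NA)) {
      refuse(name, "constant response"); return(invisible(NULL))
    }
    models[[name]] <<- fit_lmm(formula, data, transform = transform)
  }

  pd$abs_directionality <- if ("directionality" %in% names(pd)) {
    abs(pd$directionality)
  } else NULL

  try_fit("clumping",
          clumping_s ~ experience * day + (1 | pair_id), pd)
  try_fit("directionality",
          abs_directionality ~ experience * day + (1 | pair_id), pd)
  if (!is.null(rates_by_state)) {
    rs <- as_tibble(rates_by_state)
    rs$pair_id <- factor(rs$pair_id)
    rs$day <- factor(rs$day)
    rs <- filter(rs, is.finite(.data$rate_per_s))
    try_fit("calling_rate",
            rate_per_s ~ state + (1 | day) + (1 | pair_id), rs,
            transform = "sqrt")
  }
  try_fit("total_calls",
          male_stacks ~ female_stacks + (1 | day) + (1 | experience / pair_id),
          pd)
  try_fit("answer_calls",
          male_answers ~ female_answers +
            (1 | day) + (1 | experience / pair_id), pd)

  z_model <- function(name, resp_col, data) {
    if (!all(c(resp_col, "clumping_s") %in% names(data)) ||
        nrow(data) < 4) {
      refuse(name, "required columns missing or too few rows")
      return(invisible(NULL))
    }
    if (sd(data[[resp_col]]) == 0 || sd(data$clumping_s) == 0) {
      refuse(name, "constant variable; z-score undefined")
      return(invisible(NULL))
    }
    data$z_answer <- as.numeric(zscore(data[[resp_col]]))
    data$z_clump <- as.numeric(zscore(data$clumping_s))
    try_fit(name,
            z_answer ~ z_clump + (1 | day) + (1 | experience / pair_id),
            data)
  }
  z_model("male_answers_clumping", "male_answer_prop", pd)
  z_model("female_answers_clumping", "female_answer_prop", pd)
  if ("clumping_s" %in% names(pd)) {
    z_model("male_answers_clumping_nonzero", "male_answer_prop",
            filter(pd, .data$clumping_s > 0))
  }

  seeds <- split_seed(seed, max(1L, length(models)))
  draws <- purrr::imap(models, function(m, nm) {
    posterior_sim(m, n_draws = n_draws,
                  seed = seeds[match(nm, names(models))])
  })
  coefs <- purrr::imap(models, function(m, nm) {
    mutate(tidy(m, draws = draws[[nm]]), model = nm, .before = 1)
  }) |> bind_rows()

  contrasts <- if ("directionality" %in% names(models)) {
    directionality_contrasts(models$directionality, draws$directionality, pd)
  } else tibble()

  structure(list(models = models, draws = draws, coefficients = coefs,
                 contrasts = contrasts, skipped = unlist(skipped)),
            class = "exchange_models")
}

# Derived p's for the |directionality| model: day-1 vs day-7 within each
# experience group, and new vs established on the first and last day.
directionality_contrasts <- function(model, draws, pd) {
  days <- levels(pd$day)
  exps <- levels(pd$experience)
  first_day <- days[1]; last_day <- days[length(days)]
  cell <- function(experience, day) {
    nd <- data.frame(experience = factor(experience, levels = exps),
                     day = factor(day, levels = days),
                     abs_directionality = 0)
    tt <- stats::delete.response(stats::terms(model$fit, fixed.only = TRUE))
    as.numeric(draws %*% t(model.matrix(tt, nd)))
  }
  rows <- list()
  for (e in exps) {
    # fraction of draws in which the last day's |index| exceeds the first
    # day's: small when the exchange has become more symmetrical
    dp <- derived_p(cell(e, last_day), cell(e, first_day))
    rows[[length(rows) + 1L]] <- tibble(
      contrast = sprintf("day%s_vs_day%s", last_day, first_day),
      group = e, p = dp$p, p_two_sided = dp$p_two_sided)
  }
  if (length(exps) == 2) {
    for (d in c(first_day, last_day)) {
      dp <- derived_p(cell(exps[1], d), cell(exps[2], d))
      rows[[length(rows) + 1L]] <- tibble(
        contrast = sprintf("%s_vs_%s", exps[1], exps[2]),
        group = paste0("day", d), p = dp$p, p_two_sided = dp$p_two_sided)
    }
  }
  bind_rows(rows)
}

#' @export
print.exchange_models <- function(x, ...) {
  cat(sprintf("<exchange_models> %d model(s) fitted", length(x$models)))
  if (length(x$skipped)) {
    cat(sprintf(", %d refused:\n  %s", length(x$skipped),
                paste(x$skipped, collapse = "\n  ")))
  }
  cat("\n")
  print(x$coefficients, n = Inf)
  if (nrow(x$contrasts)) {
    cat("derived p (directionality contrasts):\n")
    print(x$contrasts)
  }
  invisible(x)
}
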