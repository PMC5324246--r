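#' Tidy an ML mixed-model fit
#'
#' Broom-style one-row-per-term summary of the fixed effects. When
#' `draws` is supplied (or `n_draws > 0`), estimates are posterior means
#' with 95% credible intervals from flat-prior posterior simulation;
#' otherwise ML estimates with Wald standard errors.
#'
#' @param x An `ap_lmm`.
#' @param draws Optional `posterior_draws` for `x`.
#' @param n_draws If `draws` is missing and `n_draws > 0`, simulate this
#'   many draws (seeded by `seed`).
#' @param seed Seed for the on-the-fly simulation.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, and (with draws)
#'   `conf.low`, `conf.high`.
#' @export
tidy.ap_lmm <- function(x, draws = NULL, n_draws = 0, seed = 1L, ...) {
  base <- tibble(term = names(x$beta),
                 estimate = unname(x$beta),
                 std.error = sqrt(diag(x$vcov_beta)))
  if (is.null(draws) && n_draws > 0) {
    draws <- posterior_sim(x, n_draws = n_draws, seed = seed)
  }
  if (!is.null(draws)) {
    ci <- credible_intervals(draws)
    base <- base |>
      select(-"estimate") |>
      left_join(ci, by = "term") |>
      select("term", "estimate", "std.error", "conf.low", "conf.high")
  }
  base
}

#' Glance at an ML mixed-model fit
#'
#' @param x An `ap_lmm`.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `sigma`, `logLik`, `AIC`, `r2_marginal`,
#'   `r2_conditional`, `singular`.
#' @export
glance.ap_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble(
    nobs = nobs(x$fit),
    sigma = sigma(x$fit),
    logLik = as.numeric(logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    singular = x$singular
  )
}
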