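#' Fit a linear mixed model by maximum likelihood
#'
#' Thin wrapper around [lme4::lmer()] that fixes the estimation choices
#' used throughout this package: maximum likelihood (not REML, for better
#' fixed-effect estimation and comparability), an optional response
#' transform (`"identity"` or `"sqrt"`), and singular-fit flagging rather
#' than silent acceptance. Models without random terms fall back to
#' [stats::lm()].
#'
#' @param formula Model formula in lme4 syntax, e.g.
#'   `clumping_s ~ experience * day + (1 | pair_id)`.
#' @param data A data frame / tibble.
#' @param transform `"identity"` (default) or `"sqrt"`, applied to the
#'   response before fitting.
#' @return An object of class `ap_lmm`: a list with the underlying `fit`,
#'   `formula`, `transform`, `beta` (fixed effects), `vcov_beta`,
#'   `varcomp` (named random-effect + residual variances), `singular`,
#'   and `data`.
#' @seealso [posterior_sim()], [tidy.ap_lmm()], [r2_nakagawa()]
#' @export
fit_lmm <- function(formula, data, transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  data <- as.data.frame(data)
  resp <- all.vars(formula)[1]
  if (!resp %in% names(data)) abort(sprintf("response `%s` not in data.", resp))
  if (any(!is.finite(data[[resp]]))) abort("response must be finite.")
  if (transform == "sqrt") {
    if (any(data[[resp]] < 0)) abort("sqrt transform needs response >= 0.")
    data[[resp]] <- sqrt(data[[resp]])
  }

  has_bars <- length(lme4::findbars(formula)) > 0
  if (has_bars) {
    check_grouping(formula, data)
    fit <- lme4::lmer(formula, data = data, REML = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "Residual",
                                        vc$grp))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    vb <- as.matrix(vcov(fit))
  } else {
    fit <- stats::lm(formula, data = data)
    varcomp <- c(Residual = summary(fit)$sigma^2)
    singular <- FALSE
    beta <- stats::coef(fit)
    vb <- as.matrix(vcov(fit))
  }
  if (singular) {
    warn("singular fit: one or more variance components are estimated at 0.")
  }
  structure(list(fit = fit, formula = formula, transform = transform,
                 beta = beta, vcov_beta = vb, varcomp = varcomp,
                 singular = singular, data = data),
            class = "ap_lmm")
}

check_grouping <- function(formula, data) {
  groups <- unique(unlist(lapply(lme4::findbars(formula),
                                 function(b) all.vars(b[[3]]))))
  for (g in groups) {
    if (!g %in% names(data)) abort(sprintf("grouping factor `%s` missing.", g))
    if (length(unique(data[[g]])) < 2) {
      abort(sprintf("grouping factor `%s` needs >= 2 levels.", g))
    }
  }
}

#' @export
print.ap_lmm <- function(x, ...) {
  cat("<ap_lmm> ML linear mixed model\n")
  print(x$formula)
  if (x$transform != "identity") cat("response transform:", x$transform, "\n")
  cat("fixed effects:\n")
  print(round(x$beta, 4))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  if (x$singular) cat("NOTE: singular fit\n")
  invisible(x)
}

#' Residual and random-effect diagnostics
#'
#' The standard visual checks for an `ap_lmm`: residuals vs fitted,
#' residual distribution, and normal Q-Q of the random-effect modes.
#'
#' @param x An `ap_lmm` object.
#' @return A tibble with `fitted`, `residual`; attribute `ranef_modes`
#'   holds the random-effect modes per grouping factor. Use
#'   [plot_diagnostics()] to draw them.
#' @export
lmm_diagnostics <- function(x) {
  stopifnot(inherits(x, "ap_lmm"))
  out <- tibble(fitted = stats::fitted(x$fit),
                residual = stats::residuals(x$fit))
  attr(out, "ranef_modes") <- if (inherits(x$fit, "merMod")) {
    lapply(lme4::ranef(x$fit), function(r) r[[1]])
  } else list()
  out
}

#' Posterior simulation of the fixed effects under flat priors
#'
#' Draws `n_draws` simulated fixed-effect vectors from the multivariate
#' normal distribution centred at the ML estimates with their estimated
#' covariance — the approximate posterior under flat priors, with variance
#' components held at their ML estimates. Posterior means and 95% credible
#' intervals summarise the draws.
#'
#' @param fitted An `ap_lmm` from [fit_lmm()].
#' @param n_draws Number of draws (default 10000).
#' @param seed Integer RNG seed.
#' @return An object of class `posterior_draws`: matrix of draws
#'   (`n_draws` x n coefficients, columns in design-matrix order) with
#'   attributes `seed` and `beta_hat`.
#' @export
posterior_sim <- function(fitted, n_draws = 10000, seed = 1L) {
  stopifnot(inherits(fitted, "ap_lmm"))
  check_number(n_draws, "n_draws", lower = 1)
  V <- (fitted$vcov_beta + t(fitted$vcov_beta)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    warn("non-positive-semidefinite covariance repaired by eigenvalue clipping.")
  }
  vals <- pmax(ev$values, 0)
  V <- ev$vectors %*% diag(vals, nrow = length(vals)) %*% t(ev$vectors)
  draws <- withr::with_seed(as.integer(seed),
    MASS::mvrnorm(n_draws, mu = fitted$beta, Sigma = V))
  if (n_draws == 1) draws <- matrix(draws, nrow = 1,
                                    dimnames = list(NULL, names(fitted$beta)))
  structure(draws, class = c("posterior_draws", "matrix", "array"),
            seed = as.integer(seed), beta_hat = fitted$beta)
}

#' Credible intervals from posterior draws
#'
#' @param draws A `posterior_draws` matrix.
#' @param level Credible level (default 0.95).
#' @return A tibble `term`, `estimate` (posterior mean), `conf.low`,
#'   `conf.high`.
#' @export
credible_intervals <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    conf.low = unname(apply(draws, 2, quantile, probs = a, names = FALSE)),
    conf.high = unname(apply(draws, 2, quantile, probs = 1 - a,
                             names = FALSE))
  )
}

#' Derived posterior p-value for a group comparison
#'
#' The proportion of paired posterior draws in which the first group's
#' estimated value exceeds the second's. Values near 0 or 1 indicate a
#' clear difference; by convention a threshold of 5% plays the role of a
#' frequentist significance level. The symmetric two-sided version
#' `min(p, 1 - p) * 2` is returned alongside as an extension.
#'
#' @param draws_a,draws_b Equal-length numeric vectors of paired draws
#'   (e.g. per-draw estimated group means).
#' @return A list with `p` (fraction with a > b) and `p_two_sided`.
#' @export
derived_p <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b)) {
    abort("`draws_a` and `draws_b` must be paired (equal length).")
  }
  p <- mean(draws_a > draws_b)
  list(p = p, p_two_sided = min(p, 1 - p) * 2)
}

#' z-score standardization
#'
#' Centre to mean 0 and scale to sample SD 1 (n - 1 denominator).
#'
#' @param values Numeric vector with SD > 0.
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
#' @examples
#' zscore(c(1, 2, 3))
zscore <- function(values) {
  if (any(!is.finite(values))) abort("`values` must be finite.")
  s <- sd(values)
  if (!is.finite(s) || s == 0) abort("`values` are constant; z-score undefined.")
  structure((values - mean(values)) / s, center = mean(values), scale = s)
}

#' Back-transform a standardized slope to natural units
#'
#' A slope estimated between z-scored variables states the change in SD
#' units of the response per SD of the predictor. Multiplying by the
#' response SD (and reading the predictor SD as the step size) recovers
#' the effect in natural units: e.g. a standardized slope of 0.300 with a
#' response SD of 10.1 percentage points means one predictor-SD increase
#' (627 s of clumping) raises the response by about 3 percentage points.
#'
#' @param slope_std Standardized (z-z) slope.
#' @param sd_y SD of the response in natural units.
#' @return Change in the response, natural units, per 1 SD of the
#'   predictor.
#' @export
#' @examples
#' unstandardize_slope(0.300, sd_y = 10.1)  # ~3 percentage points
unstandardize_slope <- function(slope_std, sd_y) {
  check_number(slope_std, "slope_std")
  check_number(sd_y, "sd_y", lower = 0)
  slope_std * sd_y
}
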