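#' Repeatability (intraclass correlation) from one-way ANOVA
#'
#' Repeatability sensu Lessells & Boag (1987): the among-group variance
#' component divided by the total. From a one-way ANOVA with `a` groups of
#' sizes `n_i` (N observations in total),
#' \deqn{s^2_A = (MS_A - MS_W) / n_0, \quad
#'       n_0 = (N - \sum n_i^2 / N) / (a - 1),}
#' \deqn{r = s^2_A / (s^2_A + MS_W).}
#' `n_0` is the group-size coefficient correcting for unequal group sizes
#' (equal to the common size when groups are balanced). A negative
#' among-group component is truncated to 0 and flagged. The standard error
#' is the standard large-sample approximation for the intraclass
#' correlation (Becker 1984, as used with ANOVA-based repeatability):
#' \deqn{SE(r) = \sqrt{\frac{2 (1-r)^2 (1 + (n_0 - 1) r)^2}
#'                          {n_0 (n_0 - 1) (a - 1)}}.}
#'
#' @param values Numeric measurements.
#' @param groups Group labels (factor-coercible), e.g. pair identity; the
#'   repeatability then quantifies pair-level consistency of the measure
#'   across days.
#' @return A list of class `repeatability`: `r`, `se`, `s2_among`,
#'   `s2_within`, `n0`, `n_groups`, `ms_among`, `ms_within`, `truncated`.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(1:6, each = 4)
#' y <- rnorm(6)[g] * 2 + rnorm(24, sd = 0.5)
#' repeatability(y, g)$r
repeatability <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.")
  }
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need >= 2 groups.")
  sizes <- as.numeric(table(g))
  if (!any(sizes >= 2)) abort("need >= 2 observations in at least one group.")
  a <- nlevels(g)
  N <- length(values)

  tab <- anova(aov(values ~ g))
  ms_a <- tab["g", "Mean Sq"]
  ms_w <- tab["Residuals", "Mean Sq"]
  n0 <- (N - sum(sizes^2) / N) / (a - 1)

  s2_a <- (ms_a - ms_w) / n0
  truncated <- s2_a < 0
  if (truncated) {
    warn("negative among-group variance component truncated to 0.")
    s2_a <- 0
  }
  r <- s2_a / (s2_a + ms_w)
  se <- sqrt(2 * (1 - r)^2 * (1 + (n0 - 1) * r)^2 /
               (n0 * (n0 - 1) * (a - 1)))
  structure(list(r = r, se = se, s2_among = s2_a, s2_within = ms_w,
                 n0 = n0, n_groups = a, ms_among = ms_a, ms_within = ms_w,
                 truncated = truncated),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability r = %.3f +/- %.3f (SE), %d groups, n0 = %.2f\n",
              x$r, x$se, x$n_groups, x$n0))
  if (x$truncated) cat("NOTE: among-group component truncated at 0\n")
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained summaries for an `ap_lmm` (Nakagawa & Schielzeth
#' decomposition): marginal R2 is the variance of the fixed-effect
#' predictor over the total (fixed + summed random-intercept + residual)
#' variance; conditional R2 adds the random components to the numerator.
#' By construction both lie in \code{[0, 1]} and conditional >= marginal.
#'
#' @param fitted An `ap_lmm` from [fit_lmm()].
#' @return A list with `r2_marginal` and `r2_conditional`.
#' @export
r2_nakagawa <- function(fitted) {
  stopifnot(inherits(fitted, "ap_lmm"))
  X <- model.matrix(fitted$fit)
  var_fixed <- var(as.numeric(X %*% fitted$beta))
  var_rand <- sum(fitted$varcomp[names(fitted$varcomp) != "Residual"])
  var_res <- unname(fitted$varcomp["Residual"])
  tot <- var_fixed + var_rand + var_res
  list(r2_marginal = var_fixed / tot,
       r2_conditional = (var_fixed + var_rand) / tot)
}
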