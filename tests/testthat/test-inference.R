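sim_lmm_data <- function(n_groups = 20, per_group = 10, beta = c(1, 2),
                         sd_group = 1, sd_e = 1, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(seq_len(n_groups), each = per_group)
    x <- rnorm(n_groups * per_group)
    u <- rnorm(n_groups, sd = sd_group)
    tibble::tibble(y = beta[1] + beta[2] * x + u[g] + rnorm(length(g), sd = sd_e),
                   x = x, g = factor(g))
  })
}

test_that("ML mixed-model fits recover known fixed effects", {
  hits <- vapply(1:30, function(s) {
    d <- sim_lmm_data(seed = s)
    fit <- fit_lmm(y ~ x + (1 | g), d)
    se <- sqrt(diag(fit$vcov_beta))
    all(abs(fit$beta - c(1, 2)) < 1.96 * se * 1.3)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate random structure is flagged, intercept-only recovers the mean", {
  d <- sim_lmm_data(seed = 1, sd_group = 0)
  expect_warning(fit <- fit_lmm(y ~ x + (1 | g), d), "singular")
  expect_lt(fit$varcomp[["g"]], 0.05)

  d2 <- sim_lmm_data(seed = 4)
  fit2 <- fit_lmm(y ~ 1, d2)
  expect_equal(unname(fit2$beta), mean(d2$y))

  expect_error(fit_lmm(y ~ x + (1 | g), d[d$g == "1", ]), "levels")
  bad <- d; bad$y[1] <- NA
  expect_error(fit_lmm(y ~ x + (1 | g), bad), "finite")
})

test_that("the sqrt response transform is applied before fitting", {
  d <- tibble::tibble(y = c(1, 4, 9, 16, 25, 36), x = 1:6)
  fit <- fit_lmm(y ~ x, d, transform = "sqrt")
  expect_equal(unname(fit$beta), c(0, 1), tolerance = 1e-8)
})

test_that("posterior simulation is centred on the ML estimates and reproducible", {
  d <- sim_lmm_data(seed = 5)
  fit <- fit_lmm(y ~ x + (1 | g), d)
  dr <- posterior_sim(fit, n_draws = 10000, seed = 2)
  se <- sqrt(diag(fit$vcov_beta))
  expect_true(all(abs(colMeans(dr) - fit$beta) < 3 * se / sqrt(10000) * 3))
  expect_identical(unclass(posterior_sim(fit, 10000, seed = 2))[1:10],
                   unclass(dr)[1:10])

  # credible intervals from draws of a known normal match analytic quantiles
  toy <- structure(matrix(withr::with_seed(9, rnorm(2e5)), ncol = 1,
                          dimnames = list(NULL, "z")),
                   class = c("posterior_draws", "matrix", "array"))
  ci <- credible_intervals(toy)
  expect_equal(ci$conf.low, -1.96, tolerance = 0.02)
  expect_equal(ci$conf.high, 1.96, tolerance = 0.02)
})

test_that("derived p behaves as a paired posterior comparison", {
  z <- withr::with_seed(10, rnorm(10000))
  expect_equal(derived_p(z + 1, z)$p, 1)
  expect_equal(derived_p(z - 1, z)$p, 0)
  a <- withr::with_seed(11, rnorm(10000))
  b <- withr::with_seed(12, rnorm(10000))
  expect_lt(abs(derived_p(a, b)$p - 0.5), 0.015)
  # complementarity without ties
  expect_equal(derived_p(a, b)$p + derived_p(b, a)$p, 1)
  expect_error(derived_p(1:3, 1:4), "paired")
})

test_that("z-scores standardize exactly and refuse constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  y <- withr::with_seed(13, rnorm(50, 7, 3))
  zy <- zscore(y)
  expect_lt(abs(mean(zy)), 1e-12)
  expect_equal(sd(zy), 1)
  expect_error(zscore(rep(2, 5)), "constant")
})

test_that("repeatability equals the raw-sums-of-squares oracle", {
  # constructed 3 groups x 4 observations
  vals <- c(10, 11, 12, 11, 20, 19, 21, 20, 30, 31, 29, 30)
  grp <- rep(c("a", "b", "c"), each = 4)
  got <- repeatability(vals, grp)
  expect_equal(got$r, brute_repeatability(vals, grp), tolerance = 1e-12)

  # unbalanced groups agree with the oracle too
  vals2 <- c(vals, 32, 9)
  grp2 <- c(grp, "c", "a")
  expect_equal(repeatability(vals2, grp2)$r,
               brute_repeatability(vals2, grp2), tolerance = 1e-12)

  # boundaries: no within-group variance -> 1; permuted labels -> ~0
  perfect <- repeatability(rep(c(1, 5, 9), each = 4),
                           rep(1:3, each = 4))
  expect_equal(perfect$r, 1)
  big <- withr::with_seed(14, rnorm(400))
  noise <- suppressWarnings(repeatability(big, rep(1:40, each = 10)))
  expect_lt(noise$r, 0.08)
})

test_that("marginal and conditional R2 recover a known variance partition", {
  # fixed variance 2, group variance 1, residual 1 -> r2m 0.5, r2c 0.75
  d <- sim_lmm_data(n_groups = 60, per_group = 25, beta = c(0, sqrt(2)),
                    sd_group = 1, sd_e = 1, seed = 20)
  fit <- fit_lmm(y ~ x + (1 | g), d)
  r2 <- r2_nakagawa(fit)
  expect_equal(r2$r2_marginal, 0.5, tolerance = 0.06)
  expect_equal(r2$r2_conditional, 0.75, tolerance = 0.06)
  expect_gte(r2$r2_conditional, r2$r2_marginal)

  # null fixed effect -> marginal ~ 0
  d0 <- sim_lmm_data(n_groups = 40, per_group = 10, beta = c(1, 0), seed = 21)
  r20 <- r2_nakagawa(fit_lmm(y ~ x + (1 | g), d0))
  expect_lt(r20$r2_marginal, 0.02)
})

test_that("tidy and glance return broom-shaped summaries", {
  d <- sim_lmm_data(seed = 30)
  fit <- fit_lmm(y ~ x + (1 | g), d)
  td <- tidy(fit, n_draws = 2000, seed = 1)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d))
  expect_true(gl$r2_conditional >= gl$r2_marginal)
})

test_that("a standardized slope back-transforms to natural units", {
  # slope 0.3 in SD units with response SD 10.1 -> ~3 natural units per SD
  expect_equal(unstandardize_slope(0.300, 10.1), 3.03)
  # self-consistency on simulated data: z-z slope times SDs ~ raw slope
  d <- withr::with_seed(31, {
    x <- rnorm(200, 50, 12)
    tibble::tibble(x = x, y = 3 + 0.4 * x + rnorm(200, sd = 2))
  })
  fz <- stats::lm(as.numeric(zscore(d$y)) ~ as.numeric(zscore(d$x)))
  raw_effect <- unstandardize_slope(stats::coef(fz)[2], sd(d$y))
  expect_equal(unname(raw_effect), 0.4 * sd(d$x), tolerance = 0.05)
})
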