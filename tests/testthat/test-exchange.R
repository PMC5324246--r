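test_that("single constructed pairs land in the right correlogram bin", {
  cg <- cross_correlogram(10.0, 10.21)
  expect_equal(sum(cg$count), 1L)
  hit <- cg[cg$count == 1, ]
  expect_true(hit$bin_left_s <= 0.21 && 0.21 < hit$bin_right_s)

  empty <- cross_correlogram(c(1, 2, 3), numeric(0))
  expect_true(all(empty$count == 0))
  none <- cross_correlogram(numeric(0), c(1, 2))
  expect_true(all(none$count == 0))
  expect_equal(attr(none, "n_focal"), 0L)
})

test_that("sorted-search correlogram equals the brute-force double loop", {
  for (s in 1:20) {
    set.seed(s)
    f <- sort(runif(sample(50:200, 1), 0, 300))
    p <- sort(runif(sample(50:200, 1), 0, 300))
    cg <- cross_correlogram(f, p)
    expect_identical(cg$count, brute_correlogram(f, p))
  }
})

test_that("correlogram mirror: swapping roles reverses the lag axis", {
  set.seed(4)
  f <- runif(150, 0, 200)
  p <- runif(150, 0, 200)
  ab <- cross_correlogram(f, p)
  ba <- cross_correlogram(p, f)
  # continuous data: no lag falls exactly on a bin edge, so counts mirror
  expect_identical(ab$count, rev(ba$count))
})

test_that("answer/answered counting follows the half-second windows", {
  expect_equal(count_answers(1.0, 1.3), list(n_answers = 1L, n_answered = 0L))
  expect_equal(count_answers(1.0, 0.7), list(n_answers = 0L, n_answered = 1L))
  # tie at lag zero counts as answered
  expect_equal(count_answers(1.0, 1.0), list(n_answers = 0L, n_answered = 1L))
  # dedupe: a partner call between two focal calls is counted once
  both <- count_answers(c(0, 0.4), 0.2)
  expect_equal(both$n_answers + both$n_answered, 1L)
  # all-pairs mode reproduces the literal double count
  lit <- count_answers(c(0, 0.4), 0.2, dedupe = FALSE)
  expect_equal(lit$n_answers + lit$n_answered, 2L)
})

test_that("all-pairs counting equals the brute-force oracle on random streams", {
  for (s in 1:10) {
    set.seed(s)
    f <- sort(runif(100, 0, 100))
    p <- sort(runif(100, 0, 100))
    got <- count_answers(f, p, dedupe = FALSE)
    want <- brute_answers(f, p)
    expect_equal(got$n_answers, want$n_answers)
    expect_equal(got$n_answered, want$n_answered)
  }
})

test_that("deduped counts never exceed the number of partner calls", {
  for (s in 1:10) {
    set.seed(s)
    f <- sort(runif(80, 0, 50))   # dense streams force shared windows
    p <- sort(runif(60, 0, 50))
    got <- count_answers(f, p)
    expect_lte(got$n_answers + got$n_answered, length(p))
  }
})

test_that("directionality index arithmetic, bounds, and undefined case", {
  expect_equal(directionality_index(10, 10), 0)
  expect_equal(directionality_index(3, 1), 0.5)
  expect_equal(directionality_index(0, 5), -1)
  expect_equal(directionality_index(5, 0), 1)
  expect_equal(directionality_index(3, 1, display = TRUE), 50)
  und <- directionality_index(0, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  # antisymmetry under role swap (answers <-> answered)
  for (i in 1:20) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    if (a + b == 0) next
    expect_equal(directionality_index(a, b), -directionality_index(b, a))
    expect_lte(abs(directionality_index(a, b)), 1)
  }
})

test_that("count_answers recovers the configured answer probability", {
  # sparse calling: chance coincidences are negligible next to 3 MC SDs
  cfg <- sim_config(duration_s = 10000, base_rate_f = 0.02,
                    base_rate_m = 0.02, p_answer_f = 0, p_answer_m = 0.3,
                    seed = 31)
  ev <- simulate_pair_calling(cfg)
  f <- ev$onset_s[ev$bird == "F"]
  m <- ev$onset_s[ev$bird == "M"]
  got <- count_answers(f, m)
  n_f <- length(f)
  expect_lt(abs(got$n_answers / n_f - 0.3), 3 * sqrt(0.3 * 0.7 / n_f))
})

test_that("Poisson limits match the pmf-summation oracle", {
  for (lambda in c(0.5, 1, 4, 9.7, 25)) {
    for (alpha in c(0.05, 0.01)) {
      got <- poisson_limits(rep(lambda, 10), alpha = alpha)
      want <- brute_poisson_limits(lambda, alpha)
      expect_equal(got$upper, want$upper)
      expect_equal(got$lower, want$lower)
    }
  }
  degen <- poisson_limits(rep(0, 10))
  expect_true(degen$degenerate)
  expect_equal(degen$upper, 0)
})

test_that("antiphony detection finds simulated coupling and its latency", {
  cfg <- sim_config(duration_s = 4000, p_answer_f = 0.4, p_answer_m = 0.4,
                    seed = 17)
  ev <- simulate_pair_calling(cfg)
  cg <- cross_correlogram(ev$onset_s[ev$bird == "F"],
                          ev$onset_s[ev$bird == "M"])
  det <- detect_antiphony(cg)
  expect_true(det$is_antiphonal)
  # latency distribution modes near 150 ms
  expect_gte(det$peak_latency_s, 0.1)
  expect_lte(det$peak_latency_s, 0.25)

  # constructed: a single over-threshold bin fixes the latency exactly
  cg2 <- cross_correlogram(10, 10.22)
  det2 <- detect_antiphony(cg2, limits = list(lambda = 0, upper = 0,
                                              lower = 0, alpha = 0.05))
  expect_true(det2$is_antiphonal)
  expect_equal(det2$peak_latency_s, 0.22, tolerance = 0.021)

  empty <- detect_antiphony(cross_correlogram(numeric(0), numeric(0)),
                            limits = list(lambda = 0, upper = 0, lower = 0))
  expect_false(empty$is_antiphonal)
  expect_true(is.na(empty$peak_latency_s))
})

test_that("overlap rate matches direct interval intersection", {
  expect_equal(overlap_rate(ev_tbl(c(0, 10)), ev_tbl(c(5, 20))), 0)
  same <- ev_tbl(c(0, 10, 20))
  expect_equal(overlap_rate(same, same), 1)
  for (s in 1:10) {
    set.seed(s)
    f <- ev_tbl(runif(60, 0, 60), durations = runif(60, 0.05, 0.4))
    p <- ev_tbl(runif(60, 0, 60), durations = runif(60, 0.05, 0.4))
    expect_equal(overlap_rate(f, p), brute_overlap(f, p))
  }
  expect_error(overlap_rate(dplyr::select(same, -duration_s), same),
               "duration")
})

test_that("uncoupled pairs rarely cross the 99% limits in the answer window", {
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(duration_s = 2000, base_rate_f = 0.2, base_rate_m = 0.2,
                      p_answer_f = 0, p_answer_m = 0, refractory_s = 0,
                      seed = 5000 + s)
    ev <- simulate_pair_calling(cfg)
    cg <- cross_correlogram(ev$onset_s[ev$bird == "F"],
                            ev$onset_s[ev$bird == "M"])
    detect_antiphony(cg, alpha = 0.01)$is_antiphonal
  }, logical(1))
  # 13 answer-window bins tested at ~alpha/2 each: the pair is called
  # non-antiphonal in at least 95% of uncoupled simulations
  expect_lte(mean(hits), 0.05)
})
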