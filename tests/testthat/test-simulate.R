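test_that("zero rates and zero answer probabilities give empty streams", {
  cfg <- sim_config(duration_s = 100, base_rate_f = 0, base_rate_m = 0,
                    p_answer_f = 0, p_answer_m = 0, seed = 1)
  ev <- simulate_pair_calling(cfg)
  expect_equal(nrow(ev), 0L)
})

test_that("invalid simulator parameters are rejected with clear messages", {
  expect_error(sim_config(base_rate_f = -1), "base_rate_f")
  expect_error(sim_config(p_answer_m = 1.5), "p_answer_m")
  expect_error(sim_config(duration_s = NaN), "duration_s")
  expect_error(sim_config(repertoire = c(Stack = 0.6, Tet = 0.5)), "sum to 1")
  expect_error(sim_config(repertoire = c(0.5, 0.5)), "named")
})

test_that("the generated streams respect refractoriness and latency support", {
  cfg <- sim_config(duration_s = 2000, p_answer_f = 0.5, p_answer_m = 0.5,
                    seed = 11)
  ev <- simulate_pair_calling(cfg)
  for (b in c("F", "M")) {
    on <- ev$onset_s[ev$bird == b]
    expect_true(all(diff(on) >= cfg$refractory_s - 1e-12))
  }
  ans <- ev[ev$is_answer, ]
  trig_onset <- ev$onset_s[match(ans$trigger_id, ev$event_id)]
  lat <- ans$onset_s - trig_onset
  expect_true(all(lat > 0 & lat <= 0.5))
})

test_that("simulation is reproducible for a fixed seed and call types follow the repertoire", {
  cfg <- sim_config(duration_s = 3000, seed = 7)
  a <- simulate_pair_calling(cfg)
  b <- simulate_pair_calling(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  props <- prop.table(table(a$call_type))[names(cfg$repertoire)]
  expect_true(max(abs(props - cfg$repertoire)) < 0.05)
})

test_that("event counts match the baseline-plus-answers expectation", {
  cfg <- sim_config(duration_s = 10000, base_rate_f = 0.1, base_rate_m = 0.2,
                    p_answer_f = 0.4, p_answer_m = 0.2, refractory_s = 0,
                    seed = 23)
  ev <- simulate_pair_calling(cfg)
  n_base_f <- sum(ev$bird == "F" & !ev$is_answer)
  n_base_m <- sum(ev$bird == "M" & !ev$is_answer)
  # baseline Poisson counts: within 4 SD of rate * duration
  expect_lt(abs(n_base_f - 1000), 4 * sqrt(1000))
  expect_lt(abs(n_base_m - 2000), 4 * sqrt(2000))
  # answers: binomial on the partner's baseline count
  n_ans_f <- sum(ev$bird == "F" & ev$is_answer)
  n_ans_m <- sum(ev$bird == "M" & ev$is_answer)
  expect_lt(abs(n_ans_f - 0.4 * n_base_m), 4 * sqrt(n_base_m * 0.4 * 0.6))
  expect_lt(abs(n_ans_m - 0.2 * n_base_f), 4 * sqrt(n_base_f * 0.2 * 0.8))
})

test_that("a symmetric configuration gives a directionality index near zero", {
  idx <- vapply(1:50, function(s) {
    ev <- simulate_pair_calling(sim_config(duration_s = 500, seed = s,
                                           p_answer_f = 0.3, p_answer_m = 0.3))
    a <- sum(ev$bird == "M" & ev$is_answer)
    b <- sum(ev$bird == "F" & ev$is_answer)
    (a - b) / (a + b)
  }, numeric(1))
  expect_lt(abs(mean(idx)), 3 * sd(idx) / sqrt(length(idx)))
})

test_that("asymmetric answer probabilities give the closed-form index", {
  # p_m = 0.4, p_f = 0.1, equal base rates -> E[index] = 0.3/0.5 = 0.6
  counts <- vapply(1:20, function(s) {
    ev <- simulate_pair_calling(sim_config(
      duration_s = 2000, p_answer_f = 0.1, p_answer_m = 0.4, seed = 100 + s))
    c(sum(ev$bird == "M" & ev$is_answer), sum(ev$bird == "F" & ev$is_answer))
  }, numeric(2))
  idx <- (counts[1, ] - counts[2, ]) / (counts[1, ] + counts[2, ])
  expect_lt(abs(mean(idx) - 0.6), 3 * sd(idx) / sqrt(ncol(counts)))
})

test_that("behaviour tracks tile the scored window and hit stationary occupancy", {
  one <- simulate_behavior_track("Only", 10, total_s = 100, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start_s, one$stop_s), c(0, 100))

  trk <- simulate_behavior_track(c("A", "B", "C"), c(10, 10, 10),
                                 total_s = 10000, seed = 5)
  expect_equal(trk$start_s[-1], trk$stop_s[-nrow(trk)])
  expect_equal(max(trk$stop_s), 10000)
  occ <- tapply(trk$stop_s - trk$start_s, trk$state, sum) / 10000
  expect_true(all(abs(occ - 1 / 3) < 0.05))

  again <- simulate_behavior_track(c("A", "B", "C"), c(10, 10, 10),
                                   total_s = 10000, seed = 5)
  expect_identical(as.data.frame(trk), as.data.frame(again))
  expect_error(simulate_behavior_track(character(), 1, 10), "non-empty")
})

test_that("rendered audio places calls at their onsets with the right gains", {
  sr <- 8000
  tpl <- call_templates("Stack", freq_hz = 1000, duration_s = 0.1,
                        sample_rate = sr)
  silent <- render_audio(ev_tbl(numeric(0))[0, ], tpl, sample_rate = sr,
                         duration_s = 1)
  expect_true(all(silent$F$wave == 0))

  ev <- ev_tbl(1.0)
  au <- render_audio(ev, tpl, sample_rate = sr, duration_s = 2)
  nz <- which(au$F$wave != 0)
  expect_gte(min(nz) / sr, 1.0 - 1e-3)
  expect_lte(max(nz) / sr, 1.1 + 2e-3)

  # partner leak ~10x lower RMS in the focal channel
  both <- dplyr::bind_rows(ev_tbl(1.0, bird = "F"), ev_tbl(3.0, bird = "M"))
  au2 <- render_audio(both, tpl, sample_rate = sr, own_gain = 1,
                      partner_gain = 0.1, duration_s = 4)
  rms <- function(x) sqrt(mean(x^2))
  own <- au2$F$wave[(1.0 * sr):(1.1 * sr)]
  leak <- au2$F$wave[(3.0 * sr):(3.1 * sr)]
  expect_equal(rms(own) / rms(leak), 10, tolerance = 0.01)
  expect_error(render_audio(both, tpl, own_gain = 0.1, partner_gain = 0.5),
               "own_gain")
})

test_that("WAV files round-trip through the PCM16 reader and writer", {
  sr <- 8000
  x <- sin(2 * pi * 440 * seq(0, 0.2, by = 1 / sr)) * 0.8
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f, sr)
  back <- read_wav(f)
  expect_equal(back$sample_rate, sr)
  expect_lt(max(abs(back$wave - x)), 1 / 32767 * 2)
})
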