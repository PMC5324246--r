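---
title: "Methods: simulating and measuring antiphonal calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring antiphonal calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model behind the synthetic-data generator,
every default parameter, and the numerical decisions inside the
estimators — in particular the choices that are conventions rather than
mathematical necessities.

## 1. The generator

`simulate_pair_calling()` draws one pair-recording with ground truth:

* **Baseline calling.** Each bird's spontaneous calls are a homogeneous
  Poisson process: the call count over `duration_s` is Poisson with mean
  `rate × duration`, and onsets are uniform given the count. Real
  calling is burstier than Poisson; homogeneity is chosen so that the
  correlogram's null distribution (Section 3) is exactly the one the
  detector assumes, making coverage testable.
* **Answering.** Every baseline call of one bird is answered by the
  partner independently with probability `p_answer_<partner>`, at a
  latency drawn from a Gamma(`latency_shape`, `latency_scale`)
  distribution truncated to `(0, latency_max_s]` by inverse-CDF sampling
  (draw `u` uniform on `(0, F(max)]`, return `F⁻¹(u)`; exact, no
  rejection loop). Defaults shape 4, scale 0.05 place the latency mode
  near 150 ms — the sharp sub-500-ms correlogram peak typical of
  antiphonal pairs.
* **No chaining by default.** Answers do not themselves trigger answers
  (`chain_answers = FALSE`), so event counts have closed forms: with
  equal base rates, `E[N_m_answers] = p_m × N_f_baseline` and the
  expected directionality index is `(p_m − p_f) / (p_m + p_f)`.
* **Refractory period.** Onsets closer than `refractory_s` (default
  0.1 s) to the same bird's previous kept onset are dropped — earliest
  onset wins — and answers whose trigger was dropped are removed too, so
  the `is_answer` / `trigger_id` truth columns stay consistent. Tests
  that rely on the closed forms set `refractory_s = 0`, where they are
  exact.
* **Call types.** Types are sampled i.i.d. from `repertoire`
  (default stack-dominated: Stack 0.65, Tet 0.13, Distance 0.08,
  Kackle 0.06, Whine 0.05, Hat 0.03), with per-type durations.
  Type and timing are independent — a simplification; real stack calls
  carry most of the antiphonal structure.

Default `base_rate = 0.17` calls/s is the average rate of an 8-hour
recording day in this kind of study (~5000 calls/bird/day).

**Seeds.** All randomness flows through `split_seed()`: a master seed
deterministically yields independent sub-seeds (one per stream), so
adding a stream never perturbs the others.

**What the generator does not emulate:** diurnal rate modulation,
bout structure, latency dependence on call type or context, acoustic
individuality, or any influence of behavioural state on calling. The
fixtures (`make_fixture()`) impose cohort structure (convergence of new
pairs, symmetric established pairs, uncoupled null) only through the
answer probabilities and the clumping dwell times.

## 2. Answer counting and the directionality index

`count_answers()` counts partner calls in `(0, 0.5]` s after a focal
call (*answers*) and `[−0.5, 0]` s before one (*answered*). Two
conventions needed fixing:

* **Deduplication (default).** A partner call sitting between two focal
  calls falls in both windows. By default each partner call is assigned
  to its *nearest* focal call only, so
  `n_answers + n_answered ≤ n_partner` and an answer proportion can be
  read as a per-call probability. The literal all-pairs count is
  available with `dedupe = FALSE`; the brute-force oracle in the tests
  checks that mode exactly. Note that deduplication makes the *pairing*
  slightly asymmetric under role swap; the antisymmetry property
  `D(a, b) = −D(b, a)` holds at the index-formula level, which is what
  the statistic claims.
* **Ties.** A lag of exactly 0 counts as *answered* (the partner called
  first or simultaneously); probability-zero for continuous data.

`directionality_index(n_answers, n_answered)` is the normalized
difference; `0/0` returns `NA` flagged `undefined` rather than 0 — "no
exchange" is not "symmetric exchange".

## 3. Correlogram and Poisson limits

`cross_correlogram()` histograms partner-minus-focal lags over
`[−2, 2)` s in 100 half-open `[left, right)` bins of 40 ms. Half-open
binning makes every lag land in exactly one bin; bin membership is
computed by `floor((lag + w)/bw)` rather than `findInterval` on edges so
the oracle arithmetic is identical. Lag collection uses a vectorized
sorted search (`findInterval` windows per focal call), `O((n+m) log m)`,
proven equal to the all-pairs double loop in the tests.

The **baseline flanks** `[−4, −2) ∪ (2, 4]` are binned at the same
width; their mean count is the null intensity λ. Under the uncoupled
Poisson null every main-window bin count is Poisson(λ), so
`poisson_limits()` uses integer quantiles: upper = `qpois(1 − α/2, λ)`,
lower = `qpois(α/2, λ)`. Because the distribution is discrete, the
realized two-sided exceedance is *below* α and depends on λ — at the
study-scale regime (8-h day at 0.17 calls/s, λ ≈ 33 per bin) it is
≈ 0.044 for α = 0.05. The acceptance coverage test simulates exactly
that regime and checks the empirical exceedance against (0.035, 0.065),
a band derived from this discreteness arithmetic *a priori*, not fitted.

`detect_antiphony()` flags a pair when any of the 13 answer-window bins
(centres 0.02–0.50 s) exceeds the upper limit, and reports the centre of
the maximal answer-window bin as the peak latency. With 13 bins tested
at ~α/2 each, the family-wise false-positive rate at α = 0.05 is a few
percent per pair-day in moderate-λ regimes but grows in very-low-λ
regimes (where the discrete lower limit does no work and single
coincidences can clear a tiny upper limit); screening at α = 0.01 is
recommended for short recordings, and the null-fixture test uses it.

**Detector validation at sparse rates.** Answer-proportion estimates
from the detector include chance coincidences (expected
`N_partner × 1 s / duration` per focal call), a real bias at normal
rates. The estimator test therefore uses a sparse configuration
(0.02 calls/s over 10 000 s) where the bias is far below the Monte-Carlo
tolerance, while the closed-form recovery grid uses the simulator's
truth flags — the unbiased count of *generated* answers.

## 4. Audio front end

* `render_audio()` emulates backpack microphones: own calls at gain 1,
  partner leak at a configurable lower gain, optional white noise, peak
  normalization with the scale factor reported.
* Templates are Hann-windowed (optionally chirped) sinusoids — enough to
  give call types distinct durations, spectra, and envelopes without
  modelling real syrinx acoustics.
* `segment_vocalizations()` thresholds a moving-RMS envelope in dBFS
  (5 ms window), merges active runs separated by < `min_gap_s` and
  drops runs shorter than `min_dur_s`. The threshold must sit between
  the noise floor and the call envelope; the acceptance test derives it
  from the configured 20 dB SNR rather than tuning it.
* `extract_features()` computes ten spectro-temporal parameters from a
  512-sample Hann spectrogram at 75% overlap (≈ 43 Hz bins at
  22.05 kHz). The *first peak* is interpreted as the lowest-frequency
  local maximum of the mean spectrum that reaches at least `peak_floor`
  (10%) of the frame maximum — an interpretation choice; a pure tone's
  first peak equals its centroid, which the tests pin down.
* `cluster_calls()` z-scores the features and fits a Gaussian mixture
  with the richest covariance structure the sample supports
  (BIC over VVV → EII), falling back to k-means (hard 0/1 posteriors)
  when no mixture converges. Segments whose maximum posterior is below
  0.6 are labelled `Unassigned` — mirroring manual-review workflows —
  and `apply_labels()` re-ingests hand-edited labels verbatim.
* `remove_nonfocal()` removes partner-leak segments by intensity: it
  keeps segments within `intensity_margin_db` (default 10 dB) of the
  *density mode* of segment peak levels, the mode being robust to a
  minority leak population.
* WAV I/O is a deliberately minimal mono PCM-16 RIFF reader/writer —
  the only format the renderer needs — validated by round-trip to
  16-bit quantization error.

## 5. Behaviour integration

`align_streams()` maps the video clock onto the audio clock: a constant
offset for one anchor, a least-squares affine fit (absorbing drift) for
two or more, warning when residuals exceed 0.5 s.
`clumping_proportion()` is interval arithmetic over the scored window;
`rate_by_state()` assigns onsets to half-open `[start, stop)` intervals,
returns `NA` (not 0) for unobserved states, and reports events outside
the scored intervals instead of silently dropping them.

## 6. Inference

* `fit_lmm()` fits ML (`REML = FALSE`) mixed models via `lme4`,
  dropping to `lm` with a warning when a grouping factor has too few
  levels; singular fits are flagged, not hidden. An optional `sqrt`
  transform serves rate responses.
* `posterior_sim()` draws fixed-effect vectors from
  N(β̂, V̂ᵦ) — the flat-prior approximation with variance components
  held at their ML estimates. Covariances are symmetrized and repaired
  by eigenvalue clipping only when numerically indefinite.
  `derived_p(a, b)` is the fraction of paired draws with `a > b`;
  `p_two_sided = 2 × min(p, 1 − p)` is reported alongside.
* `run_exchange_models()` fits the canonical battery (clumping,
  |directionality|, rate by state, call matching, answer matching,
  z-z answer–clumping with a nonzero-clumping rerun), *refusing* —
  with the reason listed in `$skipped` — any model whose replication is
  insufficient, and dropping pair-days where a response is undefined
  (e.g. `0/0` directionality). Group contrasts are computed by pushing
  the posterior draws through design rows, so "day 7 vs day 1 within
  new pairs" is a genuine derived p, not a coefficient test. Day enters
  as a categorical factor; the day random factor in the matching models
  is crossed with pair.
* `repeatability()` is the one-way-ANOVA intraclass correlation with the
  unequal-group-size coefficient
  `n0 = (N − Σnᵢ²/N)/(a − 1)`; a negative among-group component is
  truncated to 0 and flagged. The SE is the standard large-sample
  approximation for the intraclass correlation. `r2_nakagawa()` takes
  marginal r² as `var(Xβ̂)` over the total of fixed, summed
  random-intercept, and residual variances.

The derived-p machinery is anticonservative at small replication (ML
variance estimates are biased low and the draws are normal, not t); at
the default cohort size (12 pairs × 4 days) the effective two-sided
extremity rate of a null contrast is ≈ 0.08 rather than 0.05, which the
null-cohort acceptance bound accounts for explicitly.

## 7. Pipeline

`run_pipeline()` runs load/simulate → exchange summaries → models →
outputs from a YAML (or list) config. Failures abort naming the stage.
A `manifest.yaml` records parameters, seeds, and input checksums; a
rerun with unchanged inputs reuses the existing pair-day table
(byte-identical outputs), and any change invalidates exactly the stages
downstream of it. There is no shell wrapper: the functions are the
interface, and `make_fixture()` + `run_pipeline()` reproduce every
artefact from a seed.

## 8. Problem sizes used in validation

Oracle comparisons use up to 500 × 500-event streams (100 random
problems); coverage uses 500 simulated 8-h pair-days; parameter recovery
uses a 3 × 3 answer-probability grid × 10 replicates of 2000 s;
audio recovery uses ~45 calls of two types at 20 dB SNR and 22.05 kHz;
inference recovery uses the default cohort (12 pairs × 4 days) once for
the signal case and 100 seeds of a reduced-duration null cohort. All
tolerance bands were derived from binomial/Poisson arithmetic before the
tests were run.
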