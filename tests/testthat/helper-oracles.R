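# Independent brute-force oracles used to cross-check the fast
# implementations. Deliberately naive: double loops and raw sums only.

# O(n*m) correlogram: bin every (focal, partner) pair directly
brute_correlogram <- function(focal, partner, half_window = 2, n_bins = 100) {
  bw <- 2 * half_window / n_bins
  counts <- integer(n_bins)
  for (t in focal) {
    for (u in partner) {
      d <- u - t
      if (d >= -half_window && d < half_window) {
        b <- floor((d + half_window) / bw) + 1
        counts[min(b, n_bins)] <- counts[min(b, n_bins)] + 1L
      }
    }
  }
  counts
}

# same brute-force all-pairs binning, vectorized with outer() so large
# random problems stay fast; still O(n*m) with no sorted-search shortcuts
brute_correlogram_outer <- function(focal, partner, half_window = 2,
                                    n_bins = 100) {
  bw <- 2 * half_window / n_bins
  d <- as.numeric(outer(partner, focal, "-"))
  d <- d[d >= -half_window & d < half_window]
  tabulate(pmin(floor((d + half_window) / bw) + 1L, n_bins), nbins = n_bins)
}

# all-pairs answer counting (no dedupe), direct double loop
brute_answers <- function(focal, partner, window = 0.5) {
  n_answers <- 0L
  n_answered <- 0L
  for (t in focal) {
    for (u in partner) {
      d <- u - t
      if (d > 0 && d <= window) n_answers <- n_answers + 1L
      if (d >= -window && d <= 0) n_answered <- n_answered + 1L
    }
  }
  list(n_answers = n_answers, n_answered = n_answered)
}

# overlap by direct interval intersection
brute_overlap <- function(focal, partner) {
  hits <- vapply(seq_len(nrow(focal)), function(i) {
    f0 <- focal$onset_s[i]
    f1 <- f0 + focal$duration_s[i]
    any(partner$onset_s < f1 & partner$onset_s + partner$duration_s > f0)
  }, logical(1))
  mean(hits)
}

# one-way ANOVA repeatability from raw sums of squares (no aov/anova calls)
brute_repeatability <- function(values, groups) {
  g <- split(values, groups)
  a <- length(g)
  N <- length(values)
  grand <- mean(values)
  ss_a <- sum(vapply(g, function(x) length(x) * (mean(x) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  ms_a <- ss_a / (a - 1)
  ms_w <- ss_w / (N - a)
  sizes <- vapply(g, length, numeric(1))
  n0 <- (N - sum(sizes^2) / N) / (a - 1)
  s2_a <- max((ms_a - ms_w) / n0, 0)
  s2_a / (s2_a + ms_w)
}

# Poisson quantile limits by direct pmf summation
brute_poisson_limits <- function(lambda, alpha) {
  cum <- 0
  u <- 0
  repeat {
    cum <- cum + dpois(u, lambda)
    if (cum >= 1 - alpha / 2) break
    u <- u + 1
  }
  cum <- 0
  l <- 0
  repeat {
    # largest L with P(X <= L - 1) <= alpha/2
    if (cum + dpois(l, lambda) > alpha / 2) break
    cum <- cum + dpois(l, lambda)
    l <- l + 1
  }
  list(upper = u, lower = l)
}

# small event tibble constructor
ev_tbl <- function(onsets, durations = 0.1, bird = "F", type = "Stack") {
  tibble::tibble(bird = bird, onset_s = onsets,
                 duration_s = rep_len(durations, length(onsets)),
                 call_type = type)
}
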