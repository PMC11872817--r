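# Shared fixtures: small deterministic recordings and reduced analysis
# configurations used across the test files.

# Recording whose channels are given functions of time (or constants).
make_recording <- function(channel_fns, fs = 200, duration_s = 10,
                           labels = NULL, subject_id = "s01",
                           condition = "pre") {
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  data <- t(vapply(channel_fns, function(f) {
    if (is.function(f)) f(t) else rep_len(f, n)
  }, numeric(n)))
  if (is.null(labels)) labels <- standard_montage()[seq_len(nrow(data))]
  eeg_recording(data, fs, labels, subject_id = subject_id,
                condition = condition)
}

# Reduced analysis configuration: 3 bands, lean coherence pairs, a 2x2
# comodulogram on one region. Keeps cohort-level tests fast while touching
# every feature kind.
fast_analysis_config <- function(...) {
  analysis_config(
    bands = list(delta = c(1, 4), alpha = c(8, 14), beta_gamma = c(14, 80)),
    coherence_pairs = list("occipital", c("parietal", "frontal_complete")),
    cfc_pairs = list("fronto_polar"),
    cfc_modulating = c(4, 8), cfc_modulated = c(40, 60),
    ...)
}

# Reduced-duration cohort: the generator's stated world except for length
# (6 s instead of 120 s), used where many cohorts must be simulated.
fast_cohort_config <- function(seed, ...) {
  cohort_config(n_subjects = 10, duration_s = 6, seed = seed, ...)
}

# Phase unwrapping (test-side oracle for instantaneous-frequency fits).
unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Exact two-sided signed-rank p-value by exhaustive sign enumeration
# (feasible for n <= 12): distribution of the positive-rank sum over all
# 2^n sign assignments of the observed |diff| ranks. Mid-p convention (the
# attained value counts half), which is the discrete quantity an
# uncorrected normal approximation estimates; the ordinary tail p is what a
# continuity-corrected approximation targets instead.
exact_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_low <- mean(w_all < w_obs) + mean(w_all == w_obs) / 2
  p_high <- mean(w_all > w_obs) + mean(w_all == w_obs) / 2
  min(1, 2 * min(p_low, p_high))
}
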