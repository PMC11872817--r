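test_that("single-sample intervals give entropy exactly 1", {
  set.seed(301)
  x <- rnorm(500)
  expect_identical(entropy_at_length(x, 1), 1)
  expect_identical(tsallis_entropy(x, lengths = 1L), 1)
})

test_that("step-plus-noise entropy approaches the law-of-total-variance limit", {
  set.seed(302)
  N <- 2e4
  cc <- 2; sigma <- 1
  x <- c(rep(cc, N / 2), rep(-cc, N / 2)) + rnorm(N, sd = sigma)
  # two intervals of length N/2: within-variance ~ sigma^2, total ~ c^2+sigma^2
  expect_equal(entropy_at_length(x, N / 2), cc^2 / (cc^2 + sigma^2),
               tolerance = 0.02)
})

test_that("white-noise entropy at one length matches the 1/L prediction", {
  set.seed(303)
  N <- 5e4; L <- 50
  x <- rnorm(N)
  # E[H] = 1/L for iid noise; Var(Var) of the normal gives the scale of noise
  M <- N %/% L
  se <- sqrt(2 / L) / sqrt(M)   # sd of the mean of M interval variances
  expect_lt(abs(entropy_at_length(x, L) - 1 / L), 3 * se)
})

test_that("entropy is invariant to amplitude scaling", {
  set.seed(304)
  x <- cumsum(rnorm(3000))
  expect_equal(tsallis_entropy(17.3 * x), tsallis_entropy(x),
               tolerance = 1e-12)
  expect_equal(tsallis_entropy(-0.01 * x), tsallis_entropy(x),
               tolerance = 1e-12)
})

test_that("entropy over the length grid equals the loop-wise mean", {
  set.seed(305)
  x <- as.numeric(arima.sim(list(ar = 0.95), 2000))
  Ls <- te_lengths()
  expect_length(Ls, 100)
  expect_equal(Ls[1], 1L)
  expect_equal(Ls[100], 500L)
  by_loop <- mean(vapply(Ls, function(L) entropy_at_length(x, L),
                         numeric(1)))
  expect_equal(tsallis_entropy(x), by_loop, tolerance = 1e-12)
  # mean bounded by the per-length extremes
  hs <- vapply(Ls, function(L) entropy_at_length(x, L), numeric(1))
  expect_gte(tsallis_entropy(x), min(hs))
  expect_lte(tsallis_entropy(x), max(hs))
})

test_that("entropy stays in [0, 1] when intervals tile the series", {
  set.seed(306)
  for (i in 1:20) {
    L <- sample(c(1, 2, 5, 10, 25), 1)
    x <- rnorm(L * sample(5:40, 1)) + seq(0, runif(1, 0, 5),
                                          length.out = L * 5)[1]
    h <- entropy_at_length(x, L)
    expect_gte(h, -1e-12)
    expect_lte(h, 1 + 1e-12)
  }
})

test_that("a growing linear trend never decreases entropy", {
  set.seed(307)
  noise <- rnorm(2000)
  tt <- seq(0, 1, length.out = 2000)
  prev <- -Inf
  for (slope in c(0, 1, 2, 5, 10, 20)) {
    h <- tsallis_entropy(noise + slope * tt)
    expect_gte(h + 1e-9, prev)
    prev <- h
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(entropy_at_length(rep(3, 100), 10), "constant")
  expect_error(entropy_at_length(rnorm(100), 101), "L must be")
  expect_error(tsallis_entropy(rnorm(400)), "shorter")
})

test_that("entropy table aggregates channels into regions", {
  set.seed(308)
  v <- as.numeric(arima.sim(list(ar = 0.9), 1200))
  w <- rnorm(1200)
  rec <- make_recording(list(function(t) v, function(t) v, function(t) w),
                        duration_s = 6, labels = c("O1", "O2", "Cz"))
  regs <- list(occipital = c("O1", "O2"), central = "Cz")
  et <- entropy_table(rec, regs)
  ch <- et[et$scope_type == "channel", ]
  # identical channels, identical TE; region mean of equal values
  expect_equal(ch$te[ch$scope == "O1"], ch$te[ch$scope == "O2"])
  expect_equal(et$te[et$scope == "occipital"], ch$te[ch$scope == "O1"])
  expect_equal(et$te[et$scope == "central"], ch$te[ch$scope == "Cz"])
  expect_equal(et$te[et$scope_type == "all"], mean(ch$te))

  # structured (autocorrelated) channel has higher TE than white noise
  expect_gt(ch$te[ch$scope == "O1"], ch$te[ch$scope == "Cz"])
})
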