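test_that("Welch grid has the stated resolution and length", {
  set.seed(201)
  ps <- power_spectrum(rnorm(2000), fs = 200)
  expect_equal(diff(ps$frequencies)[1], 200 / 512)  # 0.390625 Hz
  expect_length(ps$frequencies, 512 / 2 + 1)
  expect_true(all(ps$power >= 0))
})

test_that("sinusoid power lands on the nearest bin and Parseval holds", {
  fs <- 200
  t <- (0:19999) / fs
  x <- sin(2 * pi * 10 * t)
  ps <- power_spectrum(x, fs = fs)
  peak <- ps$frequencies[which.max(ps$power)]
  expect_equal(peak, ps$frequencies[which.min(abs(ps$frequencies - 10))])
  total <- sum(ps$power) * (fs / 512)
  expect_equal(total, var(x), tolerance = 0.02)

  expect_true(all(power_spectrum(rep(0, 2000), fs = fs)$power == 0))
})

test_that("power spectra scale quadratically with amplitude", {
  set.seed(202)
  x <- rnorm(3000)
  p1 <- power_spectrum(x, fs = 200)$power
  p3 <- power_spectrum(3 * x, fs = 200)$power
  expect_equal(p3, 9 * p1, tolerance = 1e-10)
})

test_that("band power aggregates bins and channels as stated", {
  fs <- 200
  t <- (0:9999) / fs
  rec <- make_recording(list(function(tt) sin(2 * pi * 20 * tt),
                             function(tt) sin(2 * pi * 20 * tt)),
                        duration_s = 50, labels = c("O1", "O2"))
  sp <- channel_spectra(rec)
  regs <- list(occipital = c("O1", "O2"))
  expect_gt(band_power(sp, regs, "occipital", "beta"), 0)
  expect_lt(band_power(sp, regs, "occipital", "delta"),
            1e-6 * band_power(sp, regs, "occipital", "beta"))

  # composite band equals the bin-count-weighted combination of its parts
  freqs <- sp[["O1"]]$frequencies
  nb <- sum(freqs >= 14 & freqs < 31)
  ng <- sum(freqs >= 31 & freqs < 80)
  composite <- band_power(sp, regs, "occipital", "beta_gamma")
  parts <- (nb * band_power(sp, regs, "occipital", "beta") +
              ng * band_power(sp, regs, "occipital", "gamma")) / (nb + ng)
  expect_equal(composite, parts, tolerance = 1e-12)

  # identical channels: region value equals the channel value
  one <- band_power(sp, list(occipital = "O1"), "occipital", "alpha")
  both <- band_power(sp, regs, "occipital", "alpha")
  expect_equal(both, one)

  expect_error(band_power(sp, regs, "occipital", c(101, 110)), "no frequency")
})

test_that("coherence is 1 for identical signals and near 1 under delay", {
  set.seed(203)
  fs <- 200
  x <- as.numeric(arima.sim(list(ar = 0.9), 20000))
  cp <- coherence(x, x, fs = fs)
  expect_true(all(abs(cp$coherence - 1) < 1e-9))

  y <- c(rep(0, 5), x[1:(length(x) - 5)])
  cpd <- coherence(x, y, fs = fs)
  expect_gt(mean(cpd$coherence), 0.95)
})

test_that("independent-noise coherence matches the 1/K estimator bias", {
  set.seed(204)
  fs <- 200
  K <- 64
  n <- K * 512
  x <- rnorm(n); y <- rnorm(n)
  cp <- coherence(x, y, window_len = 512, overlap = 0, fs = fs)
  expect_equal(cp$n_segments, K)
  # E[coh] ~ 1/K for independent signals; SE of the bin mean ~ (1/K)/sqrt(nf)
  se <- (1 / K) / sqrt(length(cp$coherence))
  expect_lt(abs(mean(cp$coherence) - 1 / K), 3 * se + 0.2 / K)
})

test_that("coherence is symmetric, bounded, and needs two windows", {
  set.seed(205)
  fs <- 200
  x <- rnorm(4000); y <- rnorm(4000)
  cxy <- coherence(x, y, fs = fs)
  cyx <- coherence(y, x, fs = fs)
  expect_equal(cxy$coherence, cyx$coherence, tolerance = 1e-12)
  expect_true(all(cxy$coherence >= 0 & cxy$coherence <= 1))

  expect_error(coherence(rnorm(512), rnorm(512), overlap = 0, fs = fs),
               "at least 2 windows")
  expect_error(coherence(rnorm(4000), rnorm(4000), fs = NULL), "fs")
})

test_that("band coherence averages bins and rejects empty bands", {
  set.seed(206)
  x <- rnorm(4000)
  cp <- coherence(x, x, fs = 200)
  expect_equal(band_coherence(cp, "alpha"), 1, tolerance = 1e-9)
  expect_error(band_coherence(cp, c(150, 160)), "no frequency")

  # linear ramp over a band averages to ~0.5
  cp2 <- cp
  bins <- which(cp$frequencies >= 8 & cp$frequencies < 14)
  cp2$coherence[bins] <- seq(0, 1, length.out = length(bins))
  expect_equal(band_coherence(cp2, "alpha"), 0.5,
               tolerance = 1 / length(bins))
})

test_that("within-region coherence equals the two-channel coherence", {
  set.seed(207)
  fs <- 200
  shared <- rnorm(4000)
  rec <- make_recording(list(function(t) shared + rnorm(4000),
                             function(t) shared + rnorm(4000)),
                        duration_s = 20, labels = c("O1", "O2"))
  within <- region_coherence(rec, "occipital",
                             regions = list(occipital = c("O1", "O2")))
  o1 <- structure(list(region = "O1", fs = fs,
                       segments = list(rec$data[1, ])),
                  class = "region_signal")
  o2 <- structure(list(region = "O2", fs = fs,
                       segments = list(rec$data[2, ])),
                  class = "region_signal")
  direct <- coherence(o1, o2)
  expect_equal(within$coherence, direct$coherence, tolerance = 1e-12)
})
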