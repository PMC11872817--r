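test_that("analytic phase advances linearly for a sinusoid", {
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 6 * t)
  ph <- analytic_phase(x, c(4, 8), fs = fs)[[1]]
  up <- unwrap_phase(ph)
  tt <- seq_along(up) / fs
  slope <- coef(lm(up ~ tt))[2]
  expect_equal(unname(slope), 2 * pi * 6, tolerance = 0.01)
})

test_that("sign-flipped signals have opposite phase", {
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 6 * t) + 0.1 * sin(2 * pi * 5 * t)
  p1 <- analytic_phase(x, c(4, 8), fs = fs)[[1]]
  p2 <- analytic_phase(-x, c(4, 8), fs = fs)[[1]]
  dd <- (p1 - p2) %% (2 * pi)
  expect_lt(max(abs(dd - pi)), 1e-6)
})

test_that("white-noise phase is close to uniform on (-pi, pi]", {
  set.seed(401)
  fs <- 200
  ph <- analytic_phase(rnorm(60000), c(4, 8), fs = fs)[[1]]
  ks <- suppressWarnings(
    ks.test(ph, function(q) punif(q, -pi, pi))$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("analytic amplitude tracks the envelope", {
  fs <- 200
  t <- (0:7999) / fs
  x <- 2.5 * sin(2 * pi * 40 * t)
  env <- analytic_amplitude(x, c(35, 45), fs = fs)[[1]]
  expect_equal(mean(env), 2.5, tolerance = 0.03 * 2.5)
  expect_true(all(env >= 0))

  z <- analytic_amplitude(rep(0, 4000), c(35, 45), fs = fs)[[1]]
  expect_lt(max(z), 1e-10)

  a_t <- 1 + 0.8 * sin(2 * pi * 1 * t)
  xm <- a_t * sin(2 * pi * 40 * t)
  em <- analytic_amplitude(xm, c(35, 45), fs = fs)[[1]]
  ntrim <- ceiling(fs / 35)
  a_ref <- a_t[(ntrim + 1):(length(t) - ntrim)]
  expect_gt(cor(em, a_ref), 0.95)
})

test_that("band validation rejects impossible bands", {
  expect_error(analytic_phase(rnorm(1000), c(8, 4), fs = 200), "band")
  expect_error(analytic_phase(rnorm(1000), c(90, 110), fs = 200), "band")
})

test_that("Canolty MI matches closed forms", {
  # envelope A = 1 + cos(phi), phi uniform over whole cycles -> MI = 1/2
  phi <- seq(0, 2 * pi * 40, length.out = 8001)[-8001]
  expect_equal(canolty_mi(1 + cos(phi), phi), 0.5, tolerance = 1e-9)
  # constant envelope, uniform phase -> MI ~ 0
  expect_lt(canolty_mi(rep(1, length(phi)), phi), 3 / sqrt(length(phi)))
  # rotation invariance
  expect_equal(canolty_mi(1 + cos(phi), phi + 1.234),
               canolty_mi(1 + cos(phi), phi), tolerance = 1e-12)
  expect_error(canolty_mi(1:3, 1:4), "lengths differ")
})

test_that("modulation index detects synthetic coupling", {
  fs <- 200
  n <- 12000
  x1 <- pac_component(n, fs, 6, 60, depth = 1, rms = 1, seed = 402)
  mi_c <- modulation_index(x1, x1, c(5, 7), c(55, 65), fs = fs)
  x0 <- pac_component(n, fs, 6, 60, depth = 0, rms = 1, seed = 402)
  mi_0 <- modulation_index(x0, x0, c(5, 7), c(55, 65), fs = fs)
  expect_gt(mi_c, 5 * mi_0)

  # MI scales linearly with the amplitude-source scale
  mi_s <- modulation_index(x1, 3 * x1, c(5, 7), c(55, 65), fs = fs)
  expect_equal(mi_s, 3 * mi_c, tolerance = 1e-9)
})

test_that("comodulogram peaks at the injected coupling cell", {
  fs <- 200
  set.seed(403)
  x <- pac_component(12000, fs, 6, 60, depth = 1, rms = 1) +
    rnorm(12000, sd = 0.2)
  g <- cfc_grid(x, x, fs = fs)
  expect_equal(dim(g$mi), c(10, 14))
  expect_true(all(g$mi >= 0))
  idx <- arrayInd(which.max(g$mi), dim(g$mi))
  expect_equal(g$modulating_centers[idx[1]], 6)
  expect_equal(g$modulated_centers[idx[2]], 60)
})

test_that("comodulogram of a zero amplitude source is identically zero", {
  fs <- 200
  set.seed(404)
  x <- rnorm(4000)
  g <- cfc_grid(x, rep(0, 4000), modulating = c(4, 8),
                modulated = c(40, 60), fs = fs)
  expect_true(all(g$mi < 1e-10))
})

test_that("surrogate z-score separates coupled from uncoupled data", {
  # the phase must wander (not be strictly periodic): circular shifts of a
  # periodic modulation only rotate the coupling phase, and MI is rotation
  # invariant, so surrogates would not destroy it
  set.seed(405)
  fs <- 200
  ph <- analytic_phase(rnorm(12000), c(5, 7), fs = fs)[[1]]
  coupled <- 1 + 0.8 * cos(ph) + abs(rnorm(length(ph), sd = 0.05))
  z1 <- mi_surrogate_z(coupled, ph, n_surrogates = 100, seed = 1)
  expect_gt(z1$z, 5)

  flat <- 1 + abs(rnorm(length(ph), sd = 0.05))
  z0 <- mi_surrogate_z(flat, ph, n_surrogates = 100, seed = 1)
  expect_lt(abs(z0$z), 4)
})
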