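test_that("pink noise has the requested spectral slope and RMS", {
  fs <- 200
  fit_slope <- function(beta, seed) {
    x <- pink_noise(2^15, beta, rms = 10, seed = seed)
    ps <- power_spectrum(x, fs = fs)
    sel <- ps$frequencies >= 1 & ps$frequencies <= 80
    unname(coef(lm(log(ps$power[sel]) ~ log(ps$frequencies[sel])))[2])
  }
  expect_lt(abs(fit_slope(0, 601)), 0.15)
  expect_lt(abs(fit_slope(1, 602) + 1), 0.15)
  expect_equal(sd(pink_noise(5000, 1, rms = 7, seed = 603)), 7,
               tolerance = 1e-6)
  expect_identical(pink_noise(1000, 1, 1, seed = 604),
                   pink_noise(1000, 1, 1, seed = 604))
  expect_error(pink_noise(1000, beta = 3), "beta")
})

test_that("coupling depth orders the modulation index", {
  fs <- 200
  mi_at <- function(depth) {
    x <- pac_component(12000, fs, 6, 60, depth = depth, rms = 1, seed = 605)
    modulation_index(x, x, c(5, 7), c(55, 65), fs = fs)
  }
  expect_gt(mi_at(0.8), mi_at(0.2))
  expect_gt(mi_at(1), 3 * mi_at(0))
  expect_error(pac_component(1000, fs, 60, 6), "f_phase < f_amp")
  expect_error(pac_component(1000, fs, 6, 60, depth = 2), "depth")
})

test_that("subject simulation is deterministic and montage-shaped", {
  cfg <- fast_cohort_config(seed = 606)
  a <- simulate_subject(cfg, 3, "pre")
  b <- simulate_subject(cfg, 3, "pre")
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(21, 6 * 200))
  expect_equal(a$channel_labels, standard_montage())
  # pre and post differ (different noise realizations) under a null config
  p <- simulate_subject(cfg, 3, "post")
  expect_false(identical(a$data, p$data))
})

test_that("a planted power effect is realized at the configured magnitude", {
  eff <- list(list(kind = "power", region = "occipital",
                   band = "beta_gamma", multiplier = 1.3))
  cfg <- cohort_config(n_subjects = 10, duration_s = 20, seed = 607,
                       effects = eff)
  ratios <- vapply(1:10, function(i) {
    pre <- simulate_subject(cfg, i, "pre")
    post <- simulate_subject(cfg, i, "post")
    bp <- function(rec) {
      sp <- channel_spectra(rec)
      band_power(sp, default_regions(), "occipital", "beta_gamma")
    }
    bp(post) / bp(pre)
  }, numeric(1))
  expect_gt(mean(ratios), 1.15)
  expect_lt(mean(ratios), 1.45)
})

test_that("cohorts round-trip through disk and manifests", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 5, seed = 608)
  cohort <- simulate_cohort(cfg)
  expect_length(cohort, 4)
  dir <- withr::local_tempdir()
  man_path <- write_cohort(cohort, dir, format = "edf")
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 4)
  rec <- read_recording(man$path[1], fs = man$fs[1],
                        subject_id = man$subject[1],
                        condition = man$condition[1])
  src <- cohort[[paste0(man$subject[1], "_", man$condition[1])]]
  qstep <- max(abs(src$data)) * 2 / 65535
  expect_lt(max(abs(rec$data[, 1:1000] - src$data[, 1:1000])), qstep)

  expect_error(write_cohort(cohort, file.path(dir, "missing_subdir")),
               "directory")
})

test_that("delimited cohorts round-trip exactly", {
  cfg <- cohort_config(n_subjects = 2, duration_s = 5, seed = 609)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  man_path <- write_cohort(cohort, dir, format = "delimited")
  man <- read_manifest(man_path)
  rec <- read_recording(man$path[3], fs = man$fs[3],
                        subject_id = man$subject[3],
                        condition = man$condition[3])
  src <- cohort[[paste0(man$subject[3], "_", man$condition[3])]]
  expect_equal(rec$data, src$data, tolerance = 1e-6, ignore_attr = TRUE)
})
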