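test_that("signed-rank Z reproduces the closed-form worked examples", {
  # n = 10, no ties, negative-rank sum 3: |Z| = 24.5/sqrt(96.25) = 2.4973
  pre <- rep(0, 10)
  post <- c(10, 20, 30, 40, 50, 60, 70, 7, 5, -9)  # |d| ranks: -9 has rank 3
  wt <- wilcoxon_signed_rank(pre, post)
  expect_equal(wt$W, 3)
  expect_equal(abs(wt$Z), 2.4973, tolerance = 5e-5)
  expect_equal(wt$Z, -2.4973, tolerance = 5e-5)  # increase -> negative Z
  expect_lt(abs(wt$p - 0.0125), 1e-4)

  # uniform increase: W = 0; all |d| tie completely, so the tie-corrected
  # variance collapses the test to the sign-test limit |Z| = sqrt(10)
  wt2 <- wilcoxon_signed_rank(1:10, 1:10 + 1)
  expect_equal(wt2$W, 0)
  expect_equal(abs(wt2$Z), sqrt(10), tolerance = 1e-9)
  ref <- suppressWarnings(wilcox.test(1:10 + 1, 1:10, paired = TRUE,
                                      exact = FALSE, correct = FALSE))
  expect_equal(wt2$p, ref$p.value, tolerance = 1e-10)
})

test_that("normal-approximation p agrees with stats::wilcox.test", {
  set.seed(501)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    pre <- rnorm(n); post <- rnorm(n, mean = 0.3)
    wt <- wilcoxon_signed_rank(pre, post)
    ref <- suppressWarnings(
      wilcox.test(post, pre, paired = TRUE, exact = FALSE, correct = FALSE))
    expect_equal(wt$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("approximate p tracks the exhaustive sign-permutation oracle", {
  set.seed(502)
  for (i in 1:25) {
    d <- round(rnorm(8), 3)
    d <- d[d != 0]
    if (length(d) < 8) next
    wt <- wilcoxon_signed_rank(rep(0, 8), d)
    expect_lt(abs(wt$p - exact_signed_rank_p(d)), 0.03)
  }
})

test_that("swapping conditions flips Z and preserves W, p and |r|", {
  set.seed(503)
  pre <- rnorm(12); post <- rnorm(12, 0.5)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$W, b$W)
  expect_equal(a$p, b$p)
  expect_equal(abs(effect_size_r(a$Z, 12)), abs(effect_size_r(b$Z, 12)))
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "all differences are zero")
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "lengths differ")
  expect_error(wilcoxon_signed_rank(1, 2), "at least 2")
})

test_that("effect size r reproduces the published magnitudes", {
  expect_equal(round(abs(effect_size_r(-2.4973, 10)), 4), 0.7897)
  expect_equal(round(abs(effect_size_r(2.0896, 10)), 4), 0.6608)
  expect_equal(effect_size_r(0, 7), 0)
  expect_error(effect_size_r(1.5, 0), "n must be")
})

test_that("normality screen separates normal from skewed differences", {
  set.seed(504)
  ok <- normality_screen(rnorm(1000))
  expect_gt(ok$p, 0.05)
  bad <- normality_screen(rexp(1000))
  expect_lt(bad$p, 0.001)
  expect_error(normality_screen(rep(2, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "at least 3")
})

test_that("compare_all builds one tested row per feature", {
  set.seed(505)
  subs <- sprintf("s%02d", 1:10)
  mk <- function(cond, shift) {
    expand.grid(subject_id = subs,
                feature_kind = "power",
                region_or_pair = c("occipital", "temporal"),
                band = c("alpha", "beta"),
                stringsAsFactors = FALSE) |>
      transform(condition = cond,
                value = rnorm(40) + shift)
  }
  pre <- mk("pre", 0)
  post <- mk("post", 0)
  post$value[post$region_or_pair == "occipital" & post$band == "alpha"] <-
    post$value[post$region_or_pair == "occipital" & post$band == "alpha"] + 5
  res <- compare_all(pre, post)
  expect_equal(nrow(res), 4)
  hit <- res[res$region_or_pair == "occipital" & res$band == "alpha", ]
  expect_true(hit$significant)
  expect_lt(hit$p, 0.01)
  # |r| = |Z|/sqrt(10) identity on every emitted row
  expect_equal(res$abs_r, abs(res$Z) / sqrt(10), tolerance = 1e-12)
})

test_that("identical tables are reported as non-testable, not significant", {
  subs <- sprintf("s%02d", 1:6)
  tab <- data.frame(subject_id = rep(subs, 2),
                    condition = rep(c("pre", "post"), each = 6),
                    feature_kind = "entropy", region_or_pair = "all",
                    band = "broadband", value = rep(1:6, 2))
  res <- compare_all(tab)
  expect_false(res$testable)
  expect_false(res$significant)
  expect_true(is.na(res$p))
})

test_that("subject mismatches are reported by name", {
  tab <- data.frame(subject_id = c("s01", "s02", "s01"),
                    condition = c("pre", "pre", "post"),
                    feature_kind = "power", region_or_pair = "occipital",
                    band = "alpha", value = 1:3)
  expect_error(compare_all(tab), "s02")
})

test_that("BH correction is applied only when requested", {
  set.seed(506)
  subs <- sprintf("s%02d", 1:10)
  tab <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(bn)
    data.frame(subject_id = rep(subs, 2),
               condition = rep(c("pre", "post"), each = 10),
               feature_kind = "power", region_or_pair = "r", band = bn,
               value = rnorm(20))))
  res0 <- compare_all(tab)
  expect_null(res0$p_adj)
  res1 <- compare_all(tab, fdr = TRUE)
  expect_true(all(res1$p_adj >= res1$p - 1e-12))
})

test_that("cfc significance masks mirror the grid layout", {
  res <- data.frame(feature_kind = "cfc",
                    region_or_pair = "fronto_polar",
                    band = c("4:40", "8:60"),
                    significant = c(TRUE, FALSE))
  mask <- cfc_significance_mask(res, "fronto_polar",
                                modulating = c(4, 8),
                                modulated = c(40, 60))
  expect_equal(mask, matrix(c(1L, 0L, 0L, 0L), 2, 2,
                            dimnames = list(c(4, 8), c(40, 60))))
})
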