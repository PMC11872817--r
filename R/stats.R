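# Paired pre/post group statistics: Wilcoxon signed-rank with
# normal-approximation Z (no continuity correction), effect size r = Z/sqrt(n),
# Kolmogorov-Smirnov normality screen, and the all-features comparison table.

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Differences are `post - pre`; zero differences are dropped (Wilcoxon's
#' method) and ties in `|diff|` receive midranks. With `m` nonzero pairs, `W`
#' is the smaller of the positive- and negative-rank sums and
#'
#'   `Z = (W- - m(m+1)/4) / sqrt(m(m+1)(2m+1)/24 - tie_term/48)`
#'
#' where `W-` is the negative-rank sum, so that a predominant increase
#' (post > pre) yields a negative `Z` and a predominant decrease a positive
#' one. No continuity correction is applied; the two-sided p-value comes from
#' the normal tail.
#'
#' @param pre,post numeric vectors of equal length (>= 2 pairs).
#' @return List: `n` (pairs supplied), `m` (nonzero pairs), `W`, `Z`, `p`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post lengths differ")
  if (length(pre) < 2) stop("need at least 2 pairs")
  d <- post - pre
  nz <- d != 0
  m <- sum(nz)
  if (m == 0) stop("degenerate data: all differences are zero")
  d <- d[nz]
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  mu <- m * (m + 1) / 4
  tie_counts <- table(r)
  tie_term <- sum(tie_counts^3 - tie_counts)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - tie_term / 48
  if (sigma2 <= 0) stop("degenerate data: zero rank variance")
  Z <- (w_neg - mu) / sqrt(sigma2)
  list(n = length(post), m = m, W = min(w_pos, w_neg), Z = Z,
       p = 2 * stats::pnorm(-abs(Z)))
}

#' Effect size r = Z / sqrt(n)
#'
#' Rank-test effect size: the approximate test statistic divided by the
#' square root of the number of pairs (all supplied pairs, including zero
#' differences). Roughly, |r| of 0.1/0.3/0.5 are small/medium/large.
#'
#' @param Z approximate test statistic.
#' @param n number of pairs (>= 1).
#' @return Scalar r (signed; use `abs()` for magnitude tables).
#' @export
effect_size_r <- function(Z, n) {
  if (n < 1) stop("n must be >= 1")
  Z / sqrt(n)
}

#' Kolmogorov-Smirnov normality screen of paired differences
#'
#' One-sample KS statistic of the standardized differences against the
#' standard normal. Reported alongside the Wilcoxon results; it does not gate
#' the nonparametric test.
#'
#' @param diffs numeric vector of paired differences (n >= 3, not constant).
#' @return List with `statistic` and `p`.
#' @export
normality_screen <- function(diffs) {
  if (length(diffs) < 3) stop("need at least 3 differences")
  s <- stats::sd(diffs)
  if (!is.finite(s) || s == 0) stop("degenerate data: constant differences")
  z <- (diffs - mean(diffs)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Compare every feature between pre and post
#'
#' Joins the two feature tables on (subject, feature), runs the paired
#' Wilcoxon test per feature and attaches the effect size and significance /
#' trend flags. Features whose differences are all zero are reported as
#' non-testable rather than dropped. No multiple-comparison correction is
#' applied by default; `fdr = TRUE` adds Benjamini-Hochberg adjusted
#' p-values and bases the significance flag on them.
#'
#' @param features `data.frame` with columns `subject_id`, `condition`
#'   (`pre`/`post`), `feature_kind`, `region_or_pair`, `band`, `value` — or
#'   two such tables given as `features` (pre) and `features_post`.
#' @param features_post optional second table holding the post rows.
#' @param alpha significance level (default 0.05).
#' @param trend_bound upper bound of the trend band (default 0.10).
#' @param fdr apply Benjamini-Hochberg correction (default `FALSE`).
#' @return `data.frame`, one row per feature: ids, `n`, `W`, `Z`, `p`,
#'   `r`, `abs_r`, `significant`, `trend`, `testable`, and `p_adj` when
#'   `fdr = TRUE`.
#' @export
compare_all <- function(features, features_post = NULL, alpha = 0.05,
                        trend_bound = 0.10, fdr = FALSE) {
  if (!is.null(features_post)) features <- rbind(features, features_post)
  need <- c("subject_id", "condition", "feature_kind", "region_or_pair",
            "band", "value")
  if (!all(need %in% names(features)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  pre <- features[features$condition == "pre", ]
  post <- features[features$condition == "post", ]
  subj_pre <- sort(unique(pre$subject_id))
  subj_post <- sort(unique(post$subject_id))
  if (!identical(subj_pre, subj_post))
    stop("subject sets differ between conditions; missing: ",
         paste(c(setdiff(subj_pre, subj_post), setdiff(subj_post, subj_pre)),
               collapse = ", "))
  key <- function(df) paste(df$feature_kind, df$region_or_pair, df$band,
                            sep = "\r")
  pre$.key <- key(pre); post$.key <- key(post)
  feats <- unique(pre[, c("feature_kind", "region_or_pair", "band", ".key")])
  rows <- lapply(seq_len(nrow(feats)), function(i) {
    k <- feats$.key[i]
    a <- pre[pre$.key == k, ]
    b <- post[post$.key == k, ]
    a <- a[order(a$subject_id), ]
    b <- b[order(b$subject_id), ]
    if (!identical(a$subject_id, b$subject_id))
      stop("subject mismatch for feature ", gsub("\r", "/", k))
    out <- data.frame(feature_kind = feats$feature_kind[i],
                      region_or_pair = feats$region_or_pair[i],
                      band = feats$band[i],
                      n = nrow(a), W = NA_real_, Z = NA_real_, p = NA_real_,
                      r = NA_real_, abs_r = NA_real_,
                      significant = FALSE, trend = FALSE, testable = FALSE)
    if (any(b$value != a$value)) {
      wt <- wilcoxon_signed_rank(a$value, b$value)
      out$W <- wt$W; out$Z <- wt$Z; out$p <- wt$p
      out$r <- effect_size_r(wt$Z, wt$n)
      out$abs_r <- abs(out$r)
      out$testable <- TRUE
    }
    out
  })
  res <- do.call(rbind, rows)
  p_eff <- res$p
  if (fdr) {
    res$p_adj <- NA_real_
    res$p_adj[res$testable] <- stats::p.adjust(res$p[res$testable], "BH")
    p_eff <- res$p_adj
  }
  res$significant <- res$testable & !is.na(p_eff) & p_eff < alpha
  res$trend <- res$testable & !is.na(p_eff) & p_eff >= alpha &
    p_eff < trend_bound
  rownames(res) <- NULL
  res
}

#' Significance mask for a comodulogram
#'
#' Extracts the cfc rows of a [compare_all()] result for one region pair and
#' arranges the significance flags as a 0/1 matrix parallel to the MI grid
#' (modulating x modulated), mirroring the blacked-out cells of a
#' comodulogram significance figure.
#'
#' @param results `data.frame` from [compare_all()].
#' @param pair_label the `region_or_pair` label of the grid.
#' @param modulating,modulated the grid center frequencies.
#' @return Integer 0/1 matrix, modulating x modulated.
#' @export
cfc_significance_mask <- function(results, pair_label,
                                  modulating = 1:10,
                                  modulated = seq(20, 85, by = 5)) {
  sub <- results[results$feature_kind == "cfc" &
                   results$region_or_pair == pair_label, ]
  mask <- matrix(0L, length(modulating), length(modulated),
                 dimnames = list(modulating, modulated))
  for (i in seq_len(nrow(sub))) {
    cell <- strsplit(sub$band[i], ":", fixed = TRUE)[[1]]
    fi <- match(as.numeric(cell[1]), modulating)
    fj <- match(as.numeric(cell[2]), modulated)
    if (!is.na(fi) && !is.na(fj) && isTRUE(sub$significant[i]))
      mask[fi, fj] <- 1L
  }
  mask
}
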