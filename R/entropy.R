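# Binned-variance Tsallis-entropy estimator.
#
# For one interval length L the series is cut into M = floor(N/L) consecutive
# non-overlapping intervals (remainder samples dropped) and the estimator is
#
#   H(L) = 1 - sum_j Var_j / (M * sigma2)
#
# with Var_j the population variance of interval j and sigma2 the population
# variance of the full series. H is near 0 for stationary noise (within-
# interval variance ~ total variance) and approaches 1 when the variance is
# carried by slow structure between intervals. The reported entropy is the
# mean of H(L) over 100 equally spaced interval lengths in [1, 500].

#' Tsallis entropy at one interval length
#'
#' @param x numeric series (length >= `L`).
#' @param L interval length in samples (>= 1).
#' @return Scalar estimate; 1 when `L == 1` (single-sample intervals have
#'   zero variance).
#' @export
entropy_at_length <- function(x, L) {
  n <- length(x)
  L <- as.integer(L)
  if (L < 1 || L > n) stop("L must be in [1, length(x)]; got ", L)
  mu <- mean(x)
  sigma2 <- mean((x - mu)^2)
  if (sigma2 <= 0) stop("entropy undefined for a constant series")
  if (L == 1L) return(1)   # single-sample intervals have zero variance
  M <- n %/% L
  used <- x[seq_len(M * L)]
  # interval sums via cumsum: O(N) for any L
  cs <- c(0, cumsum(used))
  cs2 <- c(0, cumsum(used^2))
  idx <- (0:M) * L
  s <- diff(cs[idx + 1])
  ss <- diff(cs2[idx + 1])
  vars <- (ss - s^2 / L) / L          # population variance per interval
  1 - sum(vars) / (M * sigma2)
}

#' Interval-length grid for the entropy estimator
#'
#' 100 equally spaced lengths between 1 and 500 samples, rounded to the
#' nearest integer. Duplicates introduced by rounding are kept so the final
#' average is always over exactly `n` values.
#'
#' @param n number of lengths (default 100).
#' @param min_len,max_len grid end points in samples (defaults 1 and 500).
#' @return Integer vector of length `n`.
#' @export
te_lengths <- function(n = 100, min_len = 1, max_len = 500) {
  as.integer(round(seq(min_len, max_len, length.out = n)))
}

#' Tsallis entropy of a series
#'
#' Mean of [entropy_at_length()] over the interval-length grid (computed
#' with a single shared cumulative-sum pass). The estimate is invariant to
#' amplitude scaling of the input.
#'
#' @param x numeric series; must be at least `max(lengths)` samples long.
#' @param lengths integer interval lengths (default [te_lengths()]).
#' @return Scalar entropy estimate.
#' @export
tsallis_entropy <- function(x, lengths = te_lengths()) {
  n <- length(x)
  lengths <- as.integer(lengths)
  if (n < max(lengths))
    stop("series shorter (", n, ") than the largest interval length (",
         max(lengths), ")")
  if (any(lengths < 1)) stop("interval lengths must be >= 1")
  mean(entropy_profile_cpp(as.numeric(x), lengths))
}

#' Per-channel, per-region entropy table
#'
#' Tsallis entropy per channel on the concatenated retained samples (segments
#' shorter than the largest interval length are excluded first), then region
#' values as the mean of member-channel entropies and an `"all"` row as the
#' mean over every channel.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param regions named region list.
#' @param lengths interval-length grid.
#' @return `data.frame` with columns `scope_type` (`channel` / `region` /
#'   `all`), `scope` and `te`.
#' @export
entropy_table <- function(rec, regions = default_regions(),
                          lengths = te_lengths()) {
  min_seg <- max(lengths)
  ch_te <- vapply(rec$channel_labels, function(ch) {
    segs <- segment_data(rec, ch)
    segs <- segs[vapply(segs, length, integer(1)) >= min_seg]
    if (length(segs) == 0)
      stop("channel ", ch, ": no retained segment of at least ",
           min_seg, " samples")
    tsallis_entropy(unlist(segs, use.names = FALSE), lengths)
  }, numeric(1))
  reg_rows <- lapply(names(regions), function(rn) {
    chans <- intersect(normalize_channel_labels(regions[[rn]]),
                       rec$channel_labels)
    if (length(chans) == 0) return(NULL)
    data.frame(scope_type = "region", scope = rn,
               te = mean(ch_te[chans]))
  })
  rbind(
    data.frame(scope_type = "channel", scope = names(ch_te),
               te = unname(ch_te)),
    do.call(rbind, reg_rows),
    data.frame(scope_type = "all", scope = "all", te = mean(ch_te))
  )
}
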