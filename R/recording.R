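#' Multichannel EEG recording
#'
#' Container for one subject/condition resting-state EEG recording: a
#' channels-by-samples matrix in microvolts with 10/20 channel labels, the
#' sampling rate, and an optional list of retained (artifact-free) segments.
#' Sample indices are 0-based and segments are half-open `[start, end)`.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per row of `data`.
#'   Normalized via [normalize_channel_labels()].
#' @param subject_id subject identifier (coerced to character).
#' @param condition `"pre"` or `"post"`.
#' @param segments optional list of `c(start, end)` 0-based half-open sample
#'   intervals of retained data; defaults to the whole recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = "s01", condition = c("pre", "post"),
                          segments = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  channel_labels <- normalize_channel_labels(as.character(channel_labels))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") != number of data rows (", nrow(data), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]),
               collapse = ", "))
  n <- ncol(data)
  if (is.null(segments)) segments <- list(c(0L, n))
  segments <- validate_segments(segments, n)
  rownames(data) <- channel_labels
  structure(
    list(subject_id = as.character(subject_id), condition = condition,
         fs = fs, channel_labels = channel_labels, data = data,
         segments = segments),
    class = "eeg_recording")
}

validate_segments <- function(segments, n_samples) {
  if (!is.list(segments) || length(segments) == 0)
    stop("segments must be a non-empty list of c(start, end)")
  segments <- lapply(segments, function(s) {
    s <- as.integer(s)
    if (length(s) != 2 || s[1] < 0 || s[2] > n_samples || s[1] >= s[2])
      stop("invalid segment [", s[1], ", ", s[2], ") for n = ", n_samples)
    s
  })
  starts <- vapply(segments, `[`, integer(1), 1)
  ends <- vapply(segments, `[`, integer(1), 2)
  if (is.unsorted(starts, strictly = TRUE) || any(starts[-1] < ends[-length(ends)]))
    stop("segments must be ascending and non-overlapping")
  segments
}

#' @export
print.eeg_recording <- function(x, ...) {
  ret <- sum(vapply(x$segments, function(s) s[2] - s[1], integer(1)))
  cat("<eeg_recording> subject", x$subject_id, "condition", x$condition, "\n")
  cat(" ", nrow(x$data), "channels x", ncol(x$data), "samples @", x$fs, "Hz\n")
  cat("  retained:", length(x$segments), "segment(s),",
      sprintf("%.1f s of %.1f s", ret / x$fs, ncol(x$data) / x$fs), "\n")
  invisible(x)
}

n_retained <- function(rec) {
  sum(vapply(rec$segments, function(s) s[2] - s[1], integer(1)))
}

# Per-channel list of retained chunks (each a numeric vector), in order.
segment_data <- function(rec, channel) {
  row <- rec$data[channel, ]
  lapply(rec$segments, function(s) row[(s[1] + 1):s[2]])
}

#' Region-average signal
#'
#' Sample-wise mean across the available channels of a region, restricted to
#' the retained segments. Used as the input for coherence and
#' cross-frequency-coupling analysis. The per-segment structure is preserved
#' so that downstream windowing never crosses a rejection gap.
#'
#' @param rec an [eeg_recording()].
#' @param regions named list mapping region name to channel labels.
#' @param name region name to extract.
#' @return An object of class `region_signal` with fields `region`, `fs` and
#'   `segments` (list of numeric vectors, one per retained segment).
#' @export
region_signal <- function(rec, regions = default_regions(), name) {
  validate_regions(regions)
  if (!name %in% names(regions)) stop("unknown region '", name, "'")
  wanted <- normalize_channel_labels(regions[[name]])
  present <- intersect(wanted, rec$channel_labels)
  if (length(present) == 0)
    stop("region '", name, "': none of its channels present (missing: ",
         paste(wanted, collapse = ", "), ")")
  segs <- lapply(rec$segments, function(s) {
    block <- rec$data[present, (s[1] + 1):s[2], drop = FALSE]
    colMeans(block)
  })
  structure(list(region = name, fs = rec$fs, segments = segs),
            class = "region_signal")
}

as_region_signal <- function(x, fs, name = "signal") {
  if (inherits(x, "region_signal")) return(x)
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs required (positive scalar) for a bare numeric signal")
  structure(list(region = name, fs = fs, segments = list(as.numeric(x))),
            class = "region_signal")
}
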