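# Welch power spectra, region band power and magnitude-squared coherence.

hanning_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Hanning-windowed FFTs of all Welch windows of a region_signal, batched
# with mvfft. Returns the nf x K complex matrix plus grid/scale metadata.
welch_fft <- function(sig, window_len = 512, overlap = 0.5) {
  fs <- sig$fs
  if (window_len < 8) stop("window_len too small")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  w <- hanning_window(window_len)
  U <- sum(w^2)
  nf <- window_len %/% 2 + 1
  blocks <- list()
  for (xs in sig$segments) {
    if (length(xs) < window_len) next   # short segments are skipped
    starts <- seq(1L, length(xs) - window_len + 1L, by = step)
    win <- vapply(starts, function(s0) xs[s0:(s0 + window_len - 1L)] * w,
                  numeric(window_len))
    blocks[[length(blocks) + 1]] <- stats::mvfft(win)[1:nf, , drop = FALSE]
  }
  if (length(blocks) == 0L)
    stop("no retained segment is at least one window (", window_len,
         " samples) long")
  F <- do.call(cbind, blocks)
  scale <- rep(2, nf) / (fs * U)
  scale[1] <- 1 / (fs * U)
  if (window_len %% 2 == 0) scale[nf] <- 1 / (fs * U)
  list(F = F, k = ncol(F), scale = scale,
       frequencies = (0:(nf - 1)) * fs / window_len)
}

# Welch cross-spectral density from two batched FFT sets (pass the same set
# twice for an auto-spectrum). One-sided, window-power normalised so that
# sum(psd) * df ~ variance.
welch_csd <- function(xsig, ysig, window_len = 512, overlap = 0.5) {
  stopifnot(xsig$fs == ysig$fs, length(xsig$segments) == length(ysig$segments))
  fx <- welch_fft(xsig, window_len, overlap)
  fy <- if (identical(xsig, ysig)) fx else welch_fft(ysig, window_len, overlap)
  if (fx$k != fy$k) stop("segments not aligned")
  list(frequencies = fx$frequencies,
       csd = rowMeans(fx$F * Conj(fy$F)) * fx$scale,
       n_segments = fx$k)
}

#' Welch power spectrum
#'
#' Average of Hanning-windowed periodograms over sliding windows within each
#' retained segment (segments shorter than one window are skipped). With the
#' defaults of a 512-sample window at 200 Hz the frequency resolution is
#' 200/512 = 0.390625 Hz. One-sided density in signal-units^2/Hz, normalised
#' so that the integral over frequency approximates the signal variance.
#'
#' @param x a `region_signal`, or a plain numeric vector (then `fs` must be
#'   given).
#' @param window_len window length in samples (default 512).
#' @param overlap fractional window overlap in `[0, 1)` (default 0.5).
#' @param fs sampling rate in Hz, required when `x` is a bare vector.
#' @return Object of class `power_spectrum`: `frequencies`, `power`,
#'   `n_segments` (number of averaged windows).
#' @export
power_spectrum <- function(x, window_len = 512, overlap = 0.5, fs = NULL) {
  if (!inherits(x, "region_signal")) {
    if (is.null(fs)) stop("fs required for a bare numeric signal")
    x <- as_region_signal(x, fs)
  }
  est <- welch_csd(x, x, window_len, overlap)
  structure(list(frequencies = est$frequencies,
                 power = pmax(Re(est$csd), 0),
                 n_segments = est$n_segments,
                 fs = x$fs, window_len = window_len),
            class = "power_spectrum")
}

band_bins <- function(frequencies, band) {
  idx <- which(frequencies >= band[1] & frequencies < band[2])
  if (length(idx) == 0)
    stop("band [", band[1], ", ", band[2], ") Hz contains no frequency bins")
  idx
}

resolve_band <- function(band, bands = default_bands()) {
  if (is.character(band)) {
    if (!band %in% names(bands)) stop("unknown band '", band, "'")
    bands[[band]]
  } else {
    validate_bands(list(b = band))
    band
  }
}

#' Per-channel power spectra of a recording
#'
#' @param rec an [eeg_recording()].
#' @param window_len,overlap passed to [power_spectrum()].
#' @return Named list of `power_spectrum` objects, one per channel.
#' @export
channel_spectra <- function(rec, window_len = 512, overlap = 0.5) {
  out <- lapply(rec$channel_labels, function(ch) {
    sig <- structure(list(region = ch, fs = rec$fs,
                          segments = segment_data(rec, ch)),
                     class = "region_signal")
    power_spectrum(sig, window_len, overlap)
  })
  names(out) <- rec$channel_labels
  out
}

#' Region band power
#'
#' Mean over the region's available channels of the mean spectral power
#' across the frequency bins falling in the half-open band `[low, high)`.
#'
#' @param spectra named list of per-channel `power_spectrum` objects, as from
#'   [channel_spectra()].
#' @param regions named list of regions.
#' @param region region name.
#' @param band band name (resolved in `bands`) or `c(low, high)` Hz.
#' @param bands named band list used to resolve `band` by name.
#' @return Scalar band power.
#' @export
band_power <- function(spectra, regions = default_regions(), region, band,
                       bands = default_bands()) {
  if (!region %in% names(regions)) stop("unknown region '", region, "'")
  b <- resolve_band(band, bands)
  chans <- intersect(normalize_channel_labels(regions[[region]]),
                     names(spectra))
  if (length(chans) == 0)
    stop("region '", region, "': no channel spectra available")
  vals <- vapply(chans, function(ch) {
    sp <- spectra[[ch]]
    mean(sp$power[band_bins(sp$frequencies, b)])
  }, numeric(1))
  mean(vals)
}

#' Magnitude-squared coherence between two signals
#'
#' Welch estimate `|Sxy|^2 / (Sxx * Syy)` on the same frequency grid as
#' [power_spectrum()], with cross- and auto-spectra averaged over the same
#' windows. At least two windows are required (a single-window estimate is
#' identically 1).
#'
#' @param x,y `region_signal` objects with equal sampling rate and aligned
#'   segments, or bare numeric vectors (then `fs` is required).
#' @param window_len,overlap Welch parameters.
#' @param fs sampling rate for bare vectors.
#' @return Object of class `coherence_pair`: `x`, `y` (names),
#'   `frequencies`, `coherence`, `n_segments`.
#' @export
coherence <- function(x, y, window_len = 512, overlap = 0.5, fs = NULL) {
  if (!inherits(x, "region_signal")) x <- as_region_signal(x, fs, "x")
  if (!inherits(y, "region_signal")) y <- as_region_signal(y, fs, "y")
  if (x$fs != y$fs) stop("sampling rates differ")
  fx <- welch_fft(x, window_len, overlap)
  fy <- welch_fft(y, window_len, overlap)
  coherence_from_fft(fx, fy, x$region, y$region)
}

coherence_from_fft <- function(fx, fy, xname, yname) {
  if (fx$k != fy$k) stop("segments not aligned")
  if (fx$k < 2)
    stop("coherence needs at least 2 windows (got ", fx$k, ")")
  sxy <- rowMeans(fx$F * Conj(fy$F))
  sxx <- rowMeans(Mod(fx$F)^2)
  syy <- rowMeans(Mod(fy$F)^2)
  den <- sxx * syy
  coh <- ifelse(den > 0, Mod(sxy)^2 / den, 0)
  structure(list(x = xname, y = yname,
                 frequencies = fx$frequencies,
                 coherence = pmin(pmax(coh, 0), 1),
                 n_segments = fx$k),
            class = "coherence_pair")
}

#' Band-average coherence
#'
#' Mean coherence over the frequency bins in the half-open band.
#'
#' @param pair a `coherence_pair` from [coherence()].
#' @param band band name or `c(low, high)` Hz.
#' @param bands named band list used to resolve `band` by name.
#' @return Scalar in `[0, 1]`.
#' @export
band_coherence <- function(pair, band, bands = default_bands()) {
  b <- resolve_band(band, bands)
  mean(pair$coherence[band_bins(pair$frequencies, b)])
}

#' Coherence for a region or region pair
#'
#' For a between-region pair, the coherence of the two region-average
#' signals. For a single region ("within-region coherence"), the mean of the
#' coherence spectra over all unordered channel pairs of the region (for a
#' two-channel region this is simply the coherence of its two channels).
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param pair character vector of one region name (within) or two (between).
#' @param regions named region list.
#' @param window_len,overlap Welch parameters.
#' @return A `coherence_pair` object.
#' @export
region_coherence <- function(rec, pair, regions = default_regions(),
                             window_len = 512, overlap = 0.5) {
  if (length(pair) == 2) {
    x <- region_signal(rec, regions, pair[1])
    y <- region_signal(rec, regions, pair[2])
    return(coherence(x, y, window_len, overlap))
  }
  stopifnot(length(pair) == 1)
  chans <- intersect(normalize_channel_labels(regions[[pair]]),
                     rec$channel_labels)
  if (length(chans) < 2)
    stop("within-region coherence for '", pair,
         "' needs >= 2 present channels")
  combos <- utils::combn(chans, 2, simplify = FALSE)
  ffts <- lapply(chans, function(ch)
    welch_fft(structure(list(region = ch, fs = rec$fs,
                             segments = segment_data(rec, ch)),
                        class = "region_signal"),
              window_len, overlap))
  names(ffts) <- chans
  acc <- NULL
  for (cb in combos) {
    cp <- coherence_from_fft(ffts[[cb[1]]], ffts[[cb[2]]], cb[1], cb[2])
    if (is.null(acc)) {
      acc <- cp
    } else {
      acc$coherence <- acc$coherence + cp$coherence
    }
  }
  acc$coherence <- acc$coherence / length(combos)
  acc$x <- pair; acc$y <- pair
  acc
}

pair_label <- function(pair) paste(pair, collapse = "~")
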