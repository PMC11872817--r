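# Phase-amplitude cross-frequency coupling: Canolty modulation index and
# comodulograms over modulating [1, 10] Hz x modulated [20, 85] Hz.

bandpass_segments <- function(sig, band, fs, order = 2) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("band [", band[1], ", ", band[2], ") must lie inside (0, fs/2)")
  flt <- butter_design(order, band, fs, "pass")
  lapply(sig, function(x) filtfilt_sos(x, flt$sos))
}

edge_trim <- function(band, fs) as.integer(ceiling(fs / band[1]))

apply_trim <- function(segs, ntrim) {
  out <- lapply(segs, function(x) {
    if (length(x) <= 2 * ntrim) return(NULL)
    x[(ntrim + 1):(length(x) - ntrim)]
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Instantaneous phase in a band
#'
#' Zero-phase band-pass followed by the analytic-signal phase, computed per
#' retained segment with one cycle of the band's low edge trimmed from each
#' segment end to suppress edge artifacts.
#'
#' @param x `region_signal` or numeric vector (then `fs` required).
#' @param band `c(low, high)` Hz inside `(0, fs/2)`.
#' @param fs sampling rate for bare vectors.
#' @param order Butterworth prototype order of the band-pass (default 2,
#'   i.e. a 4th-order digital filter).
#' @return List of phase vectors in radians, one per surviving segment.
#' @export
analytic_phase <- function(x, band, fs = NULL, order = 2) {
  if (!inherits(x, "region_signal")) x <- as_region_signal(x, fs)
  bp <- bandpass_segments(x$segments, band, x$fs, order)
  apply_trim(lapply(bp, function(s) Arg(hilbert_analytic(s))),
             edge_trim(band, x$fs))
}

#' Instantaneous amplitude envelope in a band
#'
#' As [analytic_phase()] but returning the analytic-signal modulus.
#'
#' @inheritParams analytic_phase
#' @return List of non-negative envelope vectors, one per surviving segment.
#' @export
analytic_amplitude <- function(x, band, fs = NULL, order = 2) {
  if (!inherits(x, "region_signal")) x <- as_region_signal(x, fs)
  bp <- bandpass_segments(x$segments, band, x$fs, order)
  apply_trim(lapply(bp, function(s) Mod(hilbert_analytic(s))),
             edge_trim(band, x$fs))
}

#' Canolty modulation index from envelope and phase series
#'
#' The magnitude of the time-average of the envelope-weighted unit phasor,
#' `|mean(A * exp(i * phi))|`. This is the estimator core; use
#' [modulation_index()] to go from raw signals to an MI value.
#'
#' @param amplitude non-negative envelope series.
#' @param phase phase series in radians, same length.
#' @return Scalar MI >= 0.
#' @export
canolty_mi <- function(amplitude, phase) {
  if (length(amplitude) != length(phase))
    stop("amplitude and phase lengths differ")
  if (length(amplitude) == 0) stop("empty series")
  Mod(mean(amplitude * exp(1i * phase)))
}

#' Modulation index between two signals
#'
#' Phase is extracted from `phase_sig` in the modulating band `f_mod`,
#' envelope from `amp_sig` in the modulated band `f_car`; both are trimmed by
#' one cycle of the modulating band's low edge so they stay aligned, and
#' segments shorter than three cycles of the modulating low edge are skipped.
#'
#' @param phase_sig,amp_sig `region_signal` objects (or vectors with `fs`)
#'   with aligned segments.
#' @param f_mod modulating band `c(low, high)` Hz.
#' @param f_car modulated band `c(low, high)` Hz.
#' @param fs sampling rate for bare vectors.
#' @return Scalar MI.
#' @export
modulation_index <- function(phase_sig, amp_sig, f_mod, f_car, fs = NULL) {
  if (!inherits(phase_sig, "region_signal"))
    phase_sig <- as_region_signal(phase_sig, fs)
  if (!inherits(amp_sig, "region_signal"))
    amp_sig <- as_region_signal(amp_sig, fs)
  if (phase_sig$fs != amp_sig$fs) stop("sampling rates differ")
  fs <- phase_sig$fs
  ntrim <- edge_trim(f_mod, fs)
  min_len <- as.integer(ceiling(3 * fs / f_mod[1])) + 2L * ntrim
  keep <- vapply(phase_sig$segments, length, integer(1)) >= min_len
  if (!any(keep))
    stop("no segment is at least 3 modulating-band cycles long")
  psub <- structure(list(region = phase_sig$region, fs = fs,
                         segments = phase_sig$segments[keep]),
                    class = "region_signal")
  asub <- structure(list(region = amp_sig$region, fs = fs,
                         segments = amp_sig$segments[keep]),
                    class = "region_signal")
  ph <- bandpass_segments(psub$segments, f_mod, fs)
  am <- bandpass_segments(asub$segments, f_car, fs)
  ph <- apply_trim(lapply(ph, function(s) Arg(hilbert_analytic(s))), ntrim)
  am <- apply_trim(lapply(am, function(s) Mod(hilbert_analytic(s))), ntrim)
  canolty_mi(unlist(am, use.names = FALSE), unlist(ph, use.names = FALSE))
}

#' Comodulogram (modulation-index grid)
#'
#' MI at every (modulating, modulated) center-frequency pair. Default grid:
#' modulating centers 1..10 Hz in 1-Hz steps with +/-1 Hz bands (low edge
#' clipped at 0.5 Hz) and modulated centers 20..85 Hz in 5-Hz steps with
#' +/-10 Hz bands (wide enough to pass the modulation sidebands of any
#' modulating frequency in the 1-10 Hz range). Phase comes from `phase_region`, amplitude from
#' `amp_region`; pass the same signal for within-region coupling.
#'
#' @param phase_region,amp_region `region_signal` objects with aligned
#'   segments (or vectors with `fs`).
#' @param modulating modulating center frequencies in Hz.
#' @param modulated modulated center frequencies in Hz.
#' @param phase_halfwidth,amp_halfwidth half-widths of the bands around each
#'   center (Hz).
#' @param fs sampling rate for bare vectors.
#' @return Object of class `cfc_grid`: `phase_source`, `amp_source`,
#'   `modulating_centers`, `modulated_centers`, and `mi` (modulating x
#'   modulated matrix).
#' @export
cfc_grid <- function(phase_region, amp_region,
                     modulating = 1:10, modulated = seq(20, 85, by = 5),
                     phase_halfwidth = 1, amp_halfwidth = 10, fs = NULL) {
  if (!inherits(phase_region, "region_signal"))
    phase_region <- as_region_signal(phase_region, fs, "phase")
  if (!inherits(amp_region, "region_signal"))
    amp_region <- as_region_signal(amp_region, fs, "amp")
  if (phase_region$fs != amp_region$fs) stop("sampling rates differ")
  fs <- phase_region$fs
  phase_bands <- lapply(modulating, function(f)
    c(max(f - phase_halfwidth, 0.5), f + phase_halfwidth))
  amp_bands <- lapply(modulated, function(f)
    c(f - amp_halfwidth, min(f + amp_halfwidth, fs / 2 * 0.999)))
  # common trim: one cycle of the lowest modulating band edge keeps all
  # phase/envelope series aligned across the grid
  ntrim <- max(vapply(phase_bands, edge_trim, integer(1), fs = fs))
  min_len <- as.integer(ceiling(3 * fs / min(vapply(phase_bands, `[`,
                                                    numeric(1), 1)))) +
    2L * ntrim
  keep <- vapply(phase_region$segments, length, integer(1)) >= min_len
  if (!any(keep)) stop("no segment long enough for the comodulogram")
  pseg <- phase_region$segments[keep]
  aseg <- amp_region$segments[keep]
  phases <- lapply(phase_bands, function(b) {
    bp <- bandpass_segments(pseg, b, fs)
    unlist(apply_trim(lapply(bp, function(s) Arg(hilbert_analytic(s))),
                      ntrim), use.names = FALSE)
  })
  envs <- lapply(amp_bands, function(b) {
    bp <- bandpass_segments(aseg, b, fs)
    unlist(apply_trim(lapply(bp, function(s) Mod(hilbert_analytic(s))),
                      ntrim), use.names = FALSE)
  })
  mi <- matrix(0, nrow = length(modulating), ncol = length(modulated),
               dimnames = list(modulating, modulated))
  for (i in seq_along(modulating))
    for (j in seq_along(modulated))
      mi[i, j] <- canolty_mi(envs[[j]], phases[[i]])
  structure(list(phase_source = phase_region$region,
                 amp_source = amp_region$region,
                 modulating_centers = modulating,
                 modulated_centers = modulated,
                 mi = mi),
            class = "cfc_grid")
}

#' Surrogate z-score for a modulation index
#'
#' Null-normalises an MI value with circular time-shift surrogates of the
#' envelope: the observed MI minus the surrogate mean, divided by the
#' surrogate standard deviation. Off by default in the pipeline; the raw
#' Canolty MI is the reference quantity.
#'
#' @param amplitude,phase aligned envelope and phase series.
#' @param n_surrogates number of circular shifts (default 200).
#' @param seed RNG seed for the shift offsets.
#' @return List with `mi`, `z`, `surrogate_mean`, `surrogate_sd`.
#' @export
mi_surrogate_z <- function(amplitude, phase, n_surrogates = 200, seed = 1) {
  n <- length(amplitude)
  mi <- canolty_mi(amplitude, phase)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shifts <- sample(seq_len(n - 1), n_surrogates, replace = TRUE)
  null_mi <- vapply(shifts, function(s)
    canolty_mi(c(amplitude[(s + 1):n], amplitude[1:s]), phase), numeric(1))
  list(mi = mi, z = (mi - mean(null_mi)) / stats::sd(null_mi),
       surrogate_mean = mean(null_mi), surrogate_sd = stats::sd(null_mi))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
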