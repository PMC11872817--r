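# Preprocessing chain: average reference -> zero-phase high-pass + notch ->
# amplitude-based artifact segment selection. Order matters and matches the
# reference-then-filter convention; it is the only supported order.

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the column (per-sample) mean of the output is zero. Idempotent.
#'
#' @param rec an [eeg_recording()] with at least 2 channels.
#' @return A new `eeg_recording`; the input is not modified.
#' @export
apply_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average reference undefined for a single channel")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' High-pass and notch filtering
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass at
#' `highpass_hz` followed by a zero-phase 2nd-order notch (quality factor
#' `Q`) at `notch_hz`, applied per channel and per retained segment. Zero
#' phase is required because instantaneous phase estimates feed the
#' cross-frequency coupling stage.
#'
#' @param rec an [eeg_recording()].
#' @param highpass_hz high-pass corner in Hz (default 0.1).
#' @param notch_hz notch frequency in Hz (default 50, line frequency).
#' @param Q notch quality factor (default 30).
#' @return Filtered `eeg_recording`.
#' @export
apply_filters <- function(rec, highpass_hz = 0.1, notch_hz = 50, Q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(highpass_hz > 0 && highpass_hz < notch_hz))
    stop("need 0 < highpass_hz < notch_hz")
  if (notch_hz >= rec$fs / 2)
    stop("notch frequency ", notch_hz, " Hz is at or above Nyquist (",
         rec$fs / 2, " Hz)")
  hp <- butter_design(4, highpass_hz, rec$fs, "high")
  nt <- notch_design(notch_hz, rec$fs, Q)
  for (s in rec$segments) {
    idx <- (s[1] + 1):s[2]
    for (ch in seq_len(nrow(rec$data))) {
      x <- rec$data[ch, idx]
      # the 0.1 Hz high-pass settles over ~800 samples (pole radius .9988);
      # pad by three time constants so edge transients die in the padding
      x <- filtfilt_sos(x, hp$sos, npad = min(length(x) - 1, 2500))
      x <- filtfilt(x, nt$b, nt$a, npad = min(length(x) - 1, 512))
      rec$data[ch, idx] <- x
    }
  }
  rec
}

#' Select artifact-free segments by amplitude threshold
#'
#' Automated stand-in for manual artifact rejection: samples where any
#' channel exceeds `amplitude_uV` in magnitude are rejected, each excursion
#' is padded by `pad_s` seconds on both sides, and the retained data is
#' recorded as maximal half-open segments. Downstream operations use only
#' these segments. The default 150 uV threshold is a conventional gross-
#' artifact bound, not a published parameter.
#'
#' @param rec an [eeg_recording()].
#' @param amplitude_uV rejection threshold in microvolts (> 0).
#' @param pad_s padding around each excursion in seconds (default 0.5).
#' @return `eeg_recording` with an updated `segments` field.
#' @export
select_artifact_free <- function(rec, amplitude_uV = 150, pad_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(amplitude_uV) || amplitude_uV <= 0)
    stop("amplitude threshold must be > 0")
  n <- ncol(rec$data)
  bad <- colSums(abs(rec$data) > amplitude_uV) > 0
  pad <- as.integer(round(pad_s * rec$fs))
  if (any(bad) && pad > 0) {
    idx <- which(bad)
    lo <- pmax(1L, idx - pad)
    hi <- pmin(n, idx + pad)
    for (k in seq_along(idx)) bad[lo[k]:hi[k]] <- TRUE
  }
  good <- !bad
  if (!any(good)) stop("empty recording: no samples below threshold")
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rec$segments <- lapply(keep, function(k) c(starts[k] - 1L, ends[k]))
  rec
}

#' Standard preprocessing chain
#'
#' Average reference, then zero-phase high-pass and notch filtering, then
#' amplitude-based artifact segment selection, in that order.
#'
#' @param rec an [eeg_recording()].
#' @param highpass_hz,notch_hz filter parameters, see [apply_filters()].
#' @param amplitude_uV,pad_s artifact parameters, see
#'   [select_artifact_free()].
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess <- function(rec, highpass_hz = 0.1, notch_hz = 50,
                       amplitude_uV = 150, pad_s = 0.5) {
  rec <- apply_average_reference(rec)
  rec <- apply_filters(rec, highpass_hz, notch_hz)
  select_artifact_free(rec, amplitude_uV, pad_s)
}
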