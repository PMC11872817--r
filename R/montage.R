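#' Standard 21-channel 10/20 montage
#'
#' Channel labels of the clinical 21-electrode 10/20 layout (19 scalp
#' positions plus the A1/A2 ear electrodes), in the conventional
#' anterior-to-posterior order. This is the default montage of the synthetic
#' cohort generator and the label universe against which region definitions
#' are validated.
#'
#' @return Character vector of 21 channel labels.
#' @export
standard_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "A1", "T3", "C3", "Cz", "C4", "T4", "A2",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Modern (10/10-style) aliases mapped back to the classical labels used here.
.label_synonyms <- c(
  "T7" = "T3", "T8" = "T4", "P7" = "T5", "P8" = "T6"
)

#' Normalize channel labels to the classical 10/20 dialect
#'
#' Case-insensitive matching against the standard montage plus a synonym map
#' for the modern labels (T7/T8 -> T3/T4, P7/P8 -> T5/T6). Labels that do not
#' resolve to a montage position are returned with their original spelling so
#' callers can decide whether to keep or drop them.
#'
#' @param labels character vector of channel labels.
#' @return Character vector of the same length with normalized labels.
#' @export
normalize_channel_labels <- function(labels) {
  stopifnot(is.character(labels))
  out <- labels
  syn_idx <- match(toupper(labels), toupper(names(.label_synonyms)))
  out[!is.na(syn_idx)] <- unname(.label_synonyms[syn_idx[!is.na(syn_idx)]])
  std <- standard_montage()
  std_idx <- match(toupper(out), toupper(std))
  out[!is.na(std_idx)] <- std[std_idx[!is.na(std_idx)]]
  out
}

#' Default scalp regions of interest
#'
#' The five regions over which all features are aggregated: occipital (O1,
#' O2), frontal-complete (Fp1, Fp2, F4, F3, F8, F7, Fz), fronto-polar (Fp1,
#' Fp2), temporal (T3, T4) and parietal (P3, P4, Pz).
#'
#' @return Named list mapping region name to character vector of channel
#'   labels.
#' @export
default_regions <- function() {
  list(
    occipital        = c("O1", "O2"),
    frontal_complete = c("Fp1", "Fp2", "F4", "F3", "F8", "F7", "Fz"),
    fronto_polar     = c("Fp1", "Fp2"),
    temporal         = c("T3", "T4"),
    parietal         = c("P3", "P4", "Pz")
  )
}

#' Default frequency bands (Hz)
#'
#' Eight bands used throughout: delta 1-4, theta 4-8, alpha 8-14, beta 14-31,
#' gamma 31-80, and the composite bands theta-alpha 4-14, alpha-beta-gamma
#' 8-80 and beta-gamma 14-80. Band intervals are half-open `[low, high)` so
#' that adjacent bands do not double-count shared edges.
#'
#' @return Named list mapping band name to `c(low, high)` in Hz.
#' @export
default_bands <- function() {
  list(
    delta            = c(1, 4),
    theta            = c(4, 8),
    alpha            = c(8, 14),
    beta             = c(14, 31),
    gamma            = c(31, 80),
    theta_alpha      = c(4, 14),
    alpha_beta_gamma = c(8, 80),
    beta_gamma       = c(14, 80)
  )
}

#' Default region pairs for coherence
#'
#' The region and region-pair set over which coherence is reported: each of
#' the five regions "within itself" (mean coherence over the region's channel
#' pairs) and the between-region pairs parietal/frontal-complete,
#' parietal/fronto-polar, parietal/temporal and frontal-complete/temporal.
#'
#' @return List of length-1 (within-region) or length-2 (between-region)
#'   character vectors of region names.
#' @export
default_coherence_pairs <- function() {
  list(
    "occipital", "temporal", "frontal_complete", "parietal", "fronto_polar",
    c("parietal", "frontal_complete"),
    c("parietal", "fronto_polar"),
    c("parietal", "temporal"),
    c("frontal_complete", "temporal")
  )
}

#' Default region pairs for cross-frequency coupling
#'
#' Within-region coupling for all five regions plus the between-region pairs
#' reported in the study design (parietal/fronto-polar,
#' frontal-complete/temporal, parietal/temporal). For between-region pairs the
#' first region supplies the modulating phase and the second the modulated
#' amplitude; the reverse direction is computed as well.
#'
#' @return List of length-1 or length-2 character vectors of region names.
#' @export
default_cfc_pairs <- function() {
  list(
    "occipital", "frontal_complete", "fronto_polar", "temporal", "parietal",
    c("parietal", "fronto_polar"),
    c("frontal_complete", "temporal"),
    c("parietal", "temporal")
  )
}

validate_regions <- function(regions, channel_labels = NULL) {
  stopifnot(is.list(regions), length(regions) > 0)
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  for (nm in names(regions)) {
    ch <- regions[[nm]]
    if (!is.character(ch) || length(ch) == 0)
      stop("region '", nm, "' is empty")
    if (!is.null(channel_labels)) {
      miss <- setdiff(normalize_channel_labels(ch),
                      normalize_channel_labels(channel_labels))
      # Missing channels are permitted at the montage level; region_signal()
      # errors only when a region has no channel present at all.
    }
  }
  invisible(regions)
}

validate_bands <- function(bands) {
  stopifnot(is.list(bands), length(bands) > 0)
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("bands must be a named list")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop("band '", nm, "' must be c(low, high) with low < high")
  }
  invisible(bands)
}
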