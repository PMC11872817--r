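# Reading recordings from disk and cohort manifests.

#' Read an EEG recording from disk
#'
#' EDF files carry their own sampling rate; delimited text files (one column
#' per channel, header row of channel labels, comma or tab separated) need
#' `fs` supplied. Channel labels are normalized to the classical 10/20
#' dialect (T7/T8 -> T3/T4); duplicate labels are a validation error and
#' montage channels that are absent are simply recorded as missing.
#'
#' @param path file path.
#' @param format `"edf"` or `"delimited"`; default guesses from the file
#'   extension.
#' @param fs sampling rate in Hz (required for delimited files).
#' @param subject_id,condition metadata attached to the recording.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           fs = NULL, subject_id = "s01",
                           condition = c("pre", "post")) {
  format <- match.arg(format)
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") {
    e <- read_edf(path)
    return(eeg_recording(e$data, e$fs, e$channel_labels,
                         subject_id = subject_id, condition = condition))
  }
  if (is.null(fs))
    stop("fs must be supplied for delimited recordings (sidecar value)")
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 1 || !all(vapply(df, is.numeric, logical(1))))
    stop("format error: expected a numeric matrix with a header of labels")
  labels <- colnames(df)
  if (anyDuplicated(normalize_channel_labels(labels)))
    stop("duplicate channel labels in ", path)
  eeg_recording(t(as.matrix(df)), fs, labels,
                subject_id = subject_id, condition = condition)
}

#' Write a recording as delimited text
#'
#' One column per channel with a header row of labels, tab-separated. The
#' sampling rate is not stored in the file; keep it in the manifest.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Tab-separated table with columns `subject`, `condition`, `path`, `fs`.
#' Relative paths are resolved against the manifest's directory. Validates
#' that every subject has exactly one pre and one post row and that all
#' files exist, before any recording is read.
#'
#' @param path manifest file path.
#' @return `data.frame` with absolute paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject", "condition", "path", "fs")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  tab <- table(man$subject, man$condition)
  bad <- rownames(tab)[!(tab[, "pre"] == 1 & tab[, "post"] == 1)]
  if (!all(c("pre", "post") %in% colnames(tab)) || length(bad) > 0)
    stop("manifest inconsistency: subjects without exactly one pre and one ",
         "post recording: ",
         paste(if (length(bad)) bad else rownames(tab), collapse = ", "))
  missing <- man$path[!file.exists(man$path)]
  if (length(missing) > 0)
    stop("manifest lists missing files: ", paste(missing, collapse = ", "))
  man
}

#' Write the retained-segment table
#'
#' @param recs list of preprocessed [eeg_recording()] objects.
#' @param path output TSV path (subject, condition, start_s, end_s).
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(recs, path) {
  rows <- do.call(rbind, lapply(recs, function(r) {
    do.call(rbind, lapply(r$segments, function(s)
      data.frame(subject = r$subject_id, condition = r$condition,
                 start_s = s[1] / r$fs, end_s = s[2] / r$fs)))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
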