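#' Default 29-channel montage
#'
#' The 10-20 montage used by the reference configuration. The 24
#' electrodes named by the channel-count sensitivity ladder are extended
#' to 29 with Cz, CPz, FT7, FT8 and TP7 (a configurable assumption: the
#' source configuration names only 24 of its 29 electrodes).
#'
#' @return Character vector of 29 electrode labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2",
    "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T3", "C3", "Cz", "C4", "T4",
    "TP7", "CP3", "CPz", "CP4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

#' Construct an EEG recording
#'
#' A per-subject container: a channels x samples matrix in microvolts,
#' trial onsets, and the clinical severity label derived from the NIHSS
#' score (mild: NIHSS <= 4; moderate: 5 <= NIHSS <= 15).
#'
#' @param subject_id Character scalar.
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param fs Sampling rate in Hz; must exceed twice the highest analysis
#'   frequency (40 Hz), i.e. be at least 80 Hz.
#' @param trial_onsets Strictly increasing integer sample indices (1-based)
#'   of trial starts.
#' @param label `"mild"` or `"moderate"`; must be consistent with `nihss`.
#' @param nihss Integer NIHSS score in 0..15.
#' @param band Optional band name if the data have been band-pass filtered.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, data, channel_labels, fs, trial_onsets,
                          label, nihss, band = NA_character_) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         data = data,
         channel_labels = as.character(channel_labels),
         fs = as.numeric(fs),
         trial_onsets = as.integer(trial_onsets),
         label = as.character(label),
         nihss = as.integer(nihss),
         band = band),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  if (nrow(rec$data) != length(rec$channel_labels))
    stop("data row count (", nrow(rec$data), ") does not equal channel count (",
         length(rec$channel_labels), ")", call. = FALSE)
  if (anyDuplicated(rec$channel_labels))
    stop("duplicate channel labels", call. = FALSE)
  if (!is.finite(rec$fs) || rec$fs < 80)
    stop("fs must be >= 80 Hz (twice the 40 Hz gamma upper edge)",
         call. = FALSE)
  on <- rec$trial_onsets
  if (length(on) == 0 || any(diff(on) <= 0) || any(on < 1) ||
      any(on > ncol(rec$data)))
    stop("trial_onsets must be strictly increasing indices within the data",
         call. = FALSE)
  if (!rec$label %in% c("mild", "moderate"))
    stop("label must be 'mild' or 'moderate'", call. = FALSE)
  if (is.na(rec$nihss) || rec$nihss < 0 || rec$nihss > 15)
    stop("nihss must be in 0..15", call. = FALSE)
  expected <- if (rec$nihss <= 4) "mild" else "moderate"
  if (rec$label != expected)
    stop("label '", rec$label, "' inconsistent with nihss = ", rec$nihss,
         " (mild iff nihss <= 4)", call. = FALSE)
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d ch x %d samples @ %g Hz, %d trials, %s (NIHSS %d)%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              length(x$trial_onsets), x$label, x$nihss,
              if (is.na(x$band)) "" else paste0(", band ", x$band)))
  invisible(x)
}
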