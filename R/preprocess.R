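#' Zero-phase band-pass filter
#'
#' Filters every channel into one of the five analysis bands with a
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), i.e. zero phase shift — a prerequisite for
#' meaningful phase-locking values downstream.
#'
#' @param rec An [eeg_recording()].
#' @param band One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return The recording with filtered data and `band` set.
#' @export
bandpass <- function(rec, band) {
  band <- match.arg(band, names(EEG_BANDS))
  lims <- EEG_BANDS[[band]]
  if (rec$fs <= 2 * lims[2])
    stop("fs = ", rec$fs, " Hz too low for the ", band, " band (needs > ",
         2 * lims[2], " Hz)", call. = FALSE)
  bf <- signal::butter(4, lims / (rec$fs / 2), type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec$band <- band
  rec
}

# Within-trial phase layout (seconds): instruction, motor imagery, break.
# The 8-s trial is instruction [0, 2), MI [2, 6), break [6, 8) — an
# assumption consistent with how sub-8-s windows map onto trial phases.
trial_phases <- function(instruction_end = 2, mi_end = 6) {
  list(instruction_end = instruction_end, mi_end = mi_end)
}

# Start offset (s) of a window of length w inside an 8-s trial:
# 2-4 s windows start at the MI cue; 5-6 s extend backward into the
# instruction; 7-8 s extend forward into the break.
window_offset <- function(window_seconds, phases = trial_phases()) {
  mi_start <- phases$instruction_end
  mi_len <- phases$mi_end - phases$instruction_end
  if (window_seconds <= mi_len) mi_start
  else max(0, phases$mi_end - window_seconds)
}

#' Segment a recording into per-trial windows
#'
#' Cuts one window per trial, anchored to the trial's phase layout: a
#' window no longer than the motor-imagery phase starts at the MI cue;
#' longer windows extend backward into the instruction phase and, beyond
#' 6 s, forward into the break.
#'
#' @param rec An [eeg_recording()].
#' @param window_seconds Window length in seconds, in `[2, 8]`.
#' @param phases Phase layout from [trial_phases()].
#' @return List of `band_segment` objects (one per trial), each with
#'   `subject_id`, `band`, `window_index`, `window_seconds`, `fs`,
#'   `label`, `channel_labels` and the channels x samples `data`.
#' @export
segment <- function(rec, window_seconds = 8, phases = trial_phases()) {
  if (window_seconds < 2 || window_seconds > 8)
    stop("window_seconds must lie in [2, 8]", call. = FALSE)
  trial_len <- if (length(rec$trial_onsets) > 1)
    min(diff(rec$trial_onsets)) else ncol(rec$data) - rec$trial_onsets[1] + 1
  win <- round(window_seconds * rec$fs)
  if (win > trial_len)
    stop("window (", window_seconds, " s) exceeds trial length (",
         trial_len / rec$fs, " s)", call. = FALSE)
  off <- round(window_offset(window_seconds, phases) * rec$fs)
  if (off + win > trial_len) off <- trial_len - win
  lapply(seq_along(rec$trial_onsets), function(i) {
    start <- rec$trial_onsets[i] + off
    structure(list(subject_id = rec$subject_id, band = rec$band,
                   window_index = i, window_seconds = window_seconds,
                   fs = rec$fs, label = rec$label,
                   channel_labels = rec$channel_labels,
                   data = rec$data[, start:(start + win - 1L), drop = FALSE]),
              class = "band_segment")
  })
}

# The nested channel-count configurations of the sensitivity ladder.
CHANNEL_CONFIGS <- local({
  c8 <- c("Fp1", "Fp2", "C3", "C4", "O1", "O2", "Pz", "Fz")
  c16 <- c(c8, "F3", "F4", "FC3", "FC4", "CP3", "CP4", "P3", "P4")
  c22 <- c(c16, "F7", "F8", "T3", "T4", "T5", "T6")
  c24 <- c(c22, "FCz", "Oz")
  list(`8` = c8, `16` = c16, `22` = c22, `24` = c24)
})

#' Select a nested channel configuration
#'
#' Restricts a recording to one of the bilateral channel subsets used in
#' the spatial-sampling sensitivity ladder (8, 16, 22, 24 channels, or
#' the full 29-channel montage). Channel order follows the
#' configuration listing.
#'
#' @param rec An [eeg_recording()].
#' @param config One of 8, 16, 22, 24, 29.
#' @return The recording restricted to the selected channels.
#' @export
select_channels <- function(rec, config) {
  config <- as.character(config)
  if (!config %in% c(names(CHANNEL_CONFIGS), "29"))
    stop("config must be one of 8, 16, 22, 24, 29", call. = FALSE)
  wanted <- if (config == "29") rec$channel_labels else
    CHANNEL_CONFIGS[[config]]
  missing <- setdiff(wanted, rec$channel_labels)
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(wanted, rec$channel_labels)
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_labels <- wanted
  rec
}
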