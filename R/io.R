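#' Write a recording to disk
#'
#' Two formats are supported. `"csv"` writes the channels x samples
#' matrix as CSV (channel labels as row names) at full printed precision.
#' `"edf"` writes a standard EDF file (16-bit samples, per-channel
#' physical scaling), so the data round-trip is exact only up to one
#' quantization step of the channel's physical range. Both formats get a
#' JSON sidecar (same path, `.json` extension) carrying `subject_id`,
#' `fs`, `channel_labels`, `trial_onsets`, `label` and `nihss`; EDF+
#' annotation channels are deliberately not used.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path (`.csv` or `.edf` decides nothing; use
#'   `format`).
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  validate_recording(rec)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory '", dir,
                             "' does not exist", call. = FALSE)
  meta <- list(subject_id = rec$subject_id, fs = rec$fs,
               channel_labels = rec$channel_labels,
               trial_onsets = rec$trial_onsets, label = rec$label,
               nihss = rec$nihss, band = rec$band)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  if (format == "csv") {
    df <- as.data.frame(rec$data)
    rownames(df) <- rec$channel_labels
    write.csv(df, path, row.names = TRUE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path),
                                      ".json")

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]; the format is inferred from the
#' file extension. The JSON sidecar must be present; all recording
#' invariants (label/NIHSS consistency, onset monotonicity, ...) are
#' re-validated on read.
#'
#' @param path Path to a `.csv` or `.edf` file written by
#'   [write_recording()].
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("format error: missing metadata sidecar '", sp, "'", call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("subject_id", "fs", "channel_labels", "trial_onsets",
                  "label", "nihss")) {
    if (is.null(meta[[field]]))
      stop("format error: metadata field '", field, "' missing", call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", path))
  data <- if (ext == "edf") read_edf_data(path) else {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
  dimnames(data) <- NULL
  eeg_recording(subject_id = meta$subject_id, data = data,
                channel_labels = meta$channel_labels, fs = meta$fs,
                trial_onsets = meta$trial_onsets, label = meta$label,
                nihss = meta$nihss,
                band = if (is.null(meta$band)) NA_character_ else meta$band)
}

# ---- minimal EDF codec ------------------------------------------------

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# render a number into <= 8 ASCII chars (EDF numeric header fields)
edf_num <- function(x) {
  vapply(x, function(v) {
    for (d in 6:1) {
      s <- sprintf("%.*g", d, v)
      if (nchar(s) <= 8) return(s)
    }
    s
  }, "")
}

write_edf <- function(rec, path) {
  n_ch <- nrow(rec$data)
  total <- ncol(rec$data)
  if (total %% rec$fs == 0 && rec$fs == round(rec$fs)) {
    spr <- as.integer(rec$fs); n_rec <- total %/% spr; dur <- 1
  } else {
    spr <- total; n_rec <- 1L; dur <- total / rec$fs
  }
  plo <- apply(rec$data, 1, min)
  phi <- apply(rec$data, 1, max)
  flat <- phi - plo < 1e-12
  phi[flat] <- plo[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field(paste0("Startdate X ", rec$label, " NIHSS=", rec$nihss), 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (n_ch + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(format(dur, digits = 7), 8),
    edf_field(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  per(rec$channel_labels, 16)
  per(rep("", n_ch), 80)
  per(rep("uV", n_ch), 8)
  per(edf_num(plo), 8)
  per(edf_num(phi), 8)
  per(rep(dmin, n_ch), 8)
  per(rep(dmax, n_ch), 8)
  per(rep("", n_ch), 80)
  per(rep(spr, n_ch), 8)
  per(rep("", n_ch), 32)
  # re-read the printed physical limits so the stored scaling matches
  plo_s <- as.numeric(edf_num(plo))
  phi_s <- as.numeric(edf_num(phi))
  scale <- (dmax - dmin) / (phi_s - plo_s)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(n_ch)) {
      dig <- round((rec$data[ch, cols] - plo_s[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf_data <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rd(8)                      # record duration
  n_ch <- as.integer(rd(4))
  if (is.na(n_ch) || n_ch <= 0)
    stop("format error: invalid EDF signal count", call. = FALSE)
  rdv <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  out <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch]) +
        pmin[ch]
    }
  }
  out
}

# number of signals reported by an EDF header (header consistency checks)
edf_signal_count <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 252, useBytes = TRUE)
  as.integer(trimws(readChar(con, 4, useBytes = TRUE)))
}
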