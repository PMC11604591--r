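#' Minimal EDF epoch I/O
#'
#' A self-contained reader/writer for the European Data Format (EDF), the
#' 16-bit interchange format commonly used for EEG recordings. Coverage is
#' deliberately narrow: fixed-rate continuous signals, one data record per
#' epoch, plus one extra single-sample "LABEL" signal per record carrying
#' the class code. This supports round-tripping synthetic epochs and
#' ingesting externally exported, cue-aligned trials; it is not a general
#' EDF+/GDF implementation (no annotations, no variable record layouts).
#'
#' @name edf-io
NULL

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_write_str <- function(con, x, width) {
  writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
}

#' Write epochs to an EDF file
#'
#' Each epoch becomes one data record; all epochs must share the same
#' geometry. A final "LABEL" signal (one sample per record) stores the class
#' index digitally.
#'
#' @param epochs List of [signal_epoch()] objects.
#' @param path Output file path.
#' @param fs Sampling frequency in Hz (record duration is
#'   `timepoints / fs` seconds).
#' @param channel_names Optional character vector of channel labels.
#' @return `path`, invisibly.
#' @export
write_epochs_edf <- function(epochs, path, fs = 250,
                             channel_names = NULL) {
  if (length(epochs) == 0L) stop("no epochs to write")
  nch <- nrow(epochs[[1L]]$data); ntp <- ncol(epochs[[1L]]$data)
  if (!all(vapply(epochs, function(e) all(dim(e$data) == c(nch, ntp)),
                  logical(1))))
    stop("all epochs must share the same geometry")
  if (is.null(channel_names)) channel_names <- sprintf("EEG %02d", seq_len(nch))
  ns <- nch + 1L
  nrec <- length(epochs)
  # physical range per channel across all records (symmetric padding if flat)
  allmin <- min(vapply(epochs, function(e) min(e$data), numeric(1)))
  allmax <- max(vapply(epochs, function(e) max(e$data), numeric(1)))
  if (allmax - allmin < 1e-9) { allmin <- allmin - 1; allmax <- allmax + 1 }
  labels <- vapply(epochs, `[[`, integer(1), "label")
  con <- file(path, "wb")
  on.exit(close(con))
  edf_write_str(con, "0", 8L)
  edf_write_str(con, "synthetic epochs", 80L)
  edf_write_str(con, sprintf("eegram subject=%d session=%d",
                             epochs[[1L]]$subject, epochs[[1L]]$session), 80L)
  edf_write_str(con, "01.01.26", 8L)
  edf_write_str(con, "00.00.00", 8L)
  edf_write_str(con, as.character(256L * (1L + ns)), 8L)
  edf_write_str(con, "", 44L)
  edf_write_str(con, as.character(nrec), 8L)
  edf_write_str(con, format(ntp / fs, digits = 6), 8L)
  edf_write_str(con, as.character(ns), 4L)
  sig_labels <- c(channel_names, "LABEL")
  for (s in sig_labels) edf_write_str(con, s, 16L)
  for (s in seq_len(ns)) edf_write_str(con, "synthetic", 80L)
  for (s in seq_len(ns)) edf_write_str(con, "uV", 8L)
  pmins <- c(rep(allmin, nch), -128)
  pmaxs <- c(rep(allmax, nch), 127)
  for (v in pmins) edf_write_str(con, format(v, digits = 7), 8L)
  for (v in pmaxs) edf_write_str(con, format(v, digits = 7), 8L)
  for (s in seq_len(ns)) edf_write_str(con, "-32768", 8L)
  for (s in seq_len(ns)) edf_write_str(con, "32767", 8L)
  for (s in seq_len(ns)) edf_write_str(con, "none", 80L)
  spr <- c(rep(ntp, nch), 1L)
  for (v in spr) edf_write_str(con, as.character(v), 8L)
  for (s in seq_len(ns)) edf_write_str(con, "", 32L)
  # header strings above are ASCII-decimal; reparse them for exact inversion
  pmin_r <- as.numeric(edf_pad(format(allmin, digits = 7), 8L))
  pmax_r <- as.numeric(edf_pad(format(allmax, digits = 7), 8L))
  scale <- (pmax_r - pmin_r) / 65535
  for (i in seq_len(nrec)) {
    dig <- round((t(epochs[[i]]$data) - pmin_r) / scale) - 32768
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
             endian = "little")
    ldig <- round((labels[i] + 128) / (255 / 65535)) - 32768
    writeBin(as.integer(ldig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

edf_read_str <- function(con, width) trimws(readChar(con, width, useBytes = TRUE))

#' Read cue-aligned epochs from an EDF file
#'
#' Reads an EDF file written by [write_epochs_edf()] (or any EDF whose data
#' records are one trial each, with an optional single-sample "LABEL"
#' signal). Channel count and sampling rate are validated against the
#' expectation; unknown label codes raise an error naming the code.
#'
#' @param path EDF file path.
#' @param n_channels Expected EEG channel count (default 22).
#' @param fs Expected sampling frequency in Hz (default 250).
#' @param n_classes Number of valid classes; label codes outside
#'   `0..n_classes-1` are rejected.
#' @return List of [signal_epoch()] objects.
#' @export
read_external_eeg <- function(path, n_channels = 22L, fs = 250,
                              n_classes = 4L) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_read_str(con, 8L)
  if (version != "0") stop("not an EDF file (version field: ", version, ")")
  invisible(edf_read_str(con, 80L))
  rec_id <- edf_read_str(con, 80L)
  invisible(edf_read_str(con, 8L)); invisible(edf_read_str(con, 8L))
  invisible(edf_read_str(con, 8L)); invisible(edf_read_str(con, 44L))
  nrec <- as.integer(edf_read_str(con, 8L))
  rec_dur <- as.numeric(edf_read_str(con, 8L))
  ns <- as.integer(edf_read_str(con, 4L))
  rd <- function(w) vapply(seq_len(ns), function(i) edf_read_str(con, w), "")
  sig_labels <- rd(16L); invisible(rd(80L)); invisible(rd(8L))
  pmins <- as.numeric(rd(8L)); pmaxs <- as.numeric(rd(8L))
  dmins <- as.numeric(rd(8L)); dmaxs <- as.numeric(rd(8L))
  invisible(rd(80L))
  spr <- as.integer(rd(8L)); invisible(rd(32L))
  label_idx <- which(sig_labels == "LABEL")
  eeg_idx <- setdiff(seq_len(ns), label_idx)
  if (length(eeg_idx) != n_channels)
    stop(sprintf("expected %d EEG channels, found %d (missing channels?)",
                 n_channels, length(eeg_idx)))
  ntp <- spr[eeg_idx[1L]]
  got_fs <- ntp / rec_dur
  if (abs(got_fs - fs) > 1e-6)
    stop(sprintf("expected sampling frequency %g Hz, found %g Hz", fs, got_fs))
  subject <- 1L; session <- 1L
  mm <- regmatches(rec_id, regexec("subject=(\\d+) session=(\\d+)", rec_id))[[1L]]
  if (length(mm) == 3L) { subject <- as.integer(mm[2]); session <- as.integer(mm[3]) }
  scales <- (pmaxs - pmins) / (dmaxs - dmins)
  out <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    m <- matrix(NA_real_, n_channels, ntp)
    label <- NA_integer_
    ch_row <- 0L
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmins[s]) * scales[s] + pmins[s]
      if (s %in% label_idx) {
        label <- as.integer(round(phys[1L]))
      } else {
        ch_row <- ch_row + 1L
        m[ch_row, ] <- phys
      }
    }
    if (length(label_idx)) {
      if (is.na(label) || label < 0L || label >= n_classes)
        stop("unknown event code in LABEL signal: ", label)
    } else label <- 0L
    out[[i]] <- signal_epoch(m, label, subject = subject, session = session,
                             trial = i)
  }
  out
}
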