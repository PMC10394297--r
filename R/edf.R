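# Minimal EDF (European Data Format) support.
#
# EDF stores a 256-byte ASCII header, one 256-byte ASCII header per signal,
# then data records of 16-bit little-endian integers that are mapped to
# physical units through per-signal physical/digital calibration ranges.
# This implementation covers the subset the package needs: one sampling
# rate across the selected channels, 16-bit continuous recordings.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width, flag = "-")
}

#' Write a multichannel signal to an EDF file
#'
#' Writes 16-bit EDF with one data record per second. Physical calibration
#' ranges are taken per channel from the data (min/max, widened slightly for
#' constant channels), so the quantization error is bounded by
#' `(max - min) / 65535` per channel.
#'
#' @param signal a [multichannel_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf_recording <- function(signal, path) {
  x <- signal$samples
  fs <- signal$sampling_rate_hz
  if (fs != round(fs)) {
    stop_seizdg("EDF writer requires an integer sampling rate",
                class = "seizdg_io_error")
  }
  nc <- nrow(x)
  spr <- as.integer(fs)                      # samples per record (1 s records)
  n_rec <- floor(ncol(x) / spr)
  if (n_rec < 1) stop_seizdg("recording shorter than one data record",
                             class = "seizdg_io_error")
  x <- x[, seq_len(n_rec * spr), drop = FALSE]

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("X X", 80),
    pad_field(format(Sys.time(), "%d.%m.%y"), 8),
    pad_field(format(Sys.time(), "%H.%M.%S"), 8),
    pad_field(256L * (1L + nc), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(nc, 4)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(signal$channel_names, 16)
  field(rep("", nc), 80)                     # transducer
  field(rep("uV", nc), 8)                    # physical dimension
  field(formatC(pmin_, format = "g", digits = 7), 8)
  field(formatC(pmax_, format = "g", digits = 7), 8)
  field(rep(dmin, nc), 8)
  field(rep(dmax, nc), 8)
  field(rep("", nc), 80)                     # prefiltering
  field(rep(spr, nc), 8)
  field(rep("", nc), 32)                     # reserved

  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (rec in seq_len(n_rec)) {
    cols <- ((rec - 1L) * spr + 1L):(rec * spr)
    for (c_i in seq_len(nc)) {
      dig <- round((x[c_i, cols] - pmin_[c_i]) / scale[c_i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a multichannel EEG recording from an EDF file
#'
#' Reads a 16-bit EDF file, converts digital values to physical units via
#' the per-channel calibration in the header, and returns the requested
#' channels in the requested order. All selected channels must share one
#' sampling rate.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep, in
#'   the desired order; default all channels in file order.
#' @param patient_id identifier attached to the returned signal.
#' @return a [multichannel_signal()].
#' @export
read_edf_recording <- function(path, channels = NULL, patient_id = "unknown") {
  if (!file.exists(path)) {
    stop_seizdg("EDF file not found: ", path, class = "seizdg_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(nc), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  sel <- seq_len(nc)
  if (!is.null(channels)) {
    sel <- match(channels, labels)
    if (anyNA(sel)) {
      stop_seizdg("channel(s) not present in EDF: ",
                  paste(channels[is.na(sel)], collapse = ", "),
                  class = "seizdg_channel_error")
    }
  }
  if (length(unique(spr[sel])) != 1L) {
    stop_seizdg("selected channels have mixed sampling rates",
                class = "seizdg_format_error")
  }
  fs <- spr[sel[1]] / rec_dur

  out <- matrix(0, length(sel), n_rec * spr[sel[1]])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  rec_len <- sum(spr)
  for (rec in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = rec_len, size = 2L,
                   endian = "little", signed = TRUE)
    offs <- cumsum(c(0L, spr))
    for (j in seq_along(sel)) {
      ch <- sel[j]
      vals <- dig[(offs[ch] + 1L):(offs[ch] + spr[ch])]
      out[j, ((rec - 1L) * spr[ch] + 1L):(rec * spr[ch])] <-
        (vals - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  multichannel_signal(out, fs, labels[sel], patient_id)
}
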