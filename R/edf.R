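# Minimal European Data Format (EDF) support: 16-bit signals, one 1 s data
# record per second of recording. Covers exactly what the session writer
# needs; not a general-purpose EDF implementation.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are stored as 16-bit integers with a symmetric per-channel
#' physical range, so zero maps to digital zero and the quantization step is
#' `max(abs(channel)) / 32767`. The recording length must be a whole number
#' of seconds (the session synthesizer guarantees this).
#'
#' @param raw A `wd_raw`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(raw, path) {
  fs <- raw$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_samp <- ncol(raw$samples)
  if (n_samp %% fs != 0) stop("recording length must be a whole number of seconds")
  n_rec <- n_samp %/% fs
  ns <- nrow(raw$samples)

  phys_max <- apply(abs(raw$samples), 1, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(raw$channel_names, edf_pad, character(1), width = 16),
    rep(edf_pad("", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(-phys_max, function(v) edf_pad(formatC(v, digits = 7, format = "g"), 8), character(1)),
    vapply(phys_max, function(v) edf_pad(formatC(v, digits = 7, format = "g"), 8), character(1)),
    rep(edf_pad(-dig_max, 8), ns),
    rep(edf_pad(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),
    rep(edf_pad(fs, 8), ns),
    rep(edf_pad("", 32), ns)
  )
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(raw$samples[, cols, drop = FALSE] * scale)
    block <- pmin(pmax(block, -dig_max), dig_max)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return A `wd_raw` with samples in physical units.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)            # version
  readChar(con, 160, useBytes = TRUE)          # patient + recording id
  readChar(con, 16, useBytes = TRUE)           # date + time
  readChar(con, 8, useBytes = TRUE)            # header bytes
  readChar(con, 44, useBytes = TRUE)           # reserved
  n_rec <- as.integer(readChar(con, 8, useBytes = TRUE))
  rec_dur <- as.numeric(readChar(con, 8, useBytes = TRUE))
  ns <- as.integer(readChar(con, 4, useBytes = TRUE))

  rd <- function(width) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, width, useBytes = TRUE)),
           character(1))
  }
  labels <- rd(16); rd(80); rd(8)
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)

  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - gain * dig_max
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      out[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- d * gain[s] + offset[s]
    }
  }
  new_raw(out, fs, labels)
}

#' Write a synthetic session to disk
#'
#' Emits `session.edf` (signals, 16-bit, uV), `events.tsv`
#' (`sample_index`, `code`), `truth.tsv` (per-trial ground truth) and
#' `montage.tsv` (`name`, `x`, `y`, `z`) into a directory.
#'
#' @param raw A `wd_raw`.
#' @param events A `wd_events` tibble.
#' @param truth A `wd_truth` tibble.
#' @param montage A `wd_montage`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(raw, events, truth, montage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(raw, file.path(dir, "session.edf"))
  readr::write_tsv(events, file.path(dir, "events.tsv"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(montage[, c("name", "x", "y", "z")],
                   file.path(dir, "montage.tsv"))
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return List with `raw`, `events`, `truth`, `montage`.
#' @export
read_session <- function(dir) {
  raw <- read_edf(file.path(dir, "session.edf"))
  events <- readr::read_tsv(file.path(dir, "events.tsv"),
                            col_types = readr::cols(
                              sample_index = readr::col_integer(),
                              code = readr::col_character()))
  class(events) <- c("wd_events", class(events))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = readr::cols(
                             trial = readr::col_integer(),
                             side = readr::col_character(),
                             .default = readr::col_double()))
  class(truth) <- c("wd_truth", class(truth))
  montage <- default_montage(file.path(dir, "montage.tsv"))
  list(raw = raw, events = events, truth = truth, montage = montage)
}
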