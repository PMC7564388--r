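# Minimal EDF (European Data Format) reader/writer, 16-bit integer samples,
# 1-second data records. No R package for EDF is available in this stack,
# so the format is implemented directly from its fixed-width ASCII header
# layout. Only continuous unannotated EDF is supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field too wide: '%s'", x)
  formatC(x, width = -width)
}

#' Write an EEG recording to EDF
#'
#' 16-bit EDF with 1-second data records. Each channel is scaled to its own
#' symmetric physical range, so the round-trip error is bounded by
#' `max(abs(x)) / 32767` per channel (the EDF quantization step).
#' The recording must contain a whole number of seconds.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0)
    stopf("EDF writer requires a whole number of seconds (%d samples @ %g Hz)",
          n_samp, fs)
  n_rec <- n_samp %/% fs
  ns <- nrow(rec$data)

  pm_txt <- vapply(seq_len(ns), function(i) {
    pm <- max(abs(rec$data[i, ]), 1e-3) * 1.000001
    trimws(formatC(signif(pm, 6), format = "g", digits = 6))
  }, character(1))
  pm <- as.numeric(pm_txt)  # encode against the ASCII-parsed value

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8)); wr(edf_pad("1", 8)); wr(edf_pad(ns, 4))
  for (i in seq_len(ns)) wr(edf_pad(rec$channel_names[i], 16))
  for (i in seq_len(ns)) wr(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_pad(paste0("-", pm_txt[i]), 8))
  for (i in seq_len(ns)) wr(edf_pad(pm_txt[i], 8))
  for (i in seq_len(ns)) wr(edf_pad("-32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("32767", 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(fs, 32))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  dig <- round(sweep(rec$data, 1, 32767 / pm, `*`))
  dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767
  dim(dig) <- c(ns, fs, n_rec)
  dig <- aperm(dig, c(2, 1, 3))  # samples within signal within record
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the continuous 16-bit EDF files produced by [write_edf()] and
#' by standard acquisition software (equal record layout across signals,
#' no EDF+ annotations).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] (roles derived from the channel labels).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stopf("not an EDF file (version '%s'): %s", version, path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(32)); fld(32)
  if (length(unique(spr)) != 1L)
    stopf("EDF reader supports equal samples-per-record across signals only")
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  dim(raw) <- c(spr[1], ns, n_rec)
  x <- matrix(aperm(raw, c(2, 1, 3)), nrow = ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  x <- sweep(sweep(x, 1, dig_min, `-`), 1, gain, `*`)
  x <- sweep(x, 1, phys_min, `+`)
  eeg_recording(x, spr[1] / rec_dur, labels)
}
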