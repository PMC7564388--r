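# BrainVision triad (.vhdr/.vmrk/.eeg) writer and reader. Only the dialect
# this package writes is read back: binary IEEE float 32, multiplexed
# orientation, resolution 1 uV.

#' Write an EEG recording as a BrainVision triad
#'
#' Writes `<base>.vhdr` (text header), `<base>.vmrk` (marker stub) and
#' `<base>.eeg` (32-bit float, multiplexed). Float storage makes the
#' BrainVision round trip exact to single precision.
#'
#' @param rec an [eeg_recording()].
#' @param path path to the `.vhdr` file (sibling `.eeg`/`.vmrk` files are
#'   written next to it).
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  base <- sub("\\.vhdr$", "", basename(path))
  dir <- dirname(path)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$sampling_rate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nrow(rec$data)), rec$channel_names))
  writeLines(hdr, file.path(dir, paste0(base, ".vhdr")))
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"), file.path(dir, paste0(base, ".vmrk")))
  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  on.exit(close(con))
  # column-major vectorization of a channels x samples matrix is exactly
  # the multiplexed sample order
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(file.path(dir, paste0(base, ".vhdr")))
}

#' Read a BrainVision recording
#'
#' @param path path to the `.vhdr` header file.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  get1 <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(hit)) stopf("BrainVision header misses '%s': %s", key, path)
    sub(sprintf("^%s=", key), "", hit[1])
  }
  fmt <- get1("BinaryFormat"); orient <- get1("DataOrientation")
  if (fmt != "IEEE_FLOAT_32" || orient != "MULTIPLEXED")
    stopf("unsupported BrainVision dialect (%s, %s); only IEEE_FLOAT_32/MULTIPLEXED is read",
          fmt, orient)
  n_ch <- as.integer(get1("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get1("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  if (length(labels) != n_ch)
    stopf("channel count mismatch in %s", path)
  eeg_file <- file.path(dirname(path), get1("DataFile"))
  if (!file.exists(eeg_file)) stopf("data file not found: %s", eeg_file)
  n_val <- file.info(eeg_file)$size / 4
  con <- file(eeg_file, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
  eeg_recording(matrix(x, nrow = n_ch), fs, labels)
}
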