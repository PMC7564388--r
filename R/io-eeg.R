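#' Read an EEG file
#'
#' Front end over the EDF and BrainVision readers. Channel roles are
#' auto-assigned from the labels via the fixed [channel_role_map()]
#' (O1/O2/Oz occipital, C3/C4/Cz central, F3/F4/Fz/Fp1/Fp2 frontal,
#' `*EOG*` EOG); by default the result is checked to contain at least one
#' channel per ROI plus an EOG channel, and the error names the missing
#' roles.
#'
#' @param path file path (`.edf` or `.vhdr`).
#' @param format `"auto"` (by extension), `"edf"` or `"brainvision"`.
#' @param validate check that all staging-mandatory channel roles are
#'   present.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "brainvision"),
                     validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
      else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
      else stopf("cannot infer format from extension: %s", path)
  }
  rec <- switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
  if (validate) check_staging_channels(rec)
  rec
}

#' Write an EEG file
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"edf"` or `"brainvision"`.
#' @return The written path, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
      else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
      else stopf("cannot infer format from extension: %s", path)
  }
  switch(format, edf = write_edf(rec, path), brainvision = write_brainvision(rec, path))
}
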