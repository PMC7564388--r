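#' Multichannel EEG recording
#'
#' In-memory container for a multichannel EEG: a channels x samples matrix
#' in microvolts plus sampling rate, 10-20 channel labels and per-channel
#' roles. Roles drive the staging topography: the alpha centre of gravity is
#' compared across the occipital, central and frontal regions of interest
#' (ROI), and slow eye movements are read from the EOG channel(s).
#'
#' @param data numeric matrix, channels in rows, samples in columns, uV.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names character vector of channel labels (extended 10-20
#'   plus `HEOG`/`VEOG`).
#' @param channel_roles optional named character vector mapping channel to
#'   role in `occipital`, `central`, `frontal`, `eog`, `other`; derived from
#'   the labels via [channel_role_map()] when missing.
#' @param start_time optional `POSIXct` recording start.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_names,
                          channel_roles = NULL, start_time = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("EEG data must be numeric")
  assert_scalar_num(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (length(channel_names) != nrow(data))
    stopf("need one channel name per data row (%d rows, %d names)",
          nrow(data), length(channel_names))
  if (anyDuplicated(channel_names)) stopf("duplicated channel names")
  if (is.null(channel_roles)) channel_roles <- channel_role_map(channel_names)
  channel_roles <- channel_roles[channel_names]
  rownames(data) <- channel_names
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 channel_roles = channel_roles, start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$channel_roles)),
                              table(x$channel_roles)), collapse = " "), "\n")
  invisible(x)
}

#' Label to ROI role map
#'
#' Documented fixed mapping from 10-20 labels to staging roles:
#' O1, O2, Oz are occipital; C3, C4, Cz central; F3, F4, Fz, Fp1, Fp2
#' frontal; any label containing "EOG" is an EOG channel; everything else
#' is `other` (carried along but not used for ROI features).
#'
#' @param channel_names character vector of labels.
#' @return Named character vector of roles.
#' @export
channel_role_map <- function(channel_names) {
  roles <- rep("other", length(channel_names))
  up <- toupper(channel_names)
  roles[up %in% c("O1", "O2", "OZ")] <- "occipital"
  roles[up %in% c("C3", "C4", "CZ")] <- "central"
  roles[up %in% c("F3", "F4", "FZ", "FP1", "FP2")] <- "frontal"
  roles[grepl("EOG", up)] <- "eog"
  names(roles) <- channel_names
  roles
}

# The staging chain needs at least one channel per ROI plus an EOG channel.
check_staging_channels <- function(rec, require_eog = TRUE) {
  need <- c("occipital", "central", "frontal", if (require_eog) "eog")
  missing <- setdiff(need, unique(rec$channel_roles))
  if (length(missing))
    stopf("recording is missing required channel role(s): %s",
          paste(missing, collapse = ", "))
  invisible(rec)
}

role_channels <- function(rec, role) {
  rec$channel_names[rec$channel_roles == role]
}

# 31 extended 10-20 scalp labels + 2 EOG, the default synthesis montage.
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2", "PO9", "PO10",
    "HEOG", "VEOG")
}
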