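# Spectral filtering and resampling. All filters are realized in the
# frequency domain with a real, even transfer function, i.e. zero-phase by
# construction (the forward-backward equivalent for epoch-wise spectral
# features). Roll-off uses the Butterworth magnitude of order 8, whose
# asymptotic slope is 6 * 8 = 48 dB/oct.

fft_freqs <- function(n, fs) {
  f <- (seq_len(n) - 1) / n * fs
  pmin(f, fs - f)  # fold to two-sided magnitude axis
}

# Band-pass + notch via Butterworth magnitude response.
fft_band_filter <- function(x, fs, high_pass = NULL, low_pass = NULL,
                            notch = NULL, order = 8, notch_bw = 1) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  H <- rep(1, n)
  if (!is.null(low_pass)) H <- H / sqrt(1 + (f / low_pass)^(2 * order))
  if (!is.null(high_pass))
    H <- H / sqrt(1 + (high_pass / pmax(f, fs / n / 4))^(2 * order))
  if (!is.null(notch)) H <- H * (1 - exp(-0.5 * ((f - notch) / notch_bw)^2))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# Ideal (brick-wall) band-pass, used by the graphoelement and SEM detectors
# where leakage from neighbouring bands must be exactly zero.
fft_brick_band <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- fft_freqs(n, fs)
  H <- as.numeric(f >= lo & f < hi)
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# Matrix variant (samples x channels): one transfer function applied to
# every column.
fft_band_filter_mat <- function(mat, fs, high_pass = NULL, low_pass = NULL,
                                notch = NULL, order = 8, notch_bw = 1) {
  n <- nrow(mat)
  f <- fft_freqs(n, fs)
  H <- rep(1, n)
  if (!is.null(low_pass)) H <- H / sqrt(1 + (f / low_pass)^(2 * order))
  if (!is.null(high_pass))
    H <- H / sqrt(1 + (high_pass / pmax(f, fs / n / 4))^(2 * order))
  if (!is.null(notch)) H <- H * (1 - exp(-0.5 * ((f - notch) / notch_bw)^2))
  Re(mvfft(mvfft(mat) * H, inverse = TRUE)) / n
}

# Fourier resampling (ideal low-pass interpolation/decimation).
resample_fft <- function(x, fs_from, fs_to) {
  drop(resample_fft_mat(cbind(x), fs_from, fs_to))
}

resample_fft_mat <- function(mat, fs_from, fs_to) {
  if (fs_from == fs_to) return(mat)
  n <- nrow(mat)
  n_out <- as.integer(round(n * fs_to / fs_from))
  X <- mvfft(mat)
  Y <- matrix(0i, nrow = n_out, ncol = ncol(mat))
  h <- floor((min(n, n_out) - 1) / 2)  # strictly below the smaller Nyquist
  Y[1, ] <- X[1, ]
  if (h >= 1) {
    Y[2:(h + 1), ] <- X[2:(h + 1), , drop = FALSE]
    Y[(n_out - h + 1):n_out, ] <- X[(n - h + 1):n, , drop = FALSE]
  }
  Re(mvfft(Y, inverse = TRUE)) / n
}

#' Preprocess an EEG recording
#'
#' Applies the standard staging preprocessing chain: zero-phase band-pass
#' (default 0.5-70 Hz, 48 dB/oct Butterworth magnitude) with a 50 Hz mains
#' notch, then resampling to 500 Hz and finally to 100 Hz (stages above the
#' input rate are skipped). Resampling is performed by Fourier
#' interpolation, an ideal anti-aliasing low-pass, so the 100 Hz output
#' carries no energy above 50 Hz. The effective low-pass cutoff is capped
#' at 0.45 x the sampling rate, which makes a second application of
#' `preprocess()` a near no-op in the passband (idempotence).
#'
#' EOG channels are high-passed at `eog_high_pass` (default 0.05 Hz)
#' instead of `high_pass`: slow horizontal eye movements live in the
#' 0.1-1 Hz band and would be destroyed by the 0.5 Hz scalp high-pass,
#' while the staging chain reads nothing else from the EOG.
#'
#' @param rec an [eeg_recording()].
#' @param high_pass,low_pass band edges, Hz.
#' @param notch mains frequency, Hz (`NULL` to disable).
#' @param target_rates successive resampling targets, Hz.
#' @param eog_high_pass high-pass edge for EOG channels, Hz.
#' @return A preprocessed [eeg_recording()] at the final target rate.
#' @export
preprocess <- function(rec, high_pass = 0.5, low_pass = 70, notch = 50,
                       target_rates = c(500, 100), eog_high_pass = 0.05) {
  fs <- rec$sampling_rate
  if (fs < 100)
    stopf("sampling rate %g Hz is too low for the %g Hz low-pass stage", fs, low_pass)
  lp <- min(low_pass, 0.45 * fs)
  # filtering and the resampling cascade are fused into a single spectral
  # pass: under ideal (Fourier) resampling, 1000 -> 500 -> 100 Hz equals a
  # single truncation to the final rate, and one real-input forward FFT +
  # one short inverse FFT is several times faster than chaining them
  reachable <- target_rates[target_rates < fs]
  fs_out <- if (length(reachable)) min(reachable) else fs
  n <- ncol(rec$data)
  n_out <- as.integer(round(n * fs_out / fs))
  X <- mvfft(t(rec$data))  # samples x channels
  f <- fft_freqs(n, fs)
  H0 <- 1 / sqrt(1 + (f / lp)^16)
  if (!is.null(notch)) H0 <- H0 * (1 - exp(-0.5 * ((f - notch) / 1)^2))
  hp_gain <- function(edge) 1 / sqrt(1 + (edge / pmax(f, fs / n / 4))^16)
  eog <- rec$channel_roles == "eog"
  if (any(!eog)) X[, !eog] <- X[, !eog, drop = FALSE] * (H0 * hp_gain(high_pass))
  if (any(eog)) X[, eog] <- X[, eog, drop = FALSE] *
      (H0 * hp_gain(min(eog_high_pass, high_pass)))
  if (n_out != n) {
    Y <- matrix(0i, nrow = n_out, ncol = ncol(X))
    h <- floor((n_out - 1) / 2)
    Y[1, ] <- X[1, ]
    if (h >= 1) {
      Y[2:(h + 1), ] <- X[2:(h + 1), , drop = FALSE]
      Y[(n_out - h + 1):n_out, ] <- X[(n - h + 1):n, , drop = FALSE]
    }
    X <- Y
  }
  out <- Re(mvfft(X, inverse = TRUE)) / n
  eeg_recording(t(out), fs_out, rec$channel_names, rec$channel_roles,
                rec$start_time)
}

#' Segment a recording into 1-second epochs
#'
#' Cuts the recording into consecutive, non-overlapping half-open
#' 1-second segments `[t, t+1)` (0-based); a trailing fraction of a second
#' is discarded. A 20-minute recording yields exactly 1200 segments.
#'
#' @param rec an [eeg_recording()].
#' @return An `epoch_grid`: list with `segments` (channels x samples x
#'   segments array), sampling rate, channel names/roles and all-`FALSE`
#'   `artifact` and `graphoelement` flag vectors.
#' @export
segment_recording <- function(rec) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stopf("segmentation requires an integer sampling rate")
  sp <- as.integer(fs)
  n_seg <- ncol(rec$data) %/% sp
  seg <- if (n_seg > 0) {
    a <- rec$data[, seq_len(n_seg * sp), drop = FALSE]
    dim(a) <- c(nrow(rec$data), sp, n_seg)
    a
  } else array(0, dim = c(nrow(rec$data), sp, 0))
  structure(list(segments = seg, sampling_rate = sp,
                 channel_names = rec$channel_names,
                 channel_roles = rec$channel_roles,
                 artifact = logical(n_seg), graphoelement = logical(n_seg)),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d segments x %d channels @ %d Hz; %d artifact, %d graphoelement\n",
              dim(x$segments)[3], dim(x$segments)[1], x$sampling_rate,
              sum(x$artifact), sum(x$graphoelement)))
  invisible(x)
}

# max / min over the sample dimension for a (channels x samples x segments)
# slab, flattened for speed
.seg_stat <- function(m, fun) {
  d <- dim(m)
  mm <- matrix(aperm(m, c(2, 1, 3)), nrow = d[2])
  apply(mm, 2, fun)
}

#' Flag artifact segments
#'
#' A segment is flagged when any non-EOG channel's peak-to-peak amplitude
#' exceeds `amp_threshold`, or when its cross-channel mean variance exceeds
#' `var_ratio` times the recording's median segment variance. This
#' amplitude/variance surrogate replaces manual ICA-based cleaning: the
#' staging chain only needs contaminated segments excluded, not repaired.
#' Flagged segments are labelled `ARTIFACT` by [classify_recording()] and
#' excluded from all scoring fractions.
#'
#' @param grid an `epoch_grid` from [segment_recording()].
#' @param amp_threshold peak-to-peak limit, uV.
#' @param var_ratio multiple of the median segment variance.
#' @return The grid with its `artifact` flags set.
#' @export
mark_artifacts <- function(grid, amp_threshold = 200, var_ratio = 16) {
  if (amp_threshold <= 0 || var_ratio <= 0) stopf("thresholds must be positive")
  n_seg <- dim(grid$segments)[3]
  if (n_seg == 0) return(grid)
  eeg <- which(grid$channel_roles != "eog")
  m <- grid$segments[eeg, , , drop = FALSE]
  d <- dim(m)
  p2p <- .seg_stat(m, function(v) max(v) - min(v))          # per channel x segment
  p2p <- matrix(p2p, nrow = d[1])
  seg_var <- colMeans(matrix(m, nrow = d[1] * d[2])^2) -
    colMeans(matrix(m, nrow = d[1] * d[2]))^2               # cross-channel variance
  flag <- apply(p2p, 2, max) > amp_threshold |
    seg_var > var_ratio * median(seg_var)
  grid$artifact <- unname(flag)
  grid
}

#' Detect sleep graphoelements (spindles, K-complexes)
#'
#' Automatic surrogate for expert graphoelement marking, operating on the
#' mean of the central-ROI channels:
#'
#' * **Spindle**: the sigma-band (11-16 Hz, brick-wall filtered) moving RMS
#'   (0.5 s window) exceeds `max(spindle_factor x median per-segment sigma
#'   RMS, spindle_min_rms)` somewhere in the segment - i.e. sigma power is
#'   elevated for about half a second.
#' * **K-complex**: the 0.3-2 Hz band-passed peak-to-peak amplitude of the
#'   segment exceeds `max(kc_min_amp, kc_factor x median segment
#'   peak-to-peak)` - a large biphasic transient against the recording's
#'   own slow-wave background.
#'
#' An annotation table (e.g. from human raters) can override/extend the
#' detector: all listed segments are flagged regardless of the signal.
#'
#' @param grid an `epoch_grid`.
#' @param sigma_band,spindle_factor,spindle_min_rms,spindle_window spindle
#'   detector parameters (Hz, factor, uV RMS floor, seconds).
#' @param kc_band,kc_factor,kc_min_amp K-complex detector parameters.
#' @param annotations optional data frame with column `segment_index`
#'   (0-based) and optionally `label`, or a path to such a TSV.
#' @return The grid with its `graphoelement` flags set.
#' @export
detect_graphoelements <- function(grid, sigma_band = c(11, 16),
                                  spindle_factor = 4, spindle_min_rms = 5,
                                  spindle_window = 0.5,
                                  kc_band = c(0.3, 2.0), kc_factor = 2,
                                  kc_min_amp = 60, annotations = NULL) {
  n_seg <- dim(grid$segments)[3]
  if (n_seg == 0) return(grid)
  central <- which(grid$channel_roles == "central")
  if (!length(central)) stopf("graphoelement detection requires central-ROI channels")
  sp <- grid$sampling_rate
  m <- grid$segments[central, , , drop = FALSE]
  cm <- colMeans(matrix(m, nrow = length(central)))  # continuous central mean

  sigma <- fft_brick_band(cm, sp, sigma_band[1], sigma_band[2])
  w <- max(3L, as.integer(round(spindle_window * sp)))
  mov <- stats::filter(sigma^2, rep(1 / w, w), sides = 2)
  mov[is.na(mov)] <- 0
  mov_rms <- sqrt(as.numeric(mov))
  seg_rms <- sqrt(colMeans(matrix(sigma^2, nrow = sp)))
  thr_sp <- max(spindle_factor * median(seg_rms), spindle_min_rms)
  spindle <- apply(matrix(mov_rms, nrow = sp), 2, max) >= thr_sp

  lf <- fft_brick_band(cm, sp, kc_band[1], kc_band[2])
  lfm <- matrix(lf, nrow = sp)
  seg_p2p <- apply(lfm, 2, function(v) max(v) - min(v))
  thr_kc <- max(kc_min_amp, kc_factor * median(seg_p2p))
  kcomplex <- seg_p2p >= thr_kc

  flag <- spindle | kcomplex
  if (!is.null(annotations)) {
    if (is.character(annotations)) annotations <- read.delim(annotations)
    if (!"segment_index" %in% names(annotations))
      stopf("annotation override needs a 'segment_index' column")
    idx <- annotations$segment_index + 1L
    if (any(idx < 1 | idx > n_seg)) stopf("annotation segment_index out of range")
    flag[idx] <- TRUE
  }
  grid$graphoelement <- unname(flag)
  attr(grid$graphoelement, "spindle") <- unname(spindle)
  attr(grid$graphoelement, "kcomplex") <- unname(kcomplex)
  grid
}

#' Serialize / load an epoch grid
#'
#' On-disk layout: one 32-bit float little-endian array per channel
#' (`<channel>.f32`, samples ordered segment-major), a `channels.tsv`
#' table (channel, role, file, sampling_rate) and a `flags.tsv` table
#' (segment_index, artifact, graphoelement).
#'
#' @param grid an `epoch_grid`.
#' @param dir target directory (created).
#' @return `dir` (resp. the reconstructed `epoch_grid`).
#' @export
write_epoch_grid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(gsub("[^A-Za-z0-9]", "_", grid$channel_names), ".f32")
  for (i in seq_along(grid$channel_names)) {
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(as.vector(grid$segments[i, , ]), con, size = 4, endian = "little")
    close(con)
  }
  write.table(data.frame(channel = grid$channel_names,
                         role = unname(grid$channel_roles),
                         file = files, sampling_rate = grid$sampling_rate),
              file.path(dir, "channels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(segment_index = seq_along(grid$artifact) - 1L,
                         artifact = grid$artifact,
                         graphoelement = grid$graphoelement),
              file.path(dir, "flags.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epoch_grid
#' @export
read_epoch_grid <- function(dir) {
  ch <- read.delim(file.path(dir, "channels.tsv"), stringsAsFactors = FALSE)
  fl <- read.delim(file.path(dir, "flags.tsv"), stringsAsFactors = FALSE)
  sp <- as.integer(ch$sampling_rate[1])
  n_seg <- nrow(fl)
  seg <- array(0, dim = c(nrow(ch), sp, n_seg))
  for (i in seq_len(nrow(ch))) {
    con <- file(file.path(dir, ch$file[i]), "rb")
    seg[i, , ] <- readBin(con, "numeric", n = sp * n_seg, size = 4,
                          endian = "little")
    close(con)
  }
  roles <- ch$role
  names(roles) <- ch$channel
  structure(list(segments = seg, sampling_rate = sp,
                 channel_names = ch$channel, channel_roles = roles,
                 artifact = as.logical(fl$artifact),
                 graphoelement = as.logical(fl$graphoelement)),
            class = "epoch_grid")
}
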