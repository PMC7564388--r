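#' Classifier thresholds
#'
#' Numeric thresholds of the vigilance stage cascade. These are this
#' package's defaults (tuned against the synthetic generator and exposed in
#' configuration), not constants taken from any published staging tool.
#'
#' @param alpha_dominance_fraction minimum alpha share of total 2-30 Hz
#'   power for an A-stage.
#' @param low_voltage_rms RMS amplitude (uV) below which a non-alpha
#'   segment counts as low-voltage.
#' @param delta_theta_ratio minimum delta+theta share of total power for
#'   B2/3.
#' @param sem_band slow-eye-movement band on the EOG channel, Hz.
#' @param sem_amp minimum smoothed EOG excursion (uV peak-to-peak within
#'   the second) for a slow eye movement.
#' @param alpha_band,delta_theta_band,total_band band edges in Hz
#'   (inclusive at 1 Hz periodogram resolution).
#' @return A validated list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(alpha_dominance_fraction = 0.4,
                                  low_voltage_rms = 10,
                                  delta_theta_ratio = 0.5,
                                  sem_band = c(0.1, 1.0), sem_amp = 60,
                                  alpha_band = c(8, 12),
                                  delta_theta_band = c(2, 7),
                                  total_band = c(2, 30)) {
  t <- list(alpha_dominance_fraction = alpha_dominance_fraction,
            low_voltage_rms = low_voltage_rms,
            delta_theta_ratio = delta_theta_ratio,
            sem_band = sem_band, sem_amp = sem_amp,
            alpha_band = alpha_band, delta_theta_band = delta_theta_band,
            total_band = total_band)
  assert_scalar_num(t$alpha_dominance_fraction, "alpha_dominance_fraction",
                    lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(t$delta_theta_ratio, "delta_theta_ratio",
                    lower = 1e-9, upper = 1 - 1e-9)
  if (t$low_voltage_rms <= 0 || t$sem_amp <= 0)
    stopf("amplitude thresholds must be positive")
  structure(t, class = "classifier_thresholds")
}

# Band power features for a (channels x samples x segments) slab at 1 Hz
# resolution (1-second windows). Returns a data.frame with one row per
# segment. Only ROI channels enter the spectral features; EOG channels
# drive SEM detection.
.slab_features <- function(slab, roles, sampling_rate, thresholds,
                           warn_no_eog = TRUE) {
  d <- dim(slab)
  sp <- d[2]; ns <- d[3]
  if (ns == 0)
    return(data.frame(alpha_occipital = numeric(0), alpha_central = numeric(0),
                      alpha_frontal = numeric(0), alpha_power = numeric(0),
                      delta_theta_power = numeric(0), total_power = numeric(0),
                      alpha_fraction = numeric(0), rms_amplitude = numeric(0),
                      sem_present = logical(0)))
  roi <- list(occipital = which(roles == "occipital"),
              central = which(roles == "central"),
              frontal = which(roles == "frontal"))
  roi_all <- unlist(roi)
  if (!length(roi_all)) stopf("no ROI channels (occipital/central/frontal) present")

  # one-sided periodogram per channel and segment: bin k is k Hz
  nk <- sp %/% 2
  band_idx <- function(band) {
    k <- seq_len(nk)
    which(k >= band[1] & k <= band[2])
  }
  pow <- array(0, dim = c(length(roi_all), nk, ns))
  for (j in seq_along(roi_all)) {
    M <- matrix(slab[roi_all[j], , ], nrow = sp, ncol = ns)
    F <- mvfft(M)
    pw <- (2 / sp^2) * Mod(F[2:(nk + 1), , drop = FALSE])^2
    pow[j, , ] <- pw
  }
  band_mean <- function(band, channels) {
    idx <- band_idx(band)
    if (!length(channels) || !length(idx)) return(numeric(ns))
    sub <- pow[match(channels, roi_all), idx, , drop = FALSE]
    apply(sub, 3, sum) / length(channels)
  }
  alpha_occ <- band_mean(thresholds$alpha_band, roi$occipital)
  alpha_cen <- band_mean(thresholds$alpha_band, roi$central)
  alpha_fro <- band_mean(thresholds$alpha_band, roi$frontal)
  alpha_all <- band_mean(thresholds$alpha_band, roi_all)
  dt_all <- band_mean(thresholds$delta_theta_band, roi_all)
  tot_all <- band_mean(thresholds$total_band, roi_all)

  roi_slab <- slab[roi_all, , , drop = FALSE]
  rms <- sqrt(colMeans(matrix(roi_slab, nrow = length(roi_all) * sp)^2))

  eog <- which(roles == "eog")
  if (length(eog)) {
    w <- max(3L, as.integer(round(0.3 * sp)))  # ~1/(3 x sem upper edge)
    sem_rng <- rep(0, ns)
    for (j in eog) {
      M <- matrix(slab[j, , ], nrow = sp, ncol = ns)
      M <- sweep(M, 2, colMeans(M))
      S <- apply(M, 2, function(v) {
        s <- stats::filter(v, rep(1 / w, w), sides = 2)
        s <- s[!is.na(s)]
        max(s) - min(s)
      })
      sem_rng <- pmax(sem_rng, S)
    }
    sem <- sem_rng >= thresholds$sem_amp
  } else {
    if (warn_no_eog) warning("no EOG channel: slow eye movements assumed absent",
                             call. = FALSE)
    sem <- rep(FALSE, ns)
  }
  data.frame(alpha_occipital = alpha_occ, alpha_central = alpha_cen,
             alpha_frontal = alpha_fro, alpha_power = alpha_all,
             delta_theta_power = dt_all, total_power = tot_all,
             alpha_fraction = ifelse(tot_all > 0, alpha_all / tot_all, 0),
             rms_amplitude = rms, sem_present = sem)
}

#' Compute spectral/EOG features of one 1-second segment
#'
#' Band powers come from the 1-second periodogram (1 Hz resolution), the
#' topography from per-ROI channel means, and slow-eye-movement presence
#' from the smoothed EOG excursion within the second. Deterministic.
#'
#' @param segment numeric matrix, channels x samples (one second), with
#'   channel names as row names.
#' @param roles named role vector (defaults to [channel_role_map()] of the
#'   row names).
#' @param sampling_rate Hz; defaults to the number of samples (1 s window).
#' @param thresholds a [classifier_thresholds()].
#' @param graphoelement_present logical, from [detect_graphoelements()].
#' @return An object of class `epoch_features`.
#' @export
compute_features <- function(segment, roles = NULL, sampling_rate = ncol(segment),
                             thresholds = classifier_thresholds(),
                             graphoelement_present = FALSE) {
  segment <- as.matrix(segment)
  if (is.null(roles)) {
    if (is.null(rownames(segment))) stopf("need channel roles or row names")
    roles <- channel_role_map(rownames(segment))
  }
  f <- .slab_features(array(segment, dim = c(nrow(segment), ncol(segment), 1L)),
                      roles, sampling_rate, thresholds)
  structure(c(as.list(f[1, ]),
              list(graphoelement_present = isTRUE(graphoelement_present))),
            class = "epoch_features")
}

#' Classify one segment's features into a vigilance stage
#'
#' Fixed decision cascade (first match wins):
#' 1. graphoelement present -> `C` (spindles/K-complexes mark sleep onset);
#' 2. delta+theta share above `delta_theta_ratio` and alpha not dominant ->
#'    `B2/3`;
#' 3. alpha dominant -> A-substage by the ROI with maximal alpha power
#'    (occipital `A1`, central `A2`, frontal `A3`; ties broken
#'    occipital > central > frontal);
#' 4. otherwise (low-voltage non-alpha EEG): `B1` if slow eye movements are
#'    present, else `0`.
#'
#' @param f an `epoch_features` object (or list with the same fields).
#' @param t a [classifier_thresholds()].
#' @return A single stage label.
#' @export
classify_stage <- function(f, t = classifier_thresholds()) {
  vals <- c(f$alpha_fraction, f$delta_theta_power, f$total_power, f$rms_amplitude)
  if (any(!is.finite(vals))) stopf("non-finite features")
  if (isTRUE(f$graphoelement_present)) return("C")
  dom <- f$alpha_fraction >= t$alpha_dominance_fraction
  dt_ratio <- if (f$total_power > 0) f$delta_theta_power / f$total_power else 0
  if (dt_ratio > t$delta_theta_ratio && !dom) return("B2/3")
  if (dom) {
    roi_alpha <- c(f$alpha_occipital, f$alpha_central, f$alpha_frontal)
    return(c("A1", "A2", "A3")[which.max(roi_alpha)])  # which.max: first max wins
  }
  # steps 4 and 5 of the cascade coincide: with or without the low-voltage
  # qualifier, a non-alpha non-B2/3 segment is B1 iff slow eye movements
  # are present
  if (isTRUE(f$sem_present)) "B1" else "0"
}

#' Classify a whole epoch grid into a stage sequence
#'
#' Artifact-flagged segments are labelled `ARTIFACT` and never classified;
#' every other segment goes through [classify_stage()]. Deterministic:
#' the same grid always yields the same sequence.
#'
#' @param grid an `epoch_grid`, after [mark_artifacts()] and
#'   [detect_graphoelements()].
#' @param thresholds a [classifier_thresholds()].
#' @return A [stage_sequence()] of the grid's length.
#' @export
classify_recording <- function(grid, thresholds = classifier_thresholds()) {
  ns <- dim(grid$segments)[3]
  feats <- .slab_features(grid$segments, grid$channel_roles,
                          grid$sampling_rate, thresholds)
  labels <- vapply(seq_len(ns), function(i) {
    if (grid$artifact[i]) return(ARTIFACT_LABEL)
    f <- c(as.list(feats[i, ]),
           list(graphoelement_present = grid$graphoelement[i]))
    classify_stage(f, thresholds)
  }, character(1))
  stage_sequence(labels, expected_length = ns)
}
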