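#' EEG synthesis configuration
#'
#' Amplitudes and frequencies of the stage-typical signatures written into
#' synthetic recordings. The stage definitions the generator emulates are
#' qualitative (dominant alpha with an occipital/central/frontal centre of
#' gravity; low-voltage EEG; high delta/theta power; spindles/K-complexes),
#' so the numeric amplitudes here are this package's defaults, chosen so
#' that the default classifier thresholds separate the stages with margin
#' while staying inside physiological ranges and below the artifact
#' rejection limits (see the methods vignette).
#'
#' @param sampling_rate Hz, >= 200 (default 1000, the acquisition rate the
#'   pipeline emulates).
#' @param channels character vector of channel labels; default is a 31-site
#'   extended 10-20 montage plus `HEOG`/`VEOG`.
#' @param alpha_freq alpha rhythm frequency, Hz.
#' @param alpha_amp_occipital peak alpha amplitude on the dominant ROI, uV.
#' @param low_voltage_amp extra broadband noise (sd, uV) in low-voltage
#'   stages 0 and B1.
#' @param delta_theta_amp total peak amplitude of the 2-7 Hz activity in
#'   stage B2/3 (and C background), uV.
#' @param spindle_freq,spindle_amp sleep spindle frequency (Hz) and peak
#'   amplitude (uV) on central channels.
#' @param kcomplex_amp peak amplitude of the K-complex's negative deflection
#'   (uV); the positive rebound is half that.
#' @param sem_freq slow horizontal eye movement frequency, Hz.
#' @param sem_amp_eog peak SEM amplitude on the HEOG channel, uV.
#' @param noise_amp baseline white noise sd on every channel, uV.
#' @return A validated list of class `synthesis_config`.
#' @export
synthesis_config <- function(sampling_rate = 1000, channels = default_montage(),
                             alpha_freq = 10, alpha_amp_occipital = 40,
                             low_voltage_amp = 8, delta_theta_amp = 35,
                             spindle_freq = 13, spindle_amp = 45,
                             kcomplex_amp = 80, sem_freq = 0.25,
                             sem_amp_eog = 250, noise_amp = 5) {
  cfg <- list(sampling_rate = sampling_rate, channels = channels,
              n_channels = length(channels),
              alpha_freq = alpha_freq,
              alpha_amp_occipital = alpha_amp_occipital,
              low_voltage_amp = low_voltage_amp,
              delta_theta_amp = delta_theta_amp,
              spindle_freq = spindle_freq, spindle_amp = spindle_amp,
              kcomplex_amp = kcomplex_amp,
              sem_freq = sem_freq, sem_amp_eog = sem_amp_eog,
              noise_amp = noise_amp)
  assert_scalar_num(cfg$sampling_rate, "sampling_rate", lower = 200)
  for (f in c("alpha_freq", "alpha_amp_occipital", "low_voltage_amp",
              "delta_theta_amp", "spindle_freq", "spindle_amp",
              "kcomplex_amp", "sem_freq", "sem_amp_eog", "noise_amp")) {
    assert_scalar_num(cfg[[f]], f)
    if (cfg[[f]] <= 0) stopf("'%s' must be positive", f)
  }
  roles <- channel_role_map(cfg$channels)
  for (r in c("occipital", "central", "frontal", "eog"))
    if (!r %in% roles) stopf("channel set has no '%s' channel", r)
  structure(cfg, class = "synthesis_config")
}

# Alpha amplitude gain per role, per A-substage. The dominant ROI carries
# the full amplitude; the others a fraction small enough that the ROI
# argmax is unambiguous after noise.
alpha_gains <- function(stage) {
  switch(stage,
    "A1" = c(occipital = 1.00, central = 0.30, frontal = 0.10, other = 0.30),
    "A2" = c(occipital = 0.35, central = 1.00, frontal = 0.35, other = 0.30),
    "A3" = c(occipital = 0.10, central = 0.35, frontal = 1.00, other = 0.30))
}

#' Synthesize a stage-faithful EEG recording
#'
#' Renders a multichannel EEG from a per-second stage script. Each second
#' carries its stage's signature on top of baseline white noise:
#'
#' * `0`: broadband low-voltage EEG, no slow EOG activity.
#' * `A1`/`A2`/`A3`: an alpha sinusoid whose amplitude peaks on the
#'   occipital / central / frontal ROI respectively.
#' * `B1`: low-voltage EEG plus a slow (`sem_freq` Hz) horizontal sweep on
#'   the HEOG channel.
#' * `B2/3`: diffuse 2-7 Hz (delta/theta) activity on all scalp channels.
#' * `C`: B2/3 background plus a graphoelement on central channels - a
#'   sleep spindle burst (0.8 s, `spindle_freq` Hz, Hann envelope) or, with
#'   probability 0.3, a biphasic K-complex-like transient (0.7 s).
#'
#' Generation is fully reproducible given `seed`.
#'
#' @param script a `stage_script` or [stage_sequence()] without artifact
#'   labels.
#' @param config a [synthesis_config()].
#' @param seed integer seed.
#' @param duration_s number of leading script seconds to render (default:
#'   all). Shorter renders are used in tests to keep runtimes down.
#' @return An [eeg_recording()].
#' @examples
#' sc <- generate_stage_script("hyperaroused", seed = 1)
#' rec <- synthesize_eeg(sc, synthesis_config(sampling_rate = 250), seed = 1,
#'                       duration_s = 10)
#' @export
synthesize_eeg <- function(script, config = synthesis_config(), seed = 1L,
                           duration_s = NULL) {
  if (!inherits(script, "stage_sequence")) script <- stage_sequence(script)
  labels <- as.character(unclass(script))
  if (ARTIFACT_LABEL %in% labels)
    stopf("cannot synthesize from a sequence containing ARTIFACT labels")
  if (!is.null(duration_s)) {
    assert_scalar_num(duration_s, "duration_s", lower = 1)
    labels <- labels[seq_len(min(length(labels), floor(duration_s)))]
  }
  fs <- config$sampling_rate
  if (fs != round(fs)) stopf("sampling_rate must be an integer number of Hz")
  fs <- as.integer(fs)
  n_sec <- length(labels)
  chans <- config$channels
  roles <- channel_role_map(chans)
  eeg_idx <- which(roles != "eog")
  heog_idx <- which(toupper(chans) == "HEOG")
  if (!length(heog_idx)) heog_idx <- which(roles == "eog")[1]
  central_idx <- which(roles == "central")
  frontal_idx <- which(roles == "frontal")

  withr::with_seed(as.integer(seed), {
    x <- matrix(rnorm(length(chans) * n_sec * fs, sd = config$noise_amp),
                nrow = length(chans))
    tt <- (seq_len(fs) - 1) / fs
    # delta/theta component frequencies are fixed per recording
    dt_freq <- sort(runif(3, 2.2, 6.8))
    dt_amp <- config$delta_theta_amp * c(0.5, 0.3, 0.2)
    # one global slow-eye-movement oscillator keeps SEM phase coherent
    # across contiguous B1 seconds
    sem_phase0 <- runif(1, 0, 2 * pi)

    for (s in seq_len(n_sec)) {
      st <- labels[s]
      cols <- ((s - 1) * fs + 1):(s * fs)
      if (st %in% c("0", "B1")) {
        x[eeg_idx, cols] <- x[eeg_idx, cols] +
          matrix(rnorm(length(eeg_idx) * fs, sd = config$low_voltage_amp),
                 nrow = length(eeg_idx))
        if (st == "B1") {
          sem <- config$sem_amp_eog *
            sin(2 * pi * config$sem_freq * (s - 1 + tt) + sem_phase0)
          x[heog_idx[1], cols] <- x[heog_idx[1], cols] + sem
        }
      } else if (st %in% A_STAGES) {
        g <- alpha_gains(st)
        wave <- sin(2 * pi * config$alpha_freq * tt + runif(1, 0, 2 * pi))
        amp <- config$alpha_amp_occipital * g[roles[eeg_idx]]
        x[eeg_idx, cols] <- x[eeg_idx, cols] + outer(unname(amp), wave)
      } else {  # B2/3 or C
        ph <- runif(3, 0, 2 * pi)
        dt <- dt_amp[1] * sin(2 * pi * dt_freq[1] * tt + ph[1]) +
              dt_amp[2] * sin(2 * pi * dt_freq[2] * tt + ph[2]) +
              dt_amp[3] * sin(2 * pi * dt_freq[3] * tt + ph[3])
        # per-channel random polarity stands in for spatially varying phase
        pol <- sample(c(-1, 1), length(eeg_idx), replace = TRUE)
        x[eeg_idx, cols] <- x[eeg_idx, cols] + outer(pol, dt)
        if (st == "C") {
          ev <- synth_graphoelement(fs, config)
          x[central_idx, cols] <- x[central_idx, cols] +
            matrix(ev$wave, nrow = length(central_idx), ncol = fs, byrow = TRUE)
          if (ev$type == "kcomplex" && length(frontal_idx))
            x[frontal_idx, cols] <- x[frontal_idx, cols] +
              0.7 * matrix(ev$wave, nrow = length(frontal_idx), ncol = fs,
                           byrow = TRUE)
        }
      }
    }
    eeg_recording(x, fs, chans, roles)
  })
}

# One graphoelement, centred in a 1-s window: a spindle burst (p = 0.7) or
# a biphasic K-complex-like transient (sharp negative deflection followed
# by a slower positive rebound at half amplitude).
synth_graphoelement <- function(fs, config) {
  wave <- numeric(fs)
  if (runif(1) < 0.7) {
    dur <- round(0.8 * fs)
    t0 <- floor((fs - dur) / 2)
    tt <- (seq_len(dur) - 1) / fs
    env <- sin(pi * seq_len(dur) / dur)^2
    wave[t0 + seq_len(dur)] <- config$spindle_amp * env *
      sin(2 * pi * config$spindle_freq * tt)
    list(type = "spindle", wave = wave)
  } else {
    neg <- round(0.30 * fs); pos <- round(0.40 * fs)
    t0 <- floor((fs - neg - pos) / 2)
    wave[t0 + seq_len(neg)] <- -config$kcomplex_amp * sin(pi * seq_len(neg) / neg)
    wave[t0 + neg + seq_len(pos)] <-
      0.5 * config$kcomplex_amp * sin(pi * seq_len(pos) / pos)
    list(type = "kcomplex", wave = wave)
  }
}
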