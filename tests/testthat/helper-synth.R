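# Reduced montage + rate used throughout the tests: one channel per ROI
# triple plus HEOG keeps every staging feature exercised at a fraction of
# the 33-channel / 1000 Hz cost.
small_montage <- function() {
  c("F3", "Fz", "F4", "C3", "Cz", "C4", "O1", "Oz", "O2", "HEOG")
}

quick_config <- function(sampling_rate = 250) {
  synthesis_config(sampling_rate = sampling_rate, channels = small_montage())
}

# synthesize -> preprocess -> segment -> flag -> classify
stage_recording <- function(script, seed, config = quick_config(),
                            duration_s = NULL) {
  rec <- synthesize_eeg(script, config, seed = seed, duration_s = duration_s)
  grid <- segment_recording(preprocess(rec))
  grid <- detect_graphoelements(mark_artifacts(grid))
  classify_recording(grid)
}

# A 1-second test segment: named sinusoids per channel plus optional noise.
sine_segment <- function(channels, amps, freq = 10, fs = 100, noise = 0,
                         phase = 0) {
  tt <- (seq_len(fs) - 1) / fs
  x <- matrix(rnorm(length(channels) * fs, sd = noise), nrow = length(channels))
  for (i in seq_along(channels))
    x[i, ] <- x[i, ] + amps[i] * sin(2 * pi * freq * tt + phase)
  rownames(x) <- channels
  x
}
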