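# Epoch features and the stage classification cascade.

test_that("pure occipital alpha yields dominant occipital alpha features", {
  seg <- sine_segment(c("O1", "C3", "F3", "HEOG"), c(20, 0, 0, 0), freq = 10)
  f <- compute_features(seg)
  expect_gt(f$alpha_fraction, 0.9)
  expect_gt(f$alpha_occipital, f$alpha_central)
  expect_gt(f$alpha_occipital, f$alpha_frontal)
  expect_equal(f$alpha_occipital, 20^2 / 2, tolerance = 1e-6)
  expect_identical(classify_stage(f), "A1")
})

test_that("zero signal gives zero powers and alpha fraction zero", {
  seg <- matrix(0, 4, 100,
                dimnames = list(c("O1", "C3", "F3", "HEOG"), NULL))
  f <- compute_features(seg)
  expect_equal(f$total_power, 0)
  expect_equal(f$alpha_fraction, 0)
  expect_identical(classify_stage(f), "0")
})

test_that("slow EOG sweeps are detected as SEM and drive B1", {
  channels <- c("O1", "C3", "F3", "HEOG")
  seg <- sine_segment(channels, c(0, 0, 0, 0), noise = 5)
  tt <- (0:99) / 100
  # quarter cycle through the zero crossing: excursion ~ full amplitude
  seg["HEOG", ] <- seg["HEOG", ] + 250 * sin(2 * pi * 0.25 * tt)
  f <- compute_features(seg)
  expect_true(f$sem_present)
  expect_identical(classify_stage(f), "B1")

  # same scalp without the sweep: stage 0
  seg["HEOG", ] <- rnorm(100, sd = 5)
  f0 <- compute_features(seg)
  expect_false(f0$sem_present)
  expect_identical(classify_stage(f0), "0")
})

test_that("missing EOG warns and disables SEM", {
  seg <- sine_segment(c("O1", "C3", "F3"), c(0, 0, 0), noise = 5)
  expect_warning(f <- compute_features(seg), "EOG")
  expect_false(f$sem_present)
})

test_that("the cascade follows its fixed priorities", {
  t <- classifier_thresholds()
  base <- list(alpha_occipital = 1, alpha_central = 0, alpha_frontal = 0,
               alpha_power = 1, delta_theta_power = 0, total_power = 10,
               alpha_fraction = 0.1, rms_amplitude = 5, sem_present = FALSE,
               graphoelement_present = FALSE)
  # graphoelement always wins
  f <- modifyList(base, list(graphoelement_present = TRUE, alpha_fraction = 0.9))
  expect_identical(classify_stage(f, t), "C")
  # B2/3 when delta/theta dominates and alpha does not
  f <- modifyList(base, list(delta_theta_power = 8, alpha_fraction = 0.1))
  expect_identical(classify_stage(f, t), "B2/3")
  # alpha dominance beats the delta/theta rule
  f <- modifyList(base, list(delta_theta_power = 8, alpha_fraction = 0.8))
  expect_identical(classify_stage(f, t), "A1")
  # A-substage by ROI argmax, ties broken towards occipital
  f <- modifyList(base, list(alpha_fraction = 0.8, alpha_central = 2))
  expect_identical(classify_stage(f, t), "A2")
  f <- modifyList(base, list(alpha_fraction = 0.8, alpha_frontal = 3))
  expect_identical(classify_stage(f, t), "A3")
  f <- modifyList(base, list(alpha_fraction = 0.8, alpha_central = 1,
                             alpha_frontal = 1))
  expect_identical(classify_stage(f, t), "A1")
  # low-voltage split on SEM
  f <- modifyList(base, list(sem_present = TRUE))
  expect_identical(classify_stage(f, t), "B1")
  expect_error(classify_stage(modifyList(base, list(total_power = NaN)), t),
               "non-finite")
})

test_that("every random feature vector gets exactly one known label", {
  t <- classifier_thresholds()
  withr::with_seed(31, {
    for (i in 1:200) {
      a <- c(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50))
      f <- list(alpha_occipital = a[1], alpha_central = a[2],
                alpha_frontal = a[3], alpha_power = mean(a),
                delta_theta_power = runif(1, 0, 100),
                total_power = runif(1, 1, 200),
                alpha_fraction = runif(1), rms_amplitude = runif(1, 0, 60),
                sem_present = runif(1) < 0.5,
                graphoelement_present = runif(1) < 0.2)
      lab <- classify_stage(f, t)
      expect_length(lab, 1)
      expect_true(lab %in% vigilance_stages())
      if (f$graphoelement_present) expect_identical(lab, "C")
    }
  })
})

test_that("raising alpha never demotes an A-stage to a non-A stage", {
  t <- classifier_thresholds()
  withr::with_seed(32, {
    for (i in 1:100) {
      f <- list(alpha_occipital = runif(1, 0, 20),
                alpha_central = runif(1, 0, 20),
                alpha_frontal = runif(1, 0, 20),
                alpha_power = NA, delta_theta_power = runif(1, 0, 50),
                total_power = NA, alpha_fraction = NA,
                rms_amplitude = runif(1, 0, 40),
                sem_present = runif(1) < 0.5, graphoelement_present = FALSE)
      other <- f$delta_theta_power + runif(1, 0, 50)
      alpha0 <- sum(f$alpha_occipital, f$alpha_central, f$alpha_frontal)
      mk <- function(gain) {
        g <- f
        for (nm in c("alpha_occipital", "alpha_central", "alpha_frontal"))
          g[[nm]] <- g[[nm]] * gain
        g$alpha_power <- alpha0 * gain / 3
        g$total_power <- other + alpha0 * gain
        g$alpha_fraction <- alpha0 * gain / g$total_power
        g
      }
      l1 <- classify_stage(mk(1), t)
      l4 <- classify_stage(mk(4), t)
      if (l1 %in% c("A1", "A2", "A3")) expect_true(l4 %in% c("A1", "A2", "A3"))
    }
  })
})

test_that("classify_recording respects artifacts and is deterministic", {
  sc <- stage_sequence(rep("A1", 20), expected_length = NULL)
  rec <- synthesize_eeg(sc, quick_config(), seed = 9)
  grid <- detect_graphoelements(mark_artifacts(segment_recording(preprocess(rec))))
  s1 <- classify_recording(grid)
  s2 <- classify_recording(grid)
  expect_identical(unclass(s1), unclass(s2))
  expect_gte(mean(unclass(s1) %in% c("A1", "A2", "A3")), 0.95)

  grid$artifact[] <- TRUE
  s3 <- classify_recording(grid)
  expect_true(all(unclass(s3) == "ARTIFACT"))
  expect_identical(attr(s3, "n_classified"), 0L)
})

test_that("stage recovery on one clean mixed recording is high", {
  sc <- generate_stage_script("declining",
                              emergence = list(b1 = 2, b23 = 4, c = 6), seed = 12)
  pred <- stage_recording(sc, seed = 12, duration_s = 420)
  truth <- as.character(unclass(sc))[1:420]
  predc <- as.character(unclass(pred))
  keep <- predc != "ARTIFACT"
  expect_gte(mean(predc[keep] == truth[keep]), 0.9)
})
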