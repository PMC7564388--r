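# Arousal Stability scoring: worked examples, row combination, artifact
# handling, and the property suite (monotonicity, dominance, oracle
# equivalence).

seq_of <- function(labels) stage_sequence(labels)

test_that("worked examples reproduce the scoring table", {
  all_a1 <- rep("A1", 1200)
  expect_identical(arousal_stability_score(seq_of(all_a1))$score, 14L)

  # A-predominant but not A1-predominant
  expect_identical(arousal_stability_score(seq_of(rep("A2", 1200)))$score, 13L)

  # B1 >= 1/3 of minute 1
  s <- all_a1; s[1:20] <- "B1"
  expect_identical(arousal_stability_score(seq_of(s))$score, 9L)

  # single C in block 1 (minute 2)
  s <- all_a1; s[101] <- "C"
  res <- arousal_stability_score(seq_of(s))
  expect_identical(res$score, 1L)
  expect_identical(res$group, "non_hyperaroused")

  # B2/3 emergence per block: scores 5-8
  for (b in 1:4) {
    s <- all_a1
    first_min <- (b - 1) * 5 + 1
    s[((first_min - 1) * 60 + 1):((first_min - 1) * 60 + 20)] <- "B2/3"
    expect_identical(arousal_stability_score(seq_of(s))$score, 4L + b)
  }

  # combination: minimum fired row wins (B1 in min 1 -> 9, C in min 18 -> 4)
  s <- all_a1; s[1:20] <- "B1"; s[17 * 60 + 10] <- "C"
  expect_identical(arousal_stability_score(seq_of(s))$score, 4L)
})

test_that("exactly 2/3 predominance does not fire rows 13/14", {
  # 40 of 60 segments in {0, A1} is not *more than* 2/3
  minute <- c(rep("A1", 40), rep("B1", 10), rep("B2/3", 10))
  s <- rep(minute, 20)
  res <- arousal_stability_score(seq_of(s))
  expect_false(13L %in% res$fired_rows)
  expect_false(14L %in% res$fired_rows)
})

test_that("fallback fires when no row does", {
  # diffuse sub-threshold B1: 15 of 60 per minute (< 1/3), breaking 13/14
  # requires > 1/3 non-{0,A} -> use 25% B1 + 10% B2/3 diffuse... easier:
  # 15 B1 + 10 B2/3 per minute = 25/60 non-A > 1/3, both below emergence
  minute <- c(rep("A1", 35), rep("B1", 15), rep("B2/3", 10))
  s <- rep(minute, 20)
  res <- arousal_stability_score(seq_of(s))
  expect_identical(res$score, 12L)
  expect_true(res$fallback_used)
  expect_identical(res$group, "non_hyperaroused")
})

test_that("epoch fractions handle artifacts and unevaluable epochs", {
  fr <- epoch_fractions(seq_of(rep("A1", 1200)))
  expect_equal(fr$A1, rep(1, 20))
  expect_equal(fr$block, rep(1:4, each = 5))

  s <- rep("A1", 1200); s[1:20] <- "B1"
  fr <- epoch_fractions(seq_of(s))
  expect_equal(fr$B1[1], 1 / 3)

  # minute 5 fully artifact: unevaluable, others untouched
  s <- rep("A1", 1200); s[241:300] <- "ARTIFACT"
  fr <- epoch_fractions(seq_of(s))
  expect_false(fr$evaluable[5])
  expect_equal(fr$A1[-5], rep(1, 19))
  expect_identical(arousal_stability_score(seq_of(s))$score, 14L)

  # fractions are over classified segments only: 10 B1 of 30 classified
  s <- rep("A1", 1200); s[1:30] <- "ARTIFACT"; s[31:40] <- "B1"
  expect_identical(arousal_stability_score(seq_of(s))$score, 9L)
})

test_that("degenerate sequences error", {
  expect_error(arousal_stability_score(seq_of(rep("ARTIFACT", 1200))),
               "unscorable")
  expect_error(arousal_stability_score(stage_sequence(rep("A1", 600),
                                                      expected_length = 600)),
               "1200")
})

test_that("group assignment dichotomizes exactly at the cutoff", {
  expect_identical(assign_group(13L), "hyperaroused")
  expect_identical(assign_group(14L), "hyperaroused")
  expect_identical(assign_group(12L), "non_hyperaroused")
  expect_identical(assign_group(1L), "non_hyperaroused")
  expect_error(assign_group(0L), "1..14")
  expect_error(assign_group(15L), "1..14")
  expect_identical(assign_group(10L, scoring_rules(cutoff = 10)), "hyperaroused")
})

test_that("delaying an emergence by one block raises the score by one", {
  base <- rep("A1", 1200)
  for (stage in c("B1", "B2/3")) {
    scores <- vapply(1:4, function(b) {
      s <- base
      i0 <- ((b - 1) * 5) * 60  # first minute of block b
      s[(i0 + 1):(i0 + 25)] <- stage
      arousal_stability_score(seq_of(s))$score
    }, integer(1))
    expect_equal(diff(scores), rep(1L, 3), info = stage)
  }
  scores_c <- vapply(1:4, function(b) {
    s <- base; s[((b - 1) * 5) * 60 + 30] <- "C"
    arousal_stability_score(seq_of(s))$score
  }, integer(1))
  expect_equal(scores_c, 1:4)
})

test_that("adding a C segment never increases the score", {
  withr::with_seed(99, {
    for (i in 1:50) {
      labels <- random_labels()
      s0 <- arousal_stability_score(seq_of(labels))$score
      j <- sample(which(labels != "ARTIFACT"), 1)
      labels[j] <- "C"
      s1 <- arousal_stability_score(seq_of(labels))$score
      expect_lte(s1, s0)
    }
  })
})

test_that("score always lies in 1..14 and matches the brute-force oracle", {
  withr::with_seed(4711, {
    for (i in 1:200) {
      labels <- random_labels(artifact_prob = runif(1, 0, 0.1))
      res <- arousal_stability_score(seq_of(labels))
      expect_gte(res$score, 1L)
      expect_lte(res$score, 14L)
      expect_identical(res$score, as.integer(oracle_stability_score(labels)))
      expect_identical(res$group, assign_group(res$score))
    }
  })
})

test_that("stage sequence TSV round-trips", {
  s <- seq_of(random_labels())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stage_sequence(s, path)
  s2 <- read_stage_sequence(path)
  expect_identical(as.character(unclass(s2)), as.character(unclass(s)))
  expect_identical(attr(s2, "n_classified"), attr(s, "n_classified"))
})
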