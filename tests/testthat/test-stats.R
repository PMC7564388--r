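# Group statistics layer.

test_that("one-way ANOVA F equals the squared pooled t for two groups", {
  withr::with_seed(101, {
    for (i in 1:20) {
      x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2))
      y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2))
      a <- one_way_anova(c(x, y), rep(c("g1", "g2"), c(length(x), length(y))))
      tt <- t.test(x, y, var.equal = TRUE)
      expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
      expect_equal(a$p, tt$p.value, tolerance = 1e-12)
    }
  })
})

test_that("one-way ANOVA matches the linear-model decomposition", {
  withr::with_seed(102, {
    y <- rnorm(40); g <- sample(c("a", "b", "c"), 40, replace = TRUE)
    a <- one_way_anova(y, g)
    ref <- anova(lm(y ~ g))
    expect_equal(a$F, ref[1, "F value"], tolerance = 1e-12)
    expect_equal(a$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
    expect_equal(a$df_between, ref[1, "Df"])
  })
})

test_that("one-way ANOVA degenerate and error cases", {
  a <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$eta_sq_partial, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), ">= 2 observations")
  # one-tailed halves the two-tailed p
  y <- c(rnorm(10), rnorm(10, 2)); g <- rep(c("a", "b"), each = 10)
  expect_equal(one_way_anova(y, g, tails = "one")$p,
               one_way_anova(y, g)$p / 2)
})

test_that("two-way ANOVA agrees with the classical table on balanced data", {
  withr::with_seed(103, {
    a <- gl(2, 20); b <- rep(gl(2, 10), 2)
    y <- rnorm(40) + as.numeric(a) * 1.2 + as.numeric(b) * 0.5
    out <- two_way_anova(y, a, b)
    ref <- anova(lm(y ~ a * b))  # Type I == Type III when balanced
    expect_equal(out["group", "F"], ref["a", "F value"], tolerance = 1e-10)
    expect_equal(out["gender", "F"], ref["b", "F value"], tolerance = 1e-10)
    expect_equal(out["interaction", "F"], ref["a:b", "F value"],
                 tolerance = 1e-10)
    expect_equal(out$df_residual, rep(36L, 3))
  })
})

test_that("two-way ANOVA rejects degenerate designs", {
  y <- rnorm(12)
  a <- rep(c("h", "n"), each = 6)
  b <- c(rep("f", 5), "m", rep("f", 4), rep("m", 2))  # one cell has n = 1
  expect_error(two_way_anova(y, a, b), ">= 2 observations")
  b2 <- c(rep("f", 6), rep("m", 6))  # empty crossed cells
  expect_error(two_way_anova(y, a, b2), "empty design cell")
  expect_error(two_way_anova(y, a, rep("f", 12)), ">= 2 levels")
})

test_that("Levene's test behaves under equal and unequal spread", {
  x <- rep(c(3, 5, 9), 4)
  g <- rep(c("a", "b"), each = 6)
  expect_equal(levene_test(x, g)$F, 0)

  withr::with_seed(104, {
    reject_equal <- mean(replicate(400, {
      levene_test(c(rnorm(50), rnorm(50)), rep(c("a", "b"), each = 50))$p < 0.05
    }))
    # nominal type-I error 5%: allow Monte-Carlo margin (400 reps)
    expect_lt(reject_equal, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
    reject_unequal <- mean(replicate(200, {
      levene_test(c(rnorm(50, sd = 1), rnorm(50, sd = 3)),
                  rep(c("a", "b"), each = 50))$p < 0.05
    }))
    expect_gte(reject_unequal, 0.95)
  })
})

test_that("chi-squared reproduces hand-computed expectations", {
  tab <- matrix(c(14, 19, 5, 22), 2)  # gender x arousal-group counts
  res <- chi_square_2x2(tab)
  expect_equal(round(res$statistic, 2), 3.92)
  expect_equal(res$df, 1L)
  # oracle: sum((O-E)^2/E) against stats::chisq.test without correction
  withr::with_seed(105, {
    for (i in 1:20) {
      m <- matrix(rpois(4, 15) + 1, 2)
      ours <- chi_square_2x2(m)
      ref <- suppressWarnings(chisq.test(m, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      # invariance to transposition and to swapping both label orders
      expect_equal(chi_square_2x2(t(m))$statistic, ours$statistic)
      expect_equal(chi_square_2x2(m[2:1, 2:1])$statistic, ours$statistic)
    }
  })
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Mann-Whitney basics: ties, orientation, degenerate input", {
  m <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$Z, 0)
  expect_equal(m$p, 1)
  # complete separation, first sample smaller -> U = 0
  m <- mann_whitney(c(1, 2, 3), c(10, 20, 30))
  expect_equal(m$U, 0)
  expect_equal(mann_whitney(c(10, 20, 30), c(1, 2, 3))$U, 9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # all values tied: zero variance handled
  expect_equal(mann_whitney(rep(1, 4), rep(1, 5))$Z, 0)
})

test_that("Mann-Whitney exact p matches brute-force enumeration", {
  exact_oracle <- function(x, y) {
    vals <- c(x, y); n1 <- length(x); n <- length(vals)
    r <- rank(vals); mu <- n1 * (n - n1) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(utils::combn(n, n1), 2,
                function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
  withr::with_seed(106, {
    for (i in 1:30) {
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      x <- sample(0:5, n1, replace = TRUE)
      y <- sample(0:5, n2, replace = TRUE)
      m <- mann_whitney(x, y)
      expect_equal(m$p_exact, exact_oracle(x, y), tolerance = 1e-12)
    }
    # continuous data too
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(mann_whitney(x, y)$p_exact, exact_oracle(x, y),
                 tolerance = 1e-12)
  })
  # above the exact limit the field is NA
  expect_true(is.na(mann_whitney(rnorm(20), rnorm(20))$p_exact))
})

test_that("Mann-Whitney Z agrees with large-sample software conventions", {
  withr::with_seed(107, {
    x <- round(rnorm(25, 1), 1); y <- round(rnorm(30), 1)
    m <- mann_whitney(x, y)
    # wilcox.test's normal approximation with continuity correction brackets
    # our uncorrected p
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(m$p, ref$p.value, tolerance = 1e-10)
    expect_equal(m$U, unname(ref$statistic))
  })
})

test_that("screening metrics reproduce the printed screen and conserve counts", {
  test_pos <- c(rep(TRUE, 19), rep(FALSE, 41))
  cond <- c(rep(TRUE, 4), rep(FALSE, 56))  # all 4 cases screen positive
  m <- screening_metrics(test_pos, cond)
  expect_equal(m$sensitivity, 1)
  expect_equal(round(100 * m$specificity), 73)
  expect_equal(round(m$auc_binary, 2), 0.87)
  expect_equal(round(m$youden, 1), 0.7)
  expect_equal(m$auc_binary, (m$sensitivity + m$specificity) / 2)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 60)

  perfect <- screening_metrics(cond, cond)
  expect_equal(perfect$youden, 1)
  all_pos <- screening_metrics(rep(TRUE, 60), cond)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$youden, 0)
  expect_error(screening_metrics(test_pos, rep(FALSE, 60)), "no cases")
  expect_error(screening_metrics(test_pos, rep(TRUE, 60)), "no non-cases")
})

test_that("graded ROC AUC is the rank probability", {
  score <- c(1, 2, 3, 10, 11)
  cond <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(score, cond), 1)
  withr::with_seed(108, {
    s <- rnorm(40); cnd <- rep(c(TRUE, FALSE), 20)
    expect_equal(roc_auc(s, cnd),
                 unname(mann_whitney(s[cnd], s[!cnd])$U) / (20 * 20))
  })
})
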