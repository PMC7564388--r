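#' One-way ANOVA with partial eta squared
#'
#' Classical between/within decomposition. For two groups the F statistic
#' is exactly the square of the pooled-variance two-sample t statistic.
#' Partial eta squared is `SS_between / (SS_between + SS_within)`.
#'
#' @param values numeric outcome vector.
#' @param groups group labels (any number of levels, each with >= 2
#'   observations).
#' @param tails `"two"` (default) or `"one"`: the main hypothesis test in
#'   arousal-regulation designs is conventionally reported one-tailed; for
#'   a 2-level factor the one-tailed p is half the F-test p when the effect
#'   is in the hypothesized direction.
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `eta_sq_partial`, `group_means`.
#' @export
one_way_anova <- function(values, groups, tails = c("two", "one")) {
  tails <- match.arg(tails)
  g <- factor(groups)
  if (length(values) != length(g)) stopf("values and groups differ in length")
  n_per <- table(g)
  if (nlevels(g) < 2) stopf("need at least two groups")
  if (any(n_per < 2))
    stopf("every group needs >= 2 observations (violated: %s)",
          paste(names(n_per)[n_per < 2], collapse = ", "))
  gm <- tapply(values, g, mean)
  grand <- mean(values)
  ss_b <- sum(n_per * (gm - grand)^2)
  ss_w <- sum((values - gm[g])^2)
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  f <- if (ss_w == 0) {
    if (ss_b == 0) 0 else Inf
  } else (ss_b / df_b) / (ss_w / df_w)
  p <- pf(f, df_b, df_w, lower.tail = FALSE)
  if (tails == "one") p <- p / 2
  structure(list(F = f, df_between = df_b, df_within = df_w, p = p,
                 eta_sq_partial = if (ss_b + ss_w == 0) 0 else ss_b / (ss_b + ss_w),
                 group_means = gm, tails = tails),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g (%s-tailed), partial eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$tails, x$eta_sq_partial))
  invisible(x)
}

#' Two-way ANOVA (Type III sums of squares)
#'
#' Unbalanced-design two-factor ANOVA with interaction, using the
#' model-comparison (Type III) convention under sum-to-zero contrasts:
#' each effect's sum of squares is the increase in residual sum of squares
#' when its columns are dropped from the full interaction model. This
#' matches the default of mainstream commercial statistics packages for
#' this design. Partial eta squared per effect is
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param values numeric outcome.
#' @param group,gender two factors; every crossed cell needs >= 2
#'   observations.
#' @return A data.frame with rows `group`, `gender`, `interaction`:
#'   columns `F`, `df`, `df_residual`, `p`, `eta_sq_partial`.
#' @export
two_way_anova <- function(values, group, gender) {
  a <- factor(group); b <- factor(gender)
  if (nlevels(a) < 2 || nlevels(b) < 2) stopf("both factors need >= 2 levels")
  cell_n <- table(a, b)
  if (any(cell_n == 0)) stopf("empty design cell(s): %s",
                              paste(which(cell_n == 0), collapse = ", "))
  if (any(cell_n < 2)) stopf("every design cell needs >= 2 observations")
  df <- data.frame(y = values, a = a, b = b)
  ctr <- list(a = "contr.sum", b = "contr.sum")
  full <- lm(y ~ a * b, data = df, contrasts = ctr)
  rss_full <- sum(residuals(full)^2)
  df_res <- df.residual(full)
  drop1_ss <- function(term) {
    X <- model.matrix(full)
    asg <- attr(X, "assign")
    labs <- attr(terms(full), "term.labels")
    keep <- asg != match(term, labs)
    fit <- lm.fit(X[, keep, drop = FALSE], df$y)
    sum(fit$residuals^2) - rss_full
  }
  terms_map <- c(group = "a", gender = "b", interaction = "a:b")
  out <- do.call(rbind, lapply(names(terms_map), function(nm) {
    ss <- drop1_ss(terms_map[[nm]])
    dfe <- if (nm == "interaction") (nlevels(a) - 1) * (nlevels(b) - 1)
           else nlevels(if (nm == "group") a else b) - 1
    f <- (ss / dfe) / (rss_full / df_res)
    data.frame(effect = nm, F = f, df = dfe, df_residual = df_res,
               p = pf(f, dfe, df_res, lower.tail = FALSE),
               eta_sq_partial = ss / (ss + rss_full))
  }))
  rownames(out) <- out$effect
  out
}

#' Levene's test for homogeneity of variance
#'
#' Mean-centred version (absolute deviations from the group means, as used
#' by mainstream commercial packages), tested with a one-way ANOVA.
#'
#' @param values numeric outcome.
#' @param groups group labels, >= 2 observations each.
#' @return List with `F`, `df`, `p`.
#' @export
levene_test <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) < 2)) stopf("every group needs >= 2 observations")
  z <- abs(values - tapply(values, g, mean)[g])
  a <- one_way_anova(z, g)
  list(F = a$F, df = c(a$df_between, a$df_within), p = a$p)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with df = 1 (no Yates
#' continuity correction).
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stopf("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) stopf("zero margin in the 2x2 table")
  expected <- outer(rs, cs) / n
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE), expected = expected)
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Returns the U statistic of the first sample, the tie-corrected
#' standardized Z (no continuity correction, the convention of mainstream
#' commercial packages), and the two-tailed p from the normal
#' approximation. `U` counts, over all pairs, how often an `x` value
#' exceeds a `y` value (ties count 1/2), so complete separation with all
#' `x < y` gives `U = 0`.
#'
#' For small samples (`n1 + n2 <= exact_limit`) the exact two-sided
#' permutation p (`p_exact`, tie-aware, computed by a count-distribution
#' dynamic program) is returned alongside: the normal approximation is
#' coarse at such sizes, while large-sample software output corresponds to
#' `p`.
#'
#' @param x,y numeric samples (non-empty).
#' @param tails `"two"` (default) or `"one"`.
#' @param exact_limit maximum `n1 + n2` for which `p_exact` is computed.
#' @return List with `U`, `Z`, `p`, `p_exact` (or `NA`), `n`.
#' @export
mann_whitney <- function(x, y, tails = c("two", "one"), exact_limit = 16L) {
  tails <- match.arg(tails)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sig2 <= 0) 0 else (u - mu) / sqrt(sig2)
  p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  p_exact <- if (n <= exact_limit) mwu_exact_p(r, n1, u, tails) else NA_real_
  list(U = u, Z = z, p = min(p, 1), p_exact = p_exact,
       n = c(n1 = n1, n2 = n2))
}

# Exact permutation p of the U statistic with ties, via the distribution
# of rank sums over all n1-subsets (counts accumulated by dynamic
# programming over doubled midranks, which are integers).
mwu_exact_p <- function(r, n1, u_obs, tails) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  f[1, 1] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      src <- f[k, 1:(maxs + 1 - v)]
      f[k + 1, (v + 1):(maxs + 1)] <- f[k + 1, (v + 1):(maxs + 1)] + src
    }
  }
  counts <- f[n1 + 1, ]
  s <- (seq_along(counts) - 1) / 2          # rank sums
  us <- s - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  keep <- if (tails == "two") abs(us - mu) >= abs(u_obs - mu) - 1e-9
          else us - mu <= u_obs - mu + 1e-9
  sum(counts[keep]) / sum(counts)
}

#' Binary screening test metrics
#'
#' Sensitivity, specificity, the binary-test AUC `(sens + spec) / 2` (the
#' area under the single-threshold ROC), and the Youden index
#' `sens + spec - 1`.
#'
#' @param test_positive logical vector: screening test outcome per subject.
#' @param condition logical vector: true condition per subject.
#' @return List of class `screening_metrics`: `sensitivity`,
#'   `specificity`, `auc_binary`, `youden`, and the `tp`/`fp`/`tn`/`fn`
#'   counts.
#' @export
screening_metrics <- function(test_positive, condition) {
  test_positive <- as.logical(test_positive); condition <- as.logical(condition)
  if (length(test_positive) != length(condition))
    stopf("test and condition vectors differ in length")
  if (!any(condition)) stopf("no cases: sensitivity undefined")
  if (all(condition)) stopf("no non-cases: specificity undefined")
  tp <- sum(test_positive & condition); fn <- sum(!test_positive & condition)
  fp <- sum(test_positive & !condition); tn <- sum(!test_positive & !condition)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 auc_binary = (sens + spec) / 2, youden = sens + spec - 1,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%, AUC %.2f, Youden %.2f (tp %d fp %d tn %d fn %d)\n",
              100 * x$sensitivity, 100 * x$specificity, x$auc_binary,
              x$youden, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Trapezoidal ROC over a graded score
#'
#' Companion to [screening_metrics()]: full ROC AUC when the screening
#' score is used continuously (higher score = test positive at each
#' threshold), computed as the tie-corrected rank statistic
#' (probability that a case outranks a non-case).
#'
#' @param score numeric score per subject.
#' @param condition logical condition per subject.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, condition) {
  condition <- as.logical(condition)
  if (!any(condition) || all(condition)) stopf("need cases and non-cases")
  r <- rank(score)
  n1 <- sum(condition); n0 <- sum(!condition)
  (sum(r[condition]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
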