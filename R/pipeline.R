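#' Pipeline configuration
#'
#' Bundles every sub-configuration of the simulate - preprocess - stage -
#' score - analyze chain. One master `seed` fans out to per-participant
#' child seeds (documented derivation in `child_seed()`), so the whole run
#' is reproducible and per-subject results do not depend on cohort size or
#' processing order.
#'
#' @param seed master integer seed.
#' @param cohort a [cohort_params()].
#' @param synthesis a [synthesis_config()].
#' @param thresholds a [classifier_thresholds()].
#' @param rules a [scoring_rules()].
#' @param output_dir output directory (created if missing).
#' @param simulate_eeg if `TRUE` (default), synthesize, preprocess and
#'   classify a full EEG per participant; if `FALSE`, score the
#'   ground-truth stage scripts directly (fast desk-scale mode).
#' @param keep_eeg also write each synthesized recording as EDF (large).
#' @param make_figure write the group-means figure (PDF).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, cohort = cohort_params(),
                            synthesis = synthesis_config(),
                            thresholds = classifier_thresholds(),
                            rules = scoring_rules(),
                            output_dir = tempfile("vigistab_run_"),
                            simulate_eeg = TRUE, keep_eeg = FALSE,
                            make_figure = TRUE) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 synthesis = synthesis, thresholds = thresholds,
                 rules = rules, output_dir = output_dir,
                 simulate_eeg = isTRUE(simulate_eeg),
                 keep_eeg = isTRUE(keep_eeg),
                 make_figure = isTRUE(make_figure)),
            class = "pipeline_config")
}

# Stage-and-score one participant. Returns the stability result and the
# classified sequence.
process_participant <- function(id, index, profile, config) {
  cs <- child_seed(config$seed, 2L * index)
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed for participant %s: %s",
            what, id, conditionMessage(e)))
  }
  script <- step("simulate-script",
                 generate_stage_script(profile, seed = cs))
  if (config$simulate_eeg) {
    rec <- step("simulate-eeg",
                synthesize_eeg(script, config$synthesis, seed = cs + 1L))
    rec <- step("preprocess", preprocess(rec))
    grid <- step("segment", segment_recording(rec))
    grid <- step("mark-artifacts", mark_artifacts(grid))
    grid <- step("detect-graphoelements", detect_graphoelements(grid))
    seq <- step("stage", classify_recording(grid, config$thresholds))
  } else {
    rec <- NULL
    seq <- script
  }
  res <- step("score", arousal_stability_score(seq, config$rules))
  list(id = id, script = script, sequence = seq, result = res, recording = rec)
}

#' Run the full arousal-regulation pipeline
#'
#' Generates the synthetic cohort, renders and stages a resting EEG per
#' participant (hyperaroused participants get a hyperaroused stage
#' trajectory, the rest a declining one), computes every Arousal Stability
#' Score, merges scores with the questionnaire data, runs the group
#' statistics layer and writes the report plus intermediate files
#' (`cohort.csv`, `stages/<id>.tsv`, `scores.json`, `report.json`,
#' `report.tsv`, optional group-means figure). Identical seeds produce
#' byte-identical `report.json` / `report.tsv` files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the results list (`cohort`, `stats`, `files`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$output_dir, "stages"), showWarnings = FALSE)

  cohort_par <- config$cohort
  cohort_par$seed <- child_seed(config$seed, 0L)
  cohort <- generate_cohort(cohort_par)
  if (!nrow(cohort)) stopf("pipeline stage 'simulate-cohort' produced an empty cohort")
  write.csv(cohort, file.path(config$output_dir, "cohort.csv"), row.names = FALSE)

  scores <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    profile <- if (cohort$group_true[i] == "hyperaroused")
      "hyperaroused" else "declining"
    pr <- process_participant(cohort$id[i], i, profile, config)
    write_stage_sequence(pr$sequence,
                         file.path(config$output_dir, "stages",
                                   paste0(cohort$id[i], ".tsv")))
    if (config$keep_eeg && !is.null(pr$recording))
      write_edf(pr$recording,
                file.path(config$output_dir, paste0(cohort$id[i], ".edf")))
    scores[[i]] <- list(id = cohort$id[i], score = pr$result$score,
                        group = pr$result$group,
                        triggered_rule = pr$result$triggered_rule,
                        fallback_used = pr$result$fallback_used)
  }
  jsonlite::write_json(scores, file.path(config$output_dir, "scores.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cohort$score <- vapply(scores, `[[`, integer(1), "score")
  cohort$group <- vapply(scores, `[[`, character(1), "group")

  stats <- analyze_cohort(cohort, rules = config$rules)
  results <- list(config_seed = config$seed, cohort = cohort, stats = stats)
  results$files <- make_report(results, config$output_dir,
                               make_figure = config$make_figure)
  invisible(results)
}

#' Group statistics layer on a scored cohort
#'
#' Runs the analysis battery of an arousal-regulation group comparison on
#' a cohort table carrying `score` and `group` columns: descriptives per
#' arousal group, one-way ANOVA on the IDS-SR sum-score (with Levene's
#' test), a two-way ANOVA adding gender, the gender x group chi-squared
#' test, exploratory two-tailed Mann-Whitney tests on PSQI and ESS, and
#' the score-vs-depression screening metrics (moderate-to-severe IDS-SR as
#' condition) when both cases and non-cases are present.
#'
#' @param cohort data.frame with at least `ids_sr_sum`, `gender`, `psqi_total`,
#'   `ess_total`, `score`, `group`.
#' @param rules a [scoring_rules()].
#' @return Nested list of statistics.
#' @export
analyze_cohort <- function(cohort, rules = scoring_rules()) {
  need <- c("ids_sr_sum", "gender", "psqi_total", "ess_total", "score", "group")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort table misses column(s): %s",
                          paste(miss, collapse = ", "))
  two_groups <- length(unique(cohort$group)) == 2 &&
    all(table(cohort$group) >= 2)
  out <- list(n = nrow(cohort),
              n_hyper = sum(cohort$group == "hyperaroused"),
              pct_hyper = 100 * mean(cohort$group == "hyperaroused"),
              severity = table(ids_severity(cohort$ids_sr_sum)))
  if (!two_groups) {
    out$note <- "fewer than two populated arousal groups: group tests skipped"
    return(out)
  }
  out$anova_ids <- one_way_anova(cohort$ids_sr_sum, cohort$group, tails = "one")
  out$levene_ids <- levene_test(cohort$ids_sr_sum, cohort$group)
  cells <- table(cohort$group, cohort$gender)
  if (all(cells >= 2))
    out$anova_ids_gender <- two_way_anova(cohort$ids_sr_sum, cohort$group,
                                          cohort$gender)
  gender_tab <- table(factor(cohort$group,
                             levels = c("hyperaroused", "non_hyperaroused")),
                      factor(cohort$gender, levels = c("f", "m")))
  out$chi_sq_gender <- chi_square_2x2(as.matrix(gender_tab))
  hyper <- cohort$group == "hyperaroused"
  out$mwu <- list(
    psqi = mann_whitney(cohort$psqi_total[hyper], cohort$psqi_total[!hyper]),
    ess = mann_whitney(cohort$ess_total[hyper], cohort$ess_total[!hyper]))
  cond <- ids_severity(cohort$ids_sr_sum) %in% c("moderate", "severe")
  if (any(cond) && !all(cond)) {
    out$screening <- screening_metrics(hyper, cond)
    out$roc_auc_score <- roc_auc(cohort$score, cond)
  }
  out
}

#' Write the human-readable analysis report
#'
#' Emits `report.json` (full machine-readable results), `report.tsv`
#' (descriptives stratified by arousal group: n, sex, diagnosis counts,
#' MFI median, IDS-SR / PSQI / ESS mean +/- SD, median score) and an
#' optional group-means figure (mean IDS-SR per arousal group with
#' standard-error bars, split by gender).
#'
#' @param results results list from [run_pipeline()] (needs `cohort` and
#'   `stats`).
#' @param output_dir target directory.
#' @param make_figure write `fig_group_means.pdf`.
#' @return Named list of written file paths.
#' @export
make_report <- function(results, output_dir, make_figure = TRUE) {
  if (is.null(results$cohort) || is.null(results$stats))
    stopf("incomplete results: need %s",
          paste(setdiff(c("cohort", "stats"), names(results)), collapse = ", "))
  cohort <- results$cohort
  if (!nrow(cohort)) stopf("empty results: no participants")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()

  grp_stat <- function(f) {
    vapply(split(cohort, cohort$group), f, numeric(1))[
      c("hyperaroused", "non_hyperaroused")]
  }
  msd <- function(col) {
    vapply(split(cohort[[col]], cohort$group), function(v)
      sprintf("%.1f +/- %.1f", mean(v), sd(v)), character(1))[
      c("hyperaroused", "non_hyperaroused")]
  }
  tab <- rbind(
    n = as.character(grp_stat(nrow)),
    female_male = vapply(split(cohort, cohort$group), function(d)
      sprintf("%d/%d", sum(d$gender == "f"), sum(d$gender == "m")),
      character(1))[c("hyperaroused", "non_hyperaroused")],
    cancer_n = as.character(grp_stat(function(d) sum(d$dx_class == "cancer"))),
    neuroinflammatory_autoimmune_n = as.character(
      grp_stat(function(d) sum(d$dx_class != "cancer"))),
    mfi_median = as.character(grp_stat(function(d) median(d$mfi_sum))),
    ids_sr = msd("ids_sr_sum"),
    psqi = msd("psqi_total"),
    ess = msd("ess_total"),
    score_median = as.character(grp_stat(function(d) median(d$score))))
  df <- data.frame(variable = rownames(tab), tab, check.names = FALSE)
  files$report_tsv <- file.path(output_dir, "report.tsv")
  write.table(df, files$report_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  files$report_json <- file.path(output_dir, "report.json")
  jsonlite::write_json(
    list(n = nrow(cohort), seed = results$config_seed,
         groups = as.list(table(cohort$group)), stats = results$stats),
    files$report_json, auto_unbox = TRUE, pretty = TRUE, digits = 10,
    force = TRUE)

  if (make_figure) {
    files$figure <- file.path(output_dir, "fig_group_means.pdf")
    pdf(files$figure, width = 7, height = 4)
    on.exit(dev.off())
    means <- tapply(cohort$ids_sr_sum, cohort$group, mean)
    ses <- tapply(cohort$ids_sr_sum, cohort$group,
                  function(v) sd(v) / sqrt(length(v)))
    bp <- barplot2_safe(means, ses, "IDS-SR sum-score")
    by_gender <- tapply(cohort$ids_sr_sum,
                        list(cohort$group, cohort$gender), mean)
    points(rep(bp, ncol(by_gender)), as.vector(by_gender),
           pch = c(1, 17)[col(by_gender)], cex = 1.2)
    legend("topright", pch = c(1, 17), legend = colnames(by_gender),
           bty = "n", title = "gender")
  }
  files
}

barplot2_safe <- function(means, ses, ylab) {
  bp <- graphics::barplot(means, ylim = c(0, max(means + 2 * ses) * 1.2),
                          ylab = ylab, col = "grey85")
  arrows(bp, means - ses, bp, means + ses, angle = 90, code = 3, length = 0.06)
  bp
}
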