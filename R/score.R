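#' Arousal Stability scoring rules
#'
#' The fixed rule set condensing a 1200-segment stage sequence into a 1-14
#' score: the recording is divided into twenty 1-minute epochs grouped into
#' four 5-minute blocks; B1 (and B2/3) "emergence" means at least 1/3 of an
#' epoch's classified segments carry that stage, C emergence means at least
#' one C segment; scores 13/14 require more than 2/3 of every epoch's
#' segments in stages {0, A} (13) or {0, A1} (14). Participants at or above
#' `cutoff` are hyperaroused.
#'
#' @param predominance_fraction fraction for the 13/14 rows (strictly
#'   exceeded).
#' @param emergence_fraction per-epoch fraction for B1/B2-3 emergence
#'   (reached or exceeded).
#' @param epoch_length epoch length in seconds.
#' @param block_length block length in seconds (must be a multiple of
#'   `epoch_length`).
#' @param cutoff hyperarousal cutoff score.
#' @return A validated list of class `scoring_rules`.
#' @export
scoring_rules <- function(predominance_fraction = 2 / 3,
                          emergence_fraction = 1 / 3,
                          epoch_length = 60L, block_length = 300L,
                          cutoff = 13L) {
  r <- list(predominance_fraction = predominance_fraction,
            emergence_fraction = emergence_fraction,
            epoch_length = as.integer(epoch_length),
            block_length = as.integer(block_length),
            cutoff = as.integer(cutoff))
  assert_scalar_num(r$predominance_fraction, "predominance_fraction",
                    lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(r$emergence_fraction, "emergence_fraction",
                    lower = 1e-9, upper = 1 - 1e-9)
  if (r$epoch_length <= 0 || r$block_length %% r$epoch_length != 0)
    stopf("block_length must be a positive multiple of epoch_length")
  if (r$cutoff < 1 || r$cutoff > 14) stopf("cutoff must be in 1..14")
  structure(r, class = "scoring_rules")
}

#' Per-epoch stage fractions
#'
#' For each 1-minute epoch (half-open segment ranges `[60(m-1), 60m)`),
#' the fraction of each stage among that epoch's classified (non-artifact)
#' segments. Epochs with zero classified segments are marked unevaluable
#' and excluded from the predominance rows.
#'
#' @param seq a [stage_sequence()] of length 1200 (or a multiple of
#'   `epoch_length`).
#' @param rules a [scoring_rules()].
#' @return A data.frame with one row per epoch: `epoch`, `block`,
#'   `n_classified`, `evaluable`, and one fraction column per stage.
#' @export
epoch_fractions <- function(seq, rules = scoring_rules()) {
  labels <- as.character(unclass(seq))
  el <- rules$epoch_length
  if (length(labels) %% el != 0)
    stopf("sequence length %d is not a multiple of the epoch length %d",
          length(labels), el)
  n_epoch <- length(labels) %/% el
  epoch <- rep(seq_len(n_epoch), each = el)
  per_block <- rules$block_length %/% el
  out <- data.frame(epoch = seq_len(n_epoch),
                    block = (seq_len(n_epoch) - 1L) %/% per_block + 1L)
  cls <- labels != ARTIFACT_LABEL
  out$n_classified <- as.integer(tapply(cls, epoch, sum))
  out$evaluable <- out$n_classified > 0
  for (st in STAGES) {
    cnt <- tapply(labels == st & cls, epoch, sum)
    out[[st]] <- ifelse(out$n_classified > 0,
                        as.numeric(cnt) / out$n_classified, NA_real_)
  }
  out
}

#' Arousal Stability Score
#'
#' Scans the fourteen scoring rows against a per-second stage sequence and
#' returns the score, the row that produced it, and the arousal group at
#' the configured cutoff:
#'
#' * rows 1-4: at least one `C` segment; the block (1-4) of its earliest
#'   occurrence gives score 1-4 (score 4 = latest block);
#' * rows 5-8: some epoch has >= 1/3 `B2/3` segments; block of the earliest
#'   such epoch gives score 5-8;
#' * rows 9-12: likewise for `B1`, scores 9-12;
#' * row 13: every evaluable epoch has > 2/3 of segments in {0, A1, A2, A3};
#' * row 14: every evaluable epoch has > 2/3 of segments in {0, A1}.
#'
#' The final score is the minimum fired row (deepest/earliest decline
#' wins), with 14 preferred over 13 when both predominance rows hold. If no
#' row fires (possible with diffuse sub-threshold B1), the score falls back
#' to 12 and `fallback_used` is set. All fractions are computed over
#' classified (non-artifact) segments only.
#'
#' @param seq a [stage_sequence()] of length 1200.
#' @param rules a [scoring_rules()].
#' @return An object of class `stability_result`: list with `score`,
#'   `triggered_rule`, `group`, `fallback_used`, `fired_rows` and
#'   `per_epoch_fractions`.
#' @examples
#' arousal_stability_score(stage_sequence(rep("A1", 1200)))$score  # 14
#' @export
arousal_stability_score <- function(seq, rules = scoring_rules()) {
  labels <- as.character(unclass(seq))
  if (length(labels) != 1200L)
    stopf("arousal stability scoring requires a 1200-segment sequence, got %d",
          length(labels))
  if (all(labels == ARTIFACT_LABEL))
    stopf("unscorable: sequence contains no classified segments")
  fr <- epoch_fractions(seq, rules)
  el <- rules$epoch_length
  tol <- 1e-9

  fired <- integer(0)
  rule_txt <- character(0)
  fire <- function(score, txt) {
    fired <<- c(fired, score)
    rule_txt <<- c(rule_txt, sprintf("row %d: %s", score, txt))
  }

  # rows 1-4: earliest C segment
  c_idx <- which(labels == "C")
  if (length(c_idx)) {
    ep <- (c_idx[1] - 1L) %/% el + 1L
    b <- fr$block[ep]
    fire(b, sprintf("stage C emerged in block %d (min %d-%d)",
                    b, (b - 1) * 5 + 1, b * 5))
  }
  # rows 5-8 (B2/3) and 9-12 (B1): earliest epoch reaching the emergence
  # fraction
  emergence_row <- function(stage, base) {
    hit <- which(fr$evaluable & fr[[stage]] >= rules$emergence_fraction - tol)
    if (length(hit)) {
      b <- fr$block[hit[1]]
      fire(base + b, sprintf("stage %s emerged in block %d (min %d-%d)",
                             stage, b, (b - 1) * 5 + 1, b * 5))
    }
  }
  emergence_row("B2/3", 4L)
  emergence_row("B1", 8L)
  # rows 13/14: predominance of {0, A} / {0, A1} in every evaluable epoch
  ev <- fr$evaluable
  if (any(ev)) {
    frac_0A <- rowSums(fr[, c("0", A_STAGES), drop = FALSE])
    frac_0A1 <- rowSums(fr[, c("0", "A1"), drop = FALSE])
    if (all(frac_0A[ev] > rules$predominance_fraction + tol))
      fire(13L, "predominant classification of 0 and A in every epoch")
    if (all(frac_0A1[ev] > rules$predominance_fraction + tol))
      fire(14L, "predominant classification of 0 and A1 in every epoch")
  }

  fallback <- FALSE
  decline <- fired[fired <= 12L]
  if (length(decline)) {
    score <- min(decline)
  } else if (14L %in% fired) {
    score <- 14L
  } else if (13L %in% fired) {
    score <- 13L
  } else {
    score <- 12L
    fallback <- TRUE
    rule_txt <- c(rule_txt, "fallback: no scoring row fired, score 12 assigned")
  }
  structure(list(score = as.integer(score),
                 triggered_rule = if (fallback) tail(rule_txt, 1) else
                   rule_txt[match(score, fired)],
                 fired_rows = sort(unique(fired)),
                 group = assign_group(score, rules),
                 fallback_used = fallback,
                 per_epoch_fractions = fr),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> score %d (%s)%s\n  %s\n",
              x$score, x$group,
              if (x$fallback_used) " [fallback]" else "",
              x$triggered_rule))
  invisible(x)
}

#' Assign the arousal group from a score
#'
#' @param score integer score in 1..14.
#' @param rules a [scoring_rules()] (supplies the cutoff, default 13).
#' @return `"hyperaroused"` if `score >= cutoff`, else
#'   `"non_hyperaroused"`.
#' @export
assign_group <- function(score, rules = scoring_rules()) {
  if (any(score < 1 | score > 14 | score != round(score)))
    stopf("score must be an integer in 1..14")
  ifelse(score >= rules$cutoff, "hyperaroused", "non_hyperaroused")
}
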