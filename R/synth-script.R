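#' Generate a ground-truth vigilance stage script
#'
#' Produces a per-second stage trajectory for a 20-minute recording
#' (1200 labels), used both as the ground truth for EEG synthesis and as a
#' direct input to the stability scorer. Two named profiles encode the two
#' arousal regulation patterns of interest:
#'
#' * `"hyperaroused"`: the subject remains in high-arousal stages for the
#'   whole recording; the script contains only stages `0` and `A1`, so it
#'   scores 14 by construction.
#' * `"declining"`: arousal declines over time. Stage `B1` emerges at minute
#'   `emergence$b1` (that minute is guaranteed to contain at least 1/3 B1
#'   segments), optionally followed by `B2/3` at `emergence$b23` (at least
#'   1/3 of that minute) and by sleep onset `C` at `emergence$c` (at least
#'   one C segment in that minute). Unspecified emergence minutes are drawn
#'   at random; set them to `NA` to suppress the stage entirely.
#' * `"custom"`: same construction but without ordering checks, so e.g. a C
#'   segment may precede B1 emergence.
#'
#' @param profile one of `"hyperaroused"`, `"declining"`, `"custom"`.
#' @param emergence list with elements `b1`, `b23`, `c`: 1-based emergence
#'   minutes in 1..20, or `NA` to omit the stage. Ignored for
#'   `"hyperaroused"`.
#' @param seed integer seed; the draw is fully reproducible.
#' @return A `stage_script` (inherits from [stage_sequence()]) with
#'   attributes `seed`, `profile_name` and `emergence`.
#' @examples
#' s <- generate_stage_script("declining", emergence = list(b1 = 3), seed = 1)
#' arousal_stability_score(s)$score  # 9: B1 emerged in min 1-5
#' @export
generate_stage_script <- function(profile = c("hyperaroused", "declining", "custom"),
                                  emergence = list(), seed = 1L) {
  if (!is.character(profile) || !profile[1] %in% c("hyperaroused", "declining", "custom"))
    stopf("unknown profile: %s", paste(profile[1], collapse = ""))
  profile <- profile[1]
  assert_scalar_num(seed, "seed")

  labels <- withr::with_seed(as.integer(seed), {
    if (profile == "hyperaroused") {
      emergence <- list(b1 = NA, b23 = NA, c = NA)
      script_minutes(rep("high", 20), emergence)
    } else {
      em <- resolve_emergence(emergence, custom = profile == "custom")
      phases <- vapply(1:20, function(m) minute_phase(m, em), character(1))
      script_minutes(phases, em)
    }
  })

  structure(stage_sequence(labels),
            seed = as.integer(seed), profile_name = profile,
            emergence = if (profile == "hyperaroused") NULL else em_store(labels),
            class = c("stage_script", "stage_sequence"))
}

em_store <- function(labels) {
  first_min <- function(st) {
    i <- which(labels == st)
    if (!length(i)) NA_integer_ else as.integer((i[1] - 1) %/% 60 + 1)
  }
  list(b1 = first_min("B1"), b23 = first_min("B2/3"), c = first_min("C"))
}

resolve_emergence <- function(emergence, custom = FALSE) {
  em <- modifyList(list(b1 = NULL, b23 = NULL, c = NULL), emergence)
  chk <- function(x, name) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) return(x)
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x > 20 || x != round(x))
      stopf("emergence minute '%s' must be an integer in 1..20", name)
    as.integer(x)
  }
  em$b1 <- chk(em$b1, "b1"); em$b23 <- chk(em$b23, "b23"); em$c <- chk(em$c, "c")
  # fill unspecified (NULL) minutes at random; NA means "omit"
  if (is.null(em$b1)) em$b1 <- sample(2:6, 1)
  if (is.null(em$b23))
    em$b23 <- if (is.na(em$b1) || runif(1) < 0.3) NA_integer_ else
      min(20L, em$b1 + sample(3:6, 1))
  if (is.null(em$c))
    em$c <- if (is.na(em$b23) || runif(1) < 0.4) NA_integer_ else
      min(20L, em$b23 + sample(2:5, 1))
  if (!custom) {
    ord <- c(em$b1, em$b23, em$c)
    ord <- ord[!is.na(ord)]
    if (is.unsorted(ord))
      stopf("emergence minutes out of order (b1 <= b23 <= c required): %s",
            paste(ord, collapse = ", "))
    if (is.na(em$b1) && (!is.na(em$b23) || !is.na(em$c)))
      stopf("declining profile requires a B1 emergence minute")
  }
  em
}

minute_phase <- function(m, em) {
  if (!is.na(em$c) && m >= em$c) return(if (m == em$c) "c_on" else "c")
  if (!is.na(em$b23) && m >= em$b23) return(if (m == em$b23) "b23_on" else "b23")
  if (!is.na(em$b1) && m >= em$b1) return(if (m == em$b1) "b1_on" else "b1")
  "high"
}

# Build one minute (60 labels) per phase. Emergence minutes ("*_on") are
# guaranteed to satisfy the scoring thresholds: >= 1/3 of segments for
# B1/B2-3, >= 1 segment for C. Runs are contiguous (drowsiness comes in
# bouts, and contiguous ground truth keeps the synthesized EEG's slow
# features coherent across neighbouring seconds).
script_minutes <- function(phases, em) {
  unlist(lapply(phases, function(ph) {
    switch(ph,
      high = sample(c("A1", "0"), 60, replace = TRUE, prob = c(0.85, 0.15)),
      b1_on = place_run("B1", sample(25:45, 1), c("A1", "0"), c(0.8, 0.2)),
      b1 = place_run("B1", sample(30:50, 1), c("A1", "0"), c(0.7, 0.3)),
      b23_on = place_run("B2/3", sample(25:45, 1), c("B1", "A1"), c(0.7, 0.3)),
      b23 = place_run("B2/3", sample(30:50, 1), c("B1", "A1"), c(0.7, 0.3)),
      c_on = place_run("C", sample(1:3, 1), c("B2/3", "B1"), c(0.8, 0.2)),
      c = place_run("C", rbinom(1, 5, 0.4), c("B2/3", "B1"), c(0.8, 0.2)),
      stopf("internal: unknown phase %s", ph))
  }), use.names = FALSE)
}

place_run <- function(stage, n_stage, bg_stages, bg_prob) {
  n_stage <- min(60L, max(0L, n_stage))
  out <- sample(bg_stages, 60, replace = TRUE, prob = bg_prob)
  if (n_stage > 0) {
    start <- sample.int(60 - n_stage + 1, 1)
    out[start:(start + n_stage - 1)] <- stage
  }
  out
}

#' @export
print.stage_script <- function(x, ...) {
  cat(sprintf("<stage_script> profile=%s seed=%d\n",
              attr(x, "profile_name"), attr(x, "seed")))
  NextMethod()
}
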