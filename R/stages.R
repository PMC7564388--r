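#' Stage vocabulary
#'
#' The seven EEG-vigilance stages, ordered from active wakefulness (`0`)
#' to sleep onset (`C`). A1/A2/A3 are alpha-dominated stages with an
#' occipital, central and frontal alpha centre of gravity respectively;
#' B1 is low-amplitude non-alpha EEG with slow horizontal eye movements;
#' B2/3 has high delta/theta power; C is marked by sleep spindles or
#' K-complexes.
#'
#' @return Character vector of the seven stage labels.
#' @export
vigilance_stages <- function() STAGES

#' Per-second vigilance stage sequence
#'
#' A validated sequence of per-second stage labels, the output of
#' [classify_recording()] and the input of [arousal_stability_score()].
#' Artifact segments carry the reserved label `"ARTIFACT"` and are excluded
#' from all scoring fractions.
#'
#' @param labels character vector of stage labels (plus optionally
#'   `"ARTIFACT"`).
#' @param expected_length required length; the canonical 20-minute resting
#'   recording has 1200. Use `NULL` to skip the length check (synthesis of
#'   shortened test recordings).
#' @return An object of class `stage_sequence`: a character vector with
#'   attribute `n_classified` (number of non-artifact labels).
#' @examples
#' s <- stage_sequence(rep("A1", 1200))
#' attr(s, "n_classified")
#' @export
stage_sequence <- function(labels, expected_length = 1200L) {
  labels <- as.character(labels)
  if (!is.null(expected_length) && length(labels) != expected_length)
    stopf("stage sequence must have %d labels, got %d",
          expected_length, length(labels))
  bad <- setdiff(unique(labels), c(STAGES, ARTIFACT_LABEL))
  if (length(bad))
    stopf("unknown stage label(s): %s", paste(bad, collapse = ", "))
  structure(labels,
            n_classified = sum(labels != ARTIFACT_LABEL),
            class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c(STAGES, ARTIFACT_LABEL)))
  cat(sprintf("<stage_sequence> %d segments (%d classified)\n",
              length(x), attr(x, "n_classified")))
  print(tab)
  invisible(x)
}

#' Read / write a stage sequence as TSV
#'
#' The on-disk format has columns `segment_index` (0-based), `onset_s`
#' and `stage`; artifact rows are retained with stage `"ARTIFACT"`.
#'
#' @param seq a [stage_sequence()].
#' @param path file path.
#' @param expected_length passed to [stage_sequence()] on read.
#' @return `write_stage_sequence()` returns `path` invisibly;
#'   `read_stage_sequence()` returns a `stage_sequence`.
#' @export
write_stage_sequence <- function(seq, path) {
  df <- data.frame(segment_index = seq_along(seq) - 1L,
                   onset_s = seq_along(seq) - 1L,
                   stage = as.character(unclass(seq)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_sequence
#' @export
read_stage_sequence <- function(path, expected_length = 1200L) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(stage = "character"))
  if (!all(c("segment_index", "stage") %in% names(df)))
    stopf("stage TSV must have columns segment_index and stage: %s", path)
  df <- df[order(df$segment_index), , drop = FALSE]
  stage_sequence(df$stage, expected_length = expected_length)
}
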