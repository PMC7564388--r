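# Brute-force Arousal Stability oracle: enumerates all 14 scoring rows one
# by one, written independently of the package's scorer (per-row scans over
# minute slices, no shared helpers).
oracle_stability_score <- function(labels) {
  stopifnot(length(labels) == 1200)
  minute_labels <- function(m) {
    seg <- labels[((m - 1) * 60 + 1):(m * 60)]
    seg[seg != "ARTIFACT"]
  }
  block_of_minute <- function(m) (m - 1) %/% 5 + 1
  fired <- integer(0)

  # rows 1-4: at least one C segment, row = block of its first occurrence
  c_pos <- which(labels == "C")
  if (length(c_pos)) {
    blk <- block_of_minute((c_pos[1] - 1) %/% 60 + 1)
    for (row in 1:4) if (blk == row) fired <- c(fired, row)
  }
  # rows 5-8: first minute with >= 1/3 B2/3 among classified segments
  for (m in 1:20) {
    seg <- minute_labels(m)
    if (length(seg) && sum(seg == "B2/3") / length(seg) >= 1 / 3 - 1e-9) {
      for (row in 5:8) if (block_of_minute(m) == row - 4) fired <- c(fired, row)
      break
    }
  }
  # rows 9-12: same for B1
  for (m in 1:20) {
    seg <- minute_labels(m)
    if (length(seg) && sum(seg == "B1") / length(seg) >= 1 / 3 - 1e-9) {
      for (row in 9:12) if (block_of_minute(m) == row - 8) fired <- c(fired, row)
      break
    }
  }
  # rows 13/14: predominance in every evaluable minute
  predominant <- function(stages) {
    for (m in 1:20) {
      seg <- minute_labels(m)
      if (!length(seg)) next
      if (sum(seg %in% stages) / length(seg) <= 2 / 3 + 1e-9) return(FALSE)
    }
    TRUE
  }
  if (predominant(c("0", "A1", "A2", "A3"))) fired <- c(fired, 13L)
  if (predominant(c("0", "A1"))) fired <- c(fired, 14L)

  decline <- fired[fired <= 12]
  if (length(decline)) return(min(decline))
  if (14 %in% fired) return(14L)
  if (13 %in% fired) return(13L)
  12L  # fallback
}

# Random label sequences exercising all scoring rows, including artifacts.
random_labels <- function(artifact_prob = 0.02) {
  pool <- c("0", "A1", "A2", "A3", "B1", "B2/3", "C")
  w <- rexp(7) * c(1, 3, 1, 0.5, 1.5, 1, 0.1)
  labels <- sample(pool, 1200, replace = TRUE, prob = w / sum(w))
  art <- runif(1200) < artifact_prob
  labels[art] <- "ARTIFACT"
  labels
}
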