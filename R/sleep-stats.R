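# Bout extraction and sleep-architecture statistics.

#' Extract maximal same-state bouts from a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in one state. Runs shorter
#' than `min_bout_s` are merged into the longer neighbouring run (ties go to
#' the preceding neighbour), shortest offenders first, until every bout
#' satisfies the minimum.
#'
#' @param hypnogram A `hypnogram`.
#' @param min_bout_s Minimum bout duration in seconds (0 = keep all runs).
#' @return A tibble with columns `state`, `start_s`, `end_s`, `duration_s`.
#' @examples
#' h <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM"))
#' extract_bouts(h)
#' @export
extract_bouts <- function(hypnogram, min_bout_s = 0) {
  el <- epoch_length(hypnogram)
  r <- rle(hypnogram$state)
  len <- r$lengths * el
  st <- r$values
  if (min_bout_s > 0 && length(len) > 1) {
    repeat {
      short <- which(len < min_bout_s)
      if (length(short) == 0) break
      i <- short[order(len[short])][1]      # shortest first, ties earlier
      left <- if (i > 1) len[i - 1] else -Inf
      right <- if (i < length(len)) len[i + 1] else -Inf
      j <- if (left >= right) i - 1 else i + 1   # tie -> preceding
      len[j] <- len[j] + len[i]
      len <- len[-i]; st <- st[-i]
      # merging may create adjacent same-state runs; re-consolidate
      r2 <- rle(st)
      if (any(r2$lengths > 1)) {
        grp <- rep(seq_along(r2$lengths), r2$lengths)
        len <- as.numeric(tapply(len, grp, sum))
        st <- r2$values
      }
      if (length(len) == 1) break
    }
  }
  end <- hypnogram$t_start_s[1] + cumsum(len)
  tibble(state = st,
         start_s = end - len,
         end_s = end,
         duration_s = len)
}

#' Sleep-architecture statistics
#'
#' Per-state percentage of recording time (epoch counts, so percentages sum
#' to exactly 100), bout counts and mean bout durations over maximal runs,
#' and latency to the first bout of each state measured from the start of
#' the recording (`NA` when the state never occurs).
#'
#' @param hypnogram A `hypnogram`.
#' @return A tibble with one row per state (`WAKE`, `NREM`, `REM`):
#'   `percent_time`, `bout_count`, `mean_bout_duration_s`, `latency_s`.
#' @export
architecture_stats <- function(hypnogram) {
  bouts <- extract_bouts(hypnogram)
  counts <- table(factor(hypnogram$state, levels = .states))
  purrr::map_dfr(.states, function(s) {
    b <- bouts[bouts$state == s, ]
    tibble(
      state = s,
      percent_time = 100 * as.numeric(counts[[s]]) / nrow(hypnogram),
      bout_count = nrow(b),
      mean_bout_duration_s = if (nrow(b)) mean(b$duration_s) else NA_real_,
      latency_s = if (nrow(b)) min(b$start_s) - hypnogram$t_start_s[1]
                  else NA_real_
    )
  })
}
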