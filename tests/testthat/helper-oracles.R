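# Independent oracles used by unit and acceptance tests. Each is written
# as a plain, brute-force alternative to the package's implementation.

# Run-length bout oracle: walk the label sequence, no rle().
rle_bouts_oracle <- function(labels, epoch_length_s, start_s = 0) {
  out <- list()
  i <- 1
  while (i <= length(labels)) {
    j <- i
    while (j < length(labels) && labels[j + 1] == labels[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(
      state = labels[i],
      start_s = start_s + (i - 1) * epoch_length_s,
      end_s = start_s + j * epoch_length_s)
    i <- j + 1
  }
  df <- do.call(rbind, out)
  df$duration_s <- df$end_s - df$start_s
  df
}

# Architecture oracle built on the bout oracle.
architecture_oracle <- function(labels, epoch_length_s) {
  b <- rle_bouts_oracle(labels, epoch_length_s)
  do.call(rbind, lapply(c("WAKE", "NREM", "REM"), function(s) {
    bs <- b[b$state == s, ]
    data.frame(
      state = s,
      percent_time = 100 * sum(labels == s) / length(labels),
      bout_count = nrow(bs),
      mean_bout_duration_s = if (nrow(bs)) mean(bs$duration_s) else NA_real_,
      latency_s = if (nrow(bs)) min(bs$start_s) else NA_real_)
  }))
}

# Greedy minimum-interval suppression oracle on a candidate list: repeatedly
# take the tallest remaining candidate (ties -> earliest) and delete every
# candidate within min_interval of it.
peak_suppression_oracle <- function(times, heights, min_interval) {
  remaining <- seq_along(times)
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(-heights[remaining], times[remaining])][1]
    kept <- c(kept, o)
    remaining <- remaining[abs(times[remaining] - times[o]) >= min_interval]
  }
  sort(kept)
}

# Stack-based flood-fill component areas (independent of igraph).
flood_fill_areas <- function(img, connectivity = 8) {
  nr <- nrow(img); nc <- ncol(img)
  seen <- matrix(FALSE, nr, nc)
  dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  if (connectivity == 8) {
    dr <- c(dr, -1, -1, 1, 1); dc <- c(dc, -1, 1, -1, 1)
  }
  areas <- integer(0)
  stack_r <- integer(nr * nc); stack_c <- integer(nr * nc)
  for (start in which(img > 0)) {
    r0 <- ((start - 1) %% nr) + 1; c0 <- ((start - 1) %/% nr) + 1
    if (seen[r0, c0]) next
    top <- 1L
    stack_r[1] <- r0; stack_c[1] <- c0
    seen[r0, c0] <- TRUE
    area <- 0L
    while (top > 0L) {
      r <- stack_r[top]; cl <- stack_c[top]; top <- top - 1L
      area <- area + 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            img[rr, cc] > 0 && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          top <- top + 1L
          stack_r[top] <- rr; stack_c[top] <- cc
        }
      }
    }
    areas <- c(areas, area)
  }
  sort(areas)
}

# Two-sided Fisher p by hypergeometric enumeration: sum the probabilities
# of all tables with the observed margins whose probability does not
# exceed the observed one.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b          # hits
  n <- c + d          # non-hits
  k <- a + c          # set size
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mostly-NREM hypnogram used for photometry fixtures.
nrem_rich_hypnogram <- function(duration_s, seed) {
  sim_hypnogram(duration_s, epoch_length_s = 1,
                transition_matrix = matrix(
                  c(0.98, 0.02, 0.00,
                    0.002, 0.996, 0.002,
                    0.02, 0.02, 0.96), 3, byrow = TRUE),
                initial_state = "NREM", seed = seed)
}
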