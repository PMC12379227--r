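# s0-moderated two-sample t-test with permutation-based FDR.

#' Permutation-FDR moderated t-test between two groups
#'
#' For each protein the statistic is
#' `t_s0 = (mean_1 - mean_2) / (pooled_se + s0)`, where the pooled standard
#' error is the Student (equal-variance) form and `s0` is a small offset
#' that damps the significance of near-zero-variance proteins. The null
#' distribution pools `t_s0` recomputed under `n_permutations` distinct
#' group-label splits (all distinct splits are enumerated when fewer exist
#' than requested). The SAM-style q-value of a protein with `|t| = s` is
#' the mean number of permuted `|t|` values at or above `s` (per
#' permutation) divided by the observed number at or above `s`, clipped to
#' 1 and made monotone in `|t|`.
#'
#' @param data Complete (imputed) wide LFQ tibble.
#' @param design Tibble (`sample`, `group`).
#' @param group_pair Character vector of the two groups to compare as
#'   `c(group1, group2)`; log2FC is `mean(group1) - mean(group2)`. Defaults
#'   to the two groups present.
#' @param s0 Variance-stabilising offset (0.5).
#' @param n_permutations Number of label permutations (250).
#' @param fdr_threshold Significance cutoff on the q-value (0.05).
#' @param seed Integer seed for permutation sampling.
#' @param var_equal Pooled-variance (Student) SE when `TRUE` (default);
#'   Welch SE otherwise.
#' @return A tibble of class `perm_ttest` with per-protein `protein`,
#'   `log2fc`, `t_s0`, `q_value`, `significant`; permutation details are in
#'   attributes. Supports [generics::tidy()] and [generics::glance()].
#' @export
permutation_ttest <- function(data, design, group_pair = NULL, s0 = 0.5,
                              n_permutations = 250, fdr_threshold = 0.05,
                              seed = 1, var_equal = TRUE) {
  if (s0 < 0 || n_permutations < 1 ||
      fdr_threshold <= 0 || fdr_threshold >= 1) {
    abort("Invalid test configuration.")
  }
  m <- lfq_matrix_of(data)
  if (anyNA(m)) abort("Matrix contains missing values; impute first.")
  grp <- check_design(data, design)
  group_pair <- group_pair %||% unique(grp)
  if (length(group_pair) != 2) {
    abort("group_pair must name exactly two groups.")
  }
  cols <- which(grp %in% group_pair)
  m2 <- m[, cols, drop = FALSE]
  g <- grp[cols]
  n1 <- sum(g == group_pair[1]); n2 <- sum(g == group_pair[2])
  if (n1 < 2 || n2 < 2) abort("Both groups need at least 2 samples.")
  n <- n1 + n2

  tstat <- function(idx1) {
    x1 <- m2[, idx1, drop = FALSE]
    x2 <- m2[, -idx1, drop = FALSE]
    d <- rowMeans(x1) - rowMeans(x2)
    v1 <- rowSums((x1 - rowMeans(x1))^2) / (ncol(x1) - 1)
    v2 <- rowSums((x2 - rowMeans(x2))^2) / (ncol(x2) - 1)
    se <- if (var_equal) {
      sp2 <- ((ncol(x1) - 1) * v1 + (ncol(x2) - 1) * v2) / (n - 2)
      sqrt(sp2 * (1 / ncol(x1) + 1 / ncol(x2)))
    } else {
      sqrt(v1 / ncol(x1) + v2 / ncol(x2))
    }
    den <- se + s0
    list(d = d, t = ifelse(d == 0 & den == 0, 0, d / den))
  }

  obs_idx <- which(g == group_pair[1])
  obs <- tstat(obs_idx)

  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_permutations
  splits <- if (exhaustive) {
    combn(n, n1, simplify = FALSE)
  } else {
    with_seed_(seed, {
      seen <- new.env(hash = TRUE)
      res <- vector("list", n_permutations)
      k <- 0L
      while (k < n_permutations) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          k <- k + 1L
          res[[k]] <- cand
        }
      }
      res
    })
  }
  perm_abs <- vapply(splits, function(ix) abs(tstat(ix)$t),
                     numeric(nrow(m2)))
  perm_abs <- matrix(perm_abs, nrow = nrow(m2))

  s <- abs(obs$t)
  # per protein: observed exceedances and mean permuted exceedances
  sorted_perm <- sort(as.numeric(perm_abs))
  n_perm_total <- length(sorted_perm)
  n_perm_cols <- ncol(perm_abs)
  exceed_perm <- (n_perm_total -
                    findInterval(s - 1e-12, sorted_perm)) / n_perm_cols
  sorted_obs <- sort(s)
  exceed_obs <- length(s) - findInterval(s - 1e-12, sorted_obs)
  q_raw <- pmin(1, exceed_perm / pmax(exceed_obs, 1))
  # monotone: a larger |t| never has a larger q
  ord <- order(-s)
  q <- numeric(length(s))
  q[ord] <- cummin(q_raw[ord][length(s):1])[length(s):1]

  out <- tibble(protein = rownames(m2),
                log2fc = obs$d,
                t_s0 = obs$t,
                q_value = q,
                significant = q < fdr_threshold)
  class(out) <- c("perm_ttest", class(out))
  attr(out, "groups") <- group_pair
  attr(out, "n_samples") <- c(n1 = n1, n2 = n2)
  attr(out, "s0") <- s0
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "n_permutations_used") <- length(splits)
  attr(out, "exhaustive") <- exhaustive
  attr(out, "perm_abs_t") <- perm_abs
  if (exhaustive && n_distinct < n_permutations) {
    inform(paste0("Only ", n_distinct,
                  " distinct label splits exist; all were used."))
  }
  out
}

#' @export
print.perm_ttest <- function(x, ...) {
  cat(sprintf(
    "Permutation t-test (%s vs %s): %d proteins, %d significant at q < %g (s0 = %g, %d permutations%s)\n",
    attr(x, "groups")[1], attr(x, "groups")[2], nrow(x),
    sum(x$significant), attr(x, "fdr_threshold"), attr(x, "s0"),
    attr(x, "n_permutations_used"),
    if (attr(x, "exhaustive")) ", exhaustive" else ""))
  NextMethod()
}
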