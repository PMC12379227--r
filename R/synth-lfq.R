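# Synthetic label-free quantification (LFQ) matrices with MNAR missingness.

#' Simulate an LFQ protein x sample log2-intensity matrix
#'
#' Protein baselines are drawn once from
#' `Normal(base_mean_log2, protein_sd_log2)`; per-cell intensities add
#' `Normal(0, base_sd_log2)` measurement noise. A fraction
#' `frac_regulated` of proteins receives a group shift of
#' `effect_log2fc` (alternating sign) in every non-reference group. Each
#' cell is then censored (missing-not-at-random) with probability
#' `plogis((mnar_midpoint_log2 - intensity) * mnar_slope)`, so low-abundance
#' cells are preferentially missing — the mechanism motivating downshifted
#' imputation.
#'
#' @param n_proteins Number of proteins.
#' @param groups Named integer vector of samples per group, e.g.
#'   `c(sleep = 6, sd24 = 6)`; the first group is the reference.
#' @param base_mean_log2,base_sd_log2 Cell-level mean and noise SD (log2).
#' @param protein_sd_log2 SD of protein baselines around `base_mean_log2`.
#' @param effect_log2fc Injected log2 fold change for regulated proteins.
#' @param frac_regulated Fraction of proteins regulated (0 for a pure null).
#' @param mnar_slope Logistic slope of missingness vs intensity (0 disables
#'   missingness when the midpoint is at `-Inf`).
#' @param mnar_midpoint_log2 Intensity with 50% missingness probability.
#' @param seed Integer seed.
#' @return A list of class `lfq_sim`: `data` (wide tibble, `protein` column
#'   plus one numeric column per sample, `NA` = missing), `design`
#'   (tibble `sample`, `group`) and `truth` (tibble `protein`, `regulated`,
#'   `true_log2fc`), plus `complete` (the pre-censoring matrix as a wide
#'   tibble).
#' @examples
#' sim <- sim_lfq(200, c(a = 4, b = 4), seed = 1)
#' head(sim$data)
#' @export
sim_lfq <- function(n_proteins,
                    groups = c(sleep = 6, sd24 = 6),
                    base_mean_log2 = 25,
                    base_sd_log2 = 0.5,
                    protein_sd_log2 = 2,
                    effect_log2fc = 1,
                    frac_regulated = 0.1,
                    mnar_slope = 0.8,
                    mnar_midpoint_log2 = 21.5,
                    seed = 1) {
  if (n_proteins < 1) abort("n_proteins must be >= 1.")
  if (is.null(names(groups)) || any(groups < 1)) {
    abort("groups must be a named vector of positive sample counts.")
  }
  if (frac_regulated < 0 || frac_regulated > 1) {
    abort("frac_regulated must lie in [0, 1].")
  }
  n_samples <- sum(groups)
  sample_ids <- unlist(lapply(names(groups), function(g) {
    paste0(g, "_", seq_len(groups[[g]]))
  }))
  group_of <- rep(names(groups), groups)
  proteins <- sprintf("P%04d", seq_len(n_proteins))

  out <- with_seed_(seed, {
    n_reg <- round(frac_regulated * n_proteins)
    regulated <- seq_len(n_proteins) <= n_reg
    sign_fc <- rep_len(c(1, -1), n_proteins)
    true_fc <- ifelse(regulated, sign_fc * effect_log2fc, 0)
    base <- rnorm(n_proteins, base_mean_log2, protein_sd_log2)
    shift <- outer(true_fc, as.numeric(group_of != names(groups)[1]))
    mu <- base + shift
    x <- mu + matrix(rnorm(n_proteins * n_samples, 0, base_sd_log2),
                     n_proteins, n_samples)
    p_miss <- plogis((mnar_midpoint_log2 - x) * mnar_slope)
    p_miss[is.nan(p_miss)] <- 0   # slope 0 with midpoint at -Inf: no censoring
    obs <- x
    obs[matrix(runif(length(x)), nrow(x)) < p_miss] <- NA
    list(x = x, obs = obs, regulated = regulated, true_fc = true_fc)
  })
  wide <- function(m) {
    colnames(m) <- sample_ids
    dplyr::bind_cols(tibble(protein = proteins), as_tibble(m))
  }
  structure(
    list(
      data = wide(out$obs),
      complete = wide(out$x),
      design = tibble(sample = sample_ids, group = group_of),
      truth = tibble(protein = proteins, regulated = out$regulated,
                     true_log2fc = out$true_fc)
    ),
    class = "lfq_sim")
}
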