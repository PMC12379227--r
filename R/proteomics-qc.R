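# QC summaries: within-group CVs, sample correlations, PCA.

#' QC summaries for an LFQ matrix
#'
#' Three standard diagnostics: per-protein coefficients of variation within
#' each group, computed on linear-scale intensities (`2^log2`, since CVs on
#' a log scale are not CVs) and summarised as the group median; pairwise
#' Pearson sample correlations on pairwise-complete log2 intensities; and
#' PCA sample scores (singular value decomposition of the centred complete
#' matrix — impute first if values are missing).
#'
#' @param data Wide LFQ tibble.
#' @param design Tibble (`sample`, `group`).
#' @param n_components Number of principal components to return.
#' @return A list with elements `cv` (tibble `group`, `median_cv_pct`,
#'   `n_proteins`), `correlation` (tibble `sample_a`, `sample_b`,
#'   `pearson_r`), and `pca` (tibble of sample scores with
#'   `attr(, "variance_explained")`), or `pca = NULL` with missing values
#'   present.
#' @export
qc_summaries <- function(data, design, n_components = 2) {
  m <- lfq_matrix_of(data)
  if (ncol(m) < 2) abort("At least two samples are required.")
  grp <- check_design(data, design)

  lin <- 2^m
  cv <- purrr::map_dfr(unique(grp), function(g) {
    sub <- lin[, grp == g, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, sd, na.rm = TRUE)
    cvp <- 100 * s / mu
    tibble(group = g,
           median_cv_pct = median(cvp, na.rm = TRUE),
           n_proteins = sum(is.finite(cvp)))
  })

  cmat <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  correlation <- tibble(sample_a = colnames(m)[pairs[, 1]],
                        sample_b = colnames(m)[pairs[, 2]],
                        pearson_r = cmat[pairs])

  pca <- NULL
  if (!anyNA(m)) {
    if (nrow(m) < 3) abort("PCA needs at least 3 proteins.")
    pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    pca <- dplyr::bind_cols(
      tibble(sample = colnames(m), group = unname(grp)),
      as_tibble(pc$x[, seq_len(k), drop = FALSE]))
    attr(pca, "variance_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  }
  list(cv = cv, correlation = correlation, pca = pca)
}
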