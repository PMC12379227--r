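# Mixed missing-value imputation: KNN for mostly-observed proteins,
# downshifted per-sample Gaussian draws for sparsely observed ones.

#' Mixed downshift + KNN imputation of missing LFQ values
#'
#' Proteins whose detection fraction is at least `knn_cutoff` are treated
#' as missing-at-random and imputed by k-nearest-neighbour regression: the
#' neighbours are the `k_neighbors` most correlated proteins (Pearson, over
#' pairwise-complete samples) with a value at the target sample, and the
#' imputed value is their mean. Proteins below the cutoff are treated as
#' missing-not-at-random (left-censored) and imputed by per-sample Gaussian
#' draws with mean `sample_mean - downshift_sd * sample_SD` and standard
#' deviation `width * sample_SD`, where sample mean/SD are computed over
#' that sample's observed values. Observed cells are never altered, and
#' results are bit-identical for a given seed.
#'
#' @param data Wide LFQ tibble (`protein` column + sample columns).
#' @param width Gaussian width as a fraction of the sample SD (0.3).
#' @param downshift_sd Downshift in sample SDs (1.8).
#' @param knn_cutoff Detection fraction at or above which KNN is used
#'   (0.6).
#' @param k_neighbors Number of neighbours (3).
#' @param min_shared Minimum shared observed samples for a usable
#'   neighbour correlation.
#' @param seed Integer seed for the Gaussian draws.
#' @return A complete wide tibble; `attr(, "imputed_mask")` is a logical
#'   matrix marking imputed cells and `attr(, "method_per_protein")` the
#'   branch used.
#' @export
impute_mixed <- function(data, width = 0.3, downshift_sd = 1.8,
                         knn_cutoff = 0.6, k_neighbors = 3,
                         min_shared = 3, seed = 1) {
  if (width <= 0 || downshift_sd < 0 || knn_cutoff <= 0 || knn_cutoff > 1 ||
      k_neighbors < 1) {
    abort("Invalid imputation configuration.")
  }
  m <- lfq_matrix_of(data)
  miss <- is.na(m)
  if (!any(miss)) {
    out <- data
    attr(out, "imputed_mask") <- miss
    attr(out, "method_per_protein") <-
      setNames(rep("none", nrow(m)), rownames(m))
    return(out)
  }
  n_obs_per_sample <- colSums(!miss)
  if (any(n_obs_per_sample < 2)) {
    abort(paste0("Sample(s) with fewer than 2 observed values: ",
                 paste(colnames(m)[n_obs_per_sample < 2], collapse = ", ")))
  }
  s_mean <- colMeans(m, na.rm = TRUE)
  s_sd <- apply(m, 2, sd, na.rm = TRUE)
  frac_valid <- rowMeans(!miss)
  use_knn <- frac_valid >= knn_cutoff
  method <- setNames(ifelse(!rowSums(miss), "none",
                            ifelse(use_knn, "knn", "downshift")),
                     rownames(m))

  out <- m
  # KNN branch (deterministic)
  knn_rows <- which(use_knn & rowSums(miss) > 0)
  if (length(knn_rows)) {
    cm <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs"))
    shared <- (!miss) %*% t(!miss)          # shared observed sample counts
    for (i in knn_rows) {
      r <- cm[i, ]
      r[i] <- -Inf
      r[shared[i, ] < min_shared | is.na(r)] <- -Inf
      for (j in which(miss[i, ])) {
        cand <- which(!miss[, j] & is.finite(r))
        if (length(cand)) {
          nb <- cand[order(-r[cand], cand)][seq_len(min(k_neighbors,
                                                        length(cand)))]
          out[i, j] <- mean(m[nb, j])
        } else {
          method[i] <- "downshift"          # no usable neighbour: censored
        }
      }
    }
  }
  # Downshifted Gaussian branch (seeded)
  ds_rows <- which(method == "downshift")
  out <- with_seed_(seed, {
    for (j in seq_len(ncol(m))) {
      rows <- ds_rows[is.na(out[ds_rows, j])]
      if (length(rows)) {
        out[rows, j] <- rnorm(length(rows),
                              mean = s_mean[j] - downshift_sd * s_sd[j],
                              sd = width * s_sd[j])
      }
    }
    out
  })
  res <- lfq_tibble_of(out)
  attr(res, "imputed_mask") <- miss
  attr(res, "method_per_protein") <- method
  res
}
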