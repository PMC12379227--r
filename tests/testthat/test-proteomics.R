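# Proteomics module: QC filters, mixed imputation, permutation-FDR t-test
# and Fisher/BH enrichment.

make_lfq <- function(mat, proteins = NULL) {
  if (is.null(proteins)) proteins <- sprintf("P%03d", seq_len(nrow(mat)))
  dplyr::bind_cols(tibble::tibble(protein = proteins),
                   tibble::as_tibble(mat, .name_repair = "minimal"))
}

test_that("sample QC drops below-median-coverage samples", {
  withr::with_seed(1, {
    m <- matrix(rnorm(100 * 4, 25), 100, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  })
  # detected counts 90, 88, 91, 40: cutoff = 0.5 * 89 = 44.5
  for (j in 1:4) {
    m[sample(100, 100 - c(90, 88, 91, 40)[j]), j] <- NA
  }
  filtered <- filter_sample_qc(make_lfq(m))
  expect_equal(attr(filtered, "dropped_samples"), "s4")
  expect_equal(attr(filtered, "qc_cutoff"), 44.5)

  full <- make_lfq(matrix(rnorm(40), 10, 4,
                          dimnames = list(NULL, paste0("s", 1:4))))
  expect_equal(attr(filter_sample_qc(full), "dropped_samples"), character(0))
})

test_that("group completeness keeps proteins complete in at least one group", {
  design <- tibble::tibble(sample = paste0("s", 1:12),
                           group = rep(c("a", "b"), each = 6))
  m <- matrix(rnorm(3 * 12, 25), 3, 12,
              dimnames = list(NULL, design$sample))
  m[1, 6] <- NA                 # protein 1: 5/6 in a, 6/6 in b
  m[2, c(1, 7)] <- NA           # protein 2: 5/6 both groups
  m[3, c(1:2, 7:8)] <- NA       # protein 3: 4/6 both groups
  d <- make_lfq(m)
  # ceiling(0.7 * 6) = 5: proteins 1 and 2 pass, 4/6 in both groups fails
  expect_equal(filter_group_completeness(d, design, 0.7)$protein,
               c("P001", "P002"))
  expect_equal(filter_group_completeness(d, design, 0.9)$protein, "P001")

  # brute-force oracle on random masks
  withr::with_seed(3, {
    for (i in 1:20) {
      mm <- matrix(rnorm(30 * 12, 25), 30, 12,
                   dimnames = list(NULL, design$sample))
      mm[matrix(runif(length(mm)) < 0.4, nrow(mm))] <- NA
      dd <- make_lfq(mm)
      frac <- 0.7
      keep_oracle <- vapply(seq_len(30), function(p) {
        any(vapply(c("a", "b"), function(g) {
          cols <- design$sample[design$group == g]
          sum(!is.na(mm[p, cols])) >= ceiling(frac * length(cols))
        }, logical(1)))
      }, logical(1))
      got <- filter_group_completeness(dd, design, frac)$protein
      expect_setequal(got, dd$protein[keep_oracle])
    }
  })
})

test_that("filters are idempotent", {
  design <- tibble::tibble(sample = paste0("s", 1:8),
                           group = rep(c("a", "b"), each = 4))
  withr::with_seed(5, {
    m <- matrix(rnorm(50 * 8, 25), 50, 8,
                dimnames = list(NULL, design$sample))
    m[matrix(runif(length(m)) < 0.3, nrow(m))] <- NA
  })
  d <- make_lfq(m)
  once <- filter_group_completeness(d, design, 0.7)
  twice <- filter_group_completeness(once, design, 0.7)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("mixed imputation completes the matrix without touching data", {
  design_samples <- paste0("s", 1:6)
  withr::with_seed(8, {
    m <- matrix(rnorm(200 * 6, 25, 2), 200, 6,
                dimnames = list(NULL, design_samples))
    holes <- matrix(runif(length(m)) < 0.15, nrow(m))
  })
  m_complete <- make_lfq(m)
  expect_equal(as.data.frame(impute_mixed(m_complete, seed = 1)),
               as.data.frame(m_complete), ignore_attr = TRUE)

  m2 <- m; m2[holes] <- NA
  d <- make_lfq(m2)
  imp <- impute_mixed(d, seed = 2)
  expect_false(anyNA(imp))
  obs <- !is.na(m2)
  expect_identical(as.matrix(imp[-1])[obs], m2[obs])
  expect_identical(as.data.frame(impute_mixed(d, seed = 2)),
                   as.data.frame(imp))
  expect_false(identical(as.data.frame(impute_mixed(d, seed = 3)),
                         as.data.frame(imp)))
})

test_that("downshifted Gaussian draws match the configured distribution", {
  n_missing <- 3000
  withr::with_seed(11, {
    base <- matrix(rnorm(400 * 2, 25, 2), 400, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  })
  m <- rbind(base, matrix(NA_real_, n_missing, 2,
                          dimnames = list(NULL, c("s1", "s2"))))
  imp <- impute_mixed(make_lfq(m), width = 0.3, downshift_sd = 1.8,
                      seed = 12)
  vals <- as.matrix(imp[-1])[(nrow(base) + 1):nrow(m), 1]
  mu_s <- mean(base[, 1]); sd_s <- sd(base[, 1])
  se_mean <- 0.3 * sd_s / sqrt(n_missing)
  expect_lt(abs(mean(vals) - (mu_s - 1.8 * sd_s)), 3 * se_mean)
  expect_lt(abs(sd(vals) / (0.3 * sd_s) - 1), 0.1)
})

test_that("KNN imputation uses the most correlated neighbour", {
  withr::with_seed(14, {
    m <- matrix(rnorm(30 * 6, 25, 2), 30, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  })
  m <- rbind(m, m[1, , drop = FALSE])    # row 31 duplicates row 1
  m[31, 4] <- NA                         # 5/6 valid -> KNN branch
  imp <- impute_mixed(make_lfq(m), k_neighbors = 1, seed = 1)
  expect_equal(as.matrix(imp[-1])[31, 4], m[1, 4])
  expect_equal(attr(imp, "method_per_protein")[[31]], "knn")
})

test_that("identical groups with s0 = 0 give zero statistics and no hits", {
  m <- matrix(rep(rnorm(20, 25), 6), 20, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("a", "b"), 3))
  de <- permutation_ttest(make_lfq(m), design, s0 = 0, seed = 1)
  expect_true(all(de$t_s0 == 0))
  expect_false(any(de$significant))
})

test_that("3 vs 3 permutations enumerate all 20 splits", {
  withr::with_seed(19, {
    m <- matrix(rnorm(40 * 6, 25), 40, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  })
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("a", "b"), each = 3))
  de <- permutation_ttest(make_lfq(m), design, seed = 1,
                          n_permutations = 250)
  expect_true(attr(de, "exhaustive"))
  expect_equal(attr(de, "n_permutations_used"), 20)

  # oracle: recompute |t| for every split by hand
  perm <- attr(de, "perm_abs_t")
  splits <- utils::combn(6, 3, simplify = FALSE)
  oracle <- vapply(splits, function(ix) {
    x1 <- m[, ix, drop = FALSE]; x2 <- m[, -ix, drop = FALSE]
    d <- rowMeans(x1) - rowMeans(x2)
    sp2 <- (rowSums((x1 - rowMeans(x1))^2) +
              rowSums((x2 - rowMeans(x2))^2)) / 4
    abs(d / (sqrt(sp2 * (2 / 3)) + 0.5))
  }, numeric(40))
  expect_equal(sort(as.numeric(perm)), sort(as.numeric(oracle)),
               tolerance = 1e-12)
})

test_that("label exchange flips fold changes and preserves q-values", {
  sim <- sim_lfq(200, c(a = 4, b = 4), seed = 21)
  imp <- impute_mixed(sim$data, seed = 1)
  de_ab <- permutation_ttest(imp, sim$design, c("a", "b"), seed = 2)
  de_ba <- permutation_ttest(imp, sim$design, c("b", "a"), seed = 2)
  expect_equal(de_ba$log2fc, -de_ab$log2fc)
  expect_equal(de_ba$q_value, de_ab$q_value)
})

test_that("detected true positives increase with effect size", {
  hits <- vapply(c(0.5, 1, 2), function(fc) {
    sim <- sim_lfq(400, c(a = 6, b = 6), effect_log2fc = fc,
                   frac_regulated = 0.15, mnar_slope = 0,
                   mnar_midpoint_log2 = -Inf, seed = 31)
    de <- permutation_ttest(sim$data, sim$design, seed = 32)
    sum(de$significant & sim$truth$regulated)
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
  expect_gt(hits[3], 0)
})

test_that("QC summaries: correlations, CVs and PCA behave as constructed", {
  withr::with_seed(41, {
    m <- matrix(rnorm(60 * 4, 25), 60, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  })
  m[, 2] <- m[, 1]    # duplicated sample
  design <- tibble::tibble(sample = paste0("s", 1:4),
                           group = rep("g", 4))
  qc <- qc_summaries(make_lfq(m), design)
  r12 <- qc$correlation$pearson_r[qc$correlation$sample_a == "s1" &
                                    qc$correlation$sample_b == "s2"]
  expect_equal(r12, 1)

  const <- make_lfq(matrix(25, 10, 4,
                           dimnames = list(NULL, paste0("s", 1:4))))
  expect_equal(qc_summaries(const, design)$cv$median_cv_pct, 0)

  # rank-2 matrix: first two PCs carry essentially all variance
  withr::with_seed(42, {
    u <- matrix(rnorm(100 * 2), 100, 2)
    v <- matrix(rnorm(2 * 6), 2, 6)
  })
  r2 <- u %*% v + 25
  colnames(r2) <- paste0("s", 1:6)
  design6 <- tibble::tibble(sample = paste0("s", 1:6), group = rep("g", 6))
  pca <- qc_summaries(make_lfq(r2), design6)$pca
  ve <- attr(pca, "variance_explained")
  expect_gt(sum(ve[1:2]), 0.999)
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  bg <- sprintf("G%03d", 1:100)
  hits <- bg[1:10]
  sets <- list(exact = hits, disjoint = bg[51:53],
               mixed = c(bg[1:8], bg[90:91]))
  res <- fisher_enrichment(hits, bg, sets)
  expect_equal(res$set[1], "exact")
  expect_true(res$odds_ratio[res$set == "exact"] == Inf)
  expect_gte(res$p_value[res$set == "disjoint"], 0.5)
  expect_lte(res$odds_ratio[res$set == "disjoint"], 1)

  # table (8,2,2,88) against exact enumeration
  row <- res[res$set == "mixed", ]
  expect_equal(row$overlap, 8)
  expect_equal(row$p_value, fisher_p_oracle(8, 2, 2, 88), tolerance = 1e-9)

  # sets outside the background are skipped and reported
  res2 <- fisher_enrichment(hits, bg, c(sets, list(alien = c("X1", "X2"))))
  expect_equal(attr(res2, "skipped_sets"), "alien")
  expect_error(fisher_enrichment(c(hits, "X9"), bg, sets), "background")
})

test_that("BH adjustment is monotone in raw p order", {
  withr::with_seed(51, p <- runif(500))
  res <- fisher_enrichment("G001", sprintf("G%03d", 1:50),
                           list(s1 = "G001", s2 = sprintf("G%03d", 2:11)))
  expect_true(all(diff(res$p_adjusted[order(res$p_value)]) >= -1e-12))
  # property on p.adjust itself as used by the enrichment path
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})
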