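# Gene-set over-representation via Fisher's exact test with
# Benjamini-Hochberg adjustment.

#' Fisher exact enrichment of a hit list against gene sets
#'
#' For each gene set the 2x2 table (hit-in-set, hit-not-in-set,
#' set-not-hit, neither) over the background universe is tested with a
#' two-sided Fisher exact test; p-values are Benjamini-Hochberg adjusted
#' across all tested sets. Sets are intersected with the background first;
#' sets with no background overlap are skipped and reported in
#' `attr(, "skipped_sets")`.
#'
#' @param hits Character vector of significant protein/gene ids (must be a
#'   subset of `background`).
#' @param background Character vector: the detection universe.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param fdr_threshold Adjusted-p significance cutoff (0.05).
#' @return A tibble of class `enrichment_result`: `set`, `overlap`,
#'   `set_size`, `hits_size`, `background_size`, `odds_ratio`, `p_value`,
#'   `p_adjusted`, `significant`, ordered by p-value. Infinite odds ratios
#'   (empty off-diagonal) are reported as `Inf`.
#' @export
fisher_enrichment <- function(hits, background, gene_sets,
                              fdr_threshold = 0.05) {
  background <- unique(background)
  hits <- unique(hits)
  if (length(background) == 0) abort("Background is empty.")
  if (!all(hits %in% background)) {
    abort("All hits must be contained in the background.")
  }
  if (length(gene_sets) == 0 || is.null(names(gene_sets))) {
    abort("gene_sets must be a non-empty named list.")
  }
  N <- length(background)
  nh <- length(hits)
  sets_bg <- lapply(gene_sets, intersect, y = background)
  skipped <- names(sets_bg)[lengths(sets_bg) == 0]
  sets_bg <- sets_bg[lengths(sets_bg) > 0]
  if (length(sets_bg) == 0) abort("No gene set overlaps the background.")

  rows <- purrr::map_dfr(names(sets_bg), function(nm) {
    sset <- sets_bg[[nm]]
    a <- length(intersect(hits, sset))
    b <- nh - a
    cc <- length(sset) - a
    d <- N - a - b - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    orr <- if (b * cc == 0) {
      if (a * d == 0) NA_real_ else Inf
    } else {
      (a * d) / (b * cc)
    }
    tibble(set = nm, overlap = a, set_size = length(sset),
           hits_size = nh, background_size = N,
           odds_ratio = orr, p_value = p)
  })
  rows$p_adjusted <- p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$p_adjusted < fdr_threshold
  rows <- dplyr::arrange(rows, .data$p_value)
  class(rows) <- c("enrichment_result", class(rows))
  attr(rows, "skipped_sets") <- skipped
  rows
}
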