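# LFQ matrix QC and completeness filtering.
#
# The wide-table convention used throughout the proteomics functions:
# a tibble whose first column `protein` holds unique protein ids and whose
# remaining numeric columns are samples (NA = not detected), plus a design
# tibble mapping `sample` to `group`.

lfq_matrix_of <- function(data) {
  if (!"protein" %in% names(data)) {
    abort("LFQ table needs a 'protein' id column.")
  }
  if (anyDuplicated(data$protein)) abort("Duplicate protein ids.")
  m <- as.matrix(data[setdiff(names(data), "protein")])
  if (!is.numeric(m)) abort("Sample columns must be numeric.")
  rownames(m) <- data$protein
  m
}

lfq_tibble_of <- function(m) {
  dplyr::bind_cols(tibble(protein = rownames(m)), as_tibble(m))
}

check_design <- function(data, design) {
  samples <- setdiff(names(data), "protein")
  if (!all(c("sample", "group") %in% names(design))) {
    abort("Design needs columns 'sample' and 'group'.")
  }
  orphans <- setdiff(samples, design$sample)
  if (length(orphans)) {
    abort(paste0("Samples missing from the design: ",
                 paste(orphans, collapse = ", ")))
  }
  setNames(design$group, design$sample)[samples]
}

#' Drop low-coverage samples
#'
#' Removes samples whose number of detected (non-missing) proteins is below
#' `min_fraction_of_median` times the median detected count across samples
#' (e.g. with a median of ~90 detected proteins, the 0.5 default keeps only
#' samples with at least 45).
#'
#' @param data Wide LFQ tibble (`protein` column + sample columns).
#' @param min_fraction_of_median Fraction of the median detected count a
#'   sample must reach.
#' @return The filtered tibble; dropped sample ids are in
#'   `attr(, "dropped_samples")`.
#' @export
filter_sample_qc <- function(data, min_fraction_of_median = 0.5) {
  m <- lfq_matrix_of(data)
  if (ncol(m) < 1) abort("At least one sample is required.")
  counts <- colSums(!is.na(m))
  cutoff <- min_fraction_of_median * median(counts)
  drop <- colnames(m)[counts < cutoff]
  if (length(drop) == ncol(m)) abort("All samples fail the QC cutoff.")
  out <- data[c("protein", setdiff(colnames(m), drop))]
  attr(out, "dropped_samples") <- drop
  attr(out, "qc_cutoff") <- cutoff
  out
}

#' Filter proteins by within-group completeness
#'
#' Keeps proteins detected in at least `min_fraction` of the samples of at
#' least one group under comparison. The fractional threshold is converted
#' to a whole-sample count by ceiling (70% of 6 samples means at least 5).
#' Typical settings: 0.7 for extracellular fluid, 0.9 for CSF.
#'
#' @param data Wide LFQ tibble.
#' @param design Tibble (`sample`, `group`).
#' @param min_fraction Required detection fraction within a group.
#' @param groups Optional subset of groups defining the comparison;
#'   defaults to every group present.
#' @return Filtered tibble (warning + empty tibble when nothing survives).
#' @export
filter_group_completeness <- function(data, design, min_fraction,
                                      groups = NULL) {
  m <- lfq_matrix_of(data)
  grp <- check_design(data, design)
  groups <- groups %||% unique(grp)
  keep <- rep(FALSE, nrow(m))
  for (g in groups) {
    cols <- which(grp == g)
    if (length(cols) == 0) abort(paste0("Group not in design: ", g))
    need <- ceiling(min_fraction * length(cols))
    keep <- keep | rowSums(!is.na(m[, cols, drop = FALSE])) >= need
  }
  if (!any(keep)) {
    warn("No protein passes the completeness filter; returning empty table.")
  }
  data[keep, , drop = FALSE]
}
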