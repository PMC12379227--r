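# End-to-end orchestration: photometry sessions, proteomics comparisons,
# and a fully synthetic demo run. Every artefact carries a provenance
# header (package version, seed, parameter hash) and reruns with identical
# inputs are byte-identical.

#' Run a full photometry session
#'
#' Executes the chain dF/F -> NREM-bout Welch PSD -> peak detection ->
#' oscillation metrics and writes the dF/F trace, averaged PSD, peak table
#' (TSV) and metrics (JSON) to `out_dir`.
#'
#' @param recording A photometry `recording` (channels `f465`, `f405`) or a
#'   path to one in TSV form.
#' @param hypnogram A `hypnogram` or TSV path.
#' @param out_dir Output directory (created if absent).
#' @param params Named list overriding [ne_metrics()] defaults.
#' @param method dF/F method, `"fitted_405"` or `"self_median"`.
#' @return The `ne_metrics` row, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_photometry_session <- function(recording, hypnogram, out_dir,
                                   params = list(),
                                   method = "fitted_405") {
  if (is.character(recording)) recording <- read_recording_tsv(recording)
  if (is.character(hypnogram)) hypnogram <- read_hypnogram_tsv(hypnogram)
  require_channels(recording, c("f465", "f405"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = rlang::hash(list(params, method)),
               method = method)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Photometry stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  dff <- stage("dff", compute_dff(recording, method = method))
  psd <- stage("nrem_psd", do.call(nrem_psd, c(
    list(dff = dff, hypnogram = hypnogram),
    params[intersect(names(params),
                     c("min_bout_s", "window_s", "overlap_frac",
                       "poly_order", "weighting"))])))
  peaks <- stage("peaks", do.call(detect_ne_peaks, c(
    list(dff = dff, hypnogram = hypnogram),
    params[intersect(names(params),
                     c("min_interval_s", "min_amplitude_pct",
                       "poly_order"))])))
  metrics <- stage("metrics", do.call(ne_metrics, c(
    list(dff = dff, hypnogram = hypnogram), params)))

  write_somno_tsv(dff, file.path(out_dir, "dff.tsv"), prov)
  write_somno_tsv(psd, file.path(out_dir, "nrem_psd.tsv"),
                  c(prov, n_bouts = attr(psd, "n_bouts_used")))
  write_somno_tsv(peaks, file.path(out_dir, "ne_peaks.tsv"),
                  c(prov, peak_rate_hz = attr(peaks, "peak_rate_hz")))
  jsonlite::write_json(
    c(as.list(metrics),
      list(provenance = c(prov,
                          package = as.character(packageVersion("somnoflow"))))),
    file.path(out_dir, "ne_metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}

#' Run a full proteomics comparison
#'
#' Executes sample QC -> group-completeness filtering -> mixed imputation
#' -> permutation t-test (-> Fisher/BH enrichment when gene sets are
#' given) and writes the filtered/imputed matrices, differential table, QC
#' summaries and enrichment table to `out_dir`.
#'
#' @param data Wide LFQ tibble or TSV path (blank cells = missing).
#' @param design Design tibble (`sample`, `group`) or TSV path.
#' @param out_dir Output directory.
#' @param group_pair The two groups to compare (defaults to those present).
#' @param gene_sets Optional named list (or GMT path) for enrichment.
#' @param min_completeness Group-completeness fraction (0.7 for
#'   ECF-like panels, 0.9 for CSF-like).
#' @param impute_params,test_params Named lists overriding
#'   [impute_mixed()] / [permutation_ttest()] defaults.
#' @param seed Seed forwarded to imputation and permutation sampling.
#' @return A list with `de` (the `perm_ttest` result), `qc`, and
#'   `enrichment` (or `NULL`), invisibly.
#' @export
run_proteomics <- function(data, design, out_dir, group_pair = NULL,
                           gene_sets = NULL, min_completeness = 0.7,
                           impute_params = list(), test_params = list(),
                           seed = 1) {
  if (is.character(data)) data <- read_somno_tsv(data)
  if (is.character(design)) design <- read_somno_tsv(design)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = rlang::hash(list(group_pair, min_completeness,
                                              impute_params, test_params,
                                              seed)),
               seed = seed)

  qc1 <- filter_sample_qc(data)
  design <- design[design$sample %in% names(qc1), ]
  filt <- filter_group_completeness(qc1, design, min_completeness,
                                    groups = group_pair)
  imp <- do.call(impute_mixed,
                 c(list(data = filt), impute_params,
                   if (!"seed" %in% names(impute_params)) list(seed = seed)))
  de <- do.call(permutation_ttest,
                c(list(data = imp, design = design,
                       group_pair = group_pair), test_params,
                  if (!"seed" %in% names(test_params)) list(seed = seed)))
  qc <- qc_summaries(imp, design)

  enr <- NULL
  if (!is.null(gene_sets) && any(de$significant)) {
    enr <- fisher_enrichment(de$protein[de$significant], de$protein,
                             gene_sets)
    write_somno_tsv(enr, file.path(out_dir, "enrichment.tsv"), prov)
  }
  write_somno_tsv(filt, file.path(out_dir, "matrix_filtered.tsv"), prov)
  write_somno_tsv(imp, file.path(out_dir, "matrix_imputed.tsv"), prov)
  write_somno_tsv(de, file.path(out_dir, "de_table.tsv"), prov)
  write_somno_tsv(qc$cv, file.path(out_dir, "qc_cv.tsv"), prov)
  write_somno_tsv(qc$correlation, file.path(out_dir, "qc_correlation.tsv"),
                  prov)
  if (!is.null(qc$pca)) {
    write_somno_tsv(qc$pca, file.path(out_dir, "qc_pca.tsv"), prov)
  }
  invisible(list(de = de, qc = qc, enrichment = enr))
}

#' Fully synthetic end-to-end demo
#'
#' Regenerates synthetic fixtures for every stage (hypnogram, EEG/EMG,
#' photometry, LFQ matrix, particle image, vessel profiles), runs the sleep,
#' photometry, proteomics and imaging analyses, and writes all artefacts
#' under `out_dir`. Deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Invisible named list of all stage results.
#' @export
run_demo <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(seed = seed)

  # --- sleep: 2 h at 5-s epochs, scored back against truth
  hyp <- sim_hypnogram(total_duration_s = 7200, epoch_length_s = 5,
                       seed = seed)
  rec <- sim_eeg_emg(hyp, sample_rate_hz = 256, seed = seed + 1)
  scored <- score_recording(rec, epoch_length_s = 5)
  arch <- architecture_stats(scored)
  write_hypnogram_tsv(hyp, file.path(out_dir, "hypnogram_truth.tsv"), prov)
  write_hypnogram_tsv(scored, file.path(out_dir, "hypnogram_scored.tsv"),
                      prov)
  write_somno_tsv(arch, file.path(out_dir, "architecture_stats.tsv"), prov)

  # --- photometry: ~1 h session at 1-s epochs, NREM-rich
  hyp_p <- sim_hypnogram(total_duration_s = 3600, epoch_length_s = 1,
                         transition_matrix = matrix(
                           c(0.98, 0.02, 0.00,
                             0.003, 0.994, 0.003,
                             0.02, 0.02, 0.96), 3, byrow = TRUE),
                         initial_state = "NREM", seed = seed + 2)
  phot <- sim_photometry(hyp_p, sample_rate_hz = 10, seed = seed + 3)
  metrics <- run_photometry_session(phot, hyp_p,
                                    file.path(out_dir, "photometry"))

  # --- proteomics: 6 vs 6 with 10% regulated proteins
  sim <- sim_lfq(600, c(sleep = 6, sd24 = 6), seed = seed + 4)
  gene_sets <- list(
    regulated_panel = sim$truth$protein[sim$truth$regulated],
    random_panel = sim$truth$protein[seq(5, 600, by = 7)])
  prot <- run_proteomics(sim$data, sim$design,
                         file.path(out_dir, "proteomics"),
                         gene_sets = gene_sets, seed = seed + 5)

  # --- imaging
  img <- sim_particle_image(c(50, 45, 20, 12, 3, 120), seed = seed + 6)
  particles <- particle_analysis(img$image, img$pixel_size_um)
  vess <- sim_vessel_profiles(
    tibble(peak_height = c(100, 60, 40),
           background_level = c(20, 20, 20),
           peak_position_um = c(10, 9, 11)),
    seed = seed + 7)
  aqp4 <- aqp4_polarization(vess$profiles)
  write_somno_tsv(particles, file.path(out_dir, "particle_summary.tsv"),
                  prov)
  write_somno_tsv(aqp4, file.path(out_dir, "aqp4_polarization.tsv"), prov)

  invisible(list(hypnogram = hyp, scored = scored, architecture = arch,
                 ne_metrics = metrics, proteomics = prot,
                 particles = particles, aqp4 = aqp4))
}
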