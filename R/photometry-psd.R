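# Infraslow NE oscillation quantification: per-bout detrended Welch PSD,
# prominence-based peak detection with minimum-interval suppression, and
# the combined metric record.

#' Averaged Welch PSD of the NE signal over NREM bouts
#'
#' For every NREM bout at least `max(min_bout_s, window_s)` long, the dF/F
#' segment is polynomial-detrended (centering it) and a Welch PSD computed;
#' bout PSDs are averaged on a common frequency grid with bout-duration
#' weights (or unweighted, see `weighting`).
#'
#' @param dff A `dff_trace` from [compute_dff()].
#' @param hypnogram Matching `hypnogram`.
#' @param min_bout_s Minimum qualifying bout duration, seconds.
#' @param window_s Welch window, seconds; 120 s resolves ~0.008 Hz bins
#'   around the ~0.02 Hz infraslow phenomenon.
#' @param overlap_frac Fractional window overlap.
#' @param poly_order Detrending polynomial order (0-5).
#' @param weighting `"duration"` (default) or `"equal"` bout weights.
#' @return A `somno_psd` tibble (`freq_hz`, `power`), with
#'   `attr(, "per_bout")` (list of per-bout PSDs) and
#'   `attr(, "n_bouts_used")`.
#' @export
nrem_psd <- function(dff, hypnogram, min_bout_s = 120, window_s = 120,
                     overlap_frac = 0.5, poly_order = 2,
                     weighting = c("duration", "equal")) {
  weighting <- match.arg(weighting)
  if (!poly_order %in% 0:5) abort("poly_order must be an integer in 0..5.")
  fs <- attr(dff, "sample_rate_hz") %||% (1 / median(diff(dff$time_s)))
  bouts <- extract_bouts(hypnogram)
  need <- max(min_bout_s, window_s)
  bouts <- bouts[bouts$state == "NREM" & bouts$duration_s >= need, ]
  if (nrow(bouts) == 0) {
    abort(paste0("Insufficient NREM: no bout of at least ", need, " s."))
  }
  t0 <- dff$time_s[1]
  psds <- purrr::map(seq_len(nrow(bouts)), function(i) {
    i0 <- max(1, floor((bouts$start_s[i] - t0) * fs) + 1)
    i1 <- min(nrow(dff), floor((bouts$end_s[i] - t0) * fs))
    seg <- detrend_segment(dff$dff_pct[i0:i1], poly_order)
    welch_psd(seg, fs, window_s, overlap_frac)
  })
  w <- if (weighting == "duration") bouts$duration_s
       else rep(1, nrow(bouts))
  out <- average_psds(psds, weights = w)
  attr(out, "per_bout") <- psds
  attr(out, "n_bouts_used") <- nrow(bouts)
  attr(out, "bouts") <- bouts
  out
}

#' Detect NE peaks during NREM sleep
#'
#' Within each NREM bout the dF/F segment is polynomial-detrended and local
#' maxima are located; a candidate's amplitude is its topographic
#' prominence above the detrended local baseline. Candidates below
#' `min_amplitude_pct` are discarded; among peaks closer than
#' `min_interval_s` the taller survives (ties go to the earlier peak). Bout
#' boundaries are hard edges: the minimum interval is not enforced across
#' bouts. The peak rate divides the surviving count by the total NREM time.
#'
#' @param dff A `dff_trace`.
#' @param hypnogram Matching `hypnogram`.
#' @param min_interval_s Minimum interval between surviving peaks (10 s).
#' @param min_amplitude_pct Minimum prominence in %dF/F (0.5).
#' @param poly_order Detrending order applied per bout.
#' @return A tibble (`time_s`, `height_pct`, `bout`) of surviving peaks
#'   with `attr(, "peak_rate_hz")` (count / total NREM seconds) and
#'   `attr(, "total_nrem_s")`.
#' @export
detect_ne_peaks <- function(dff, hypnogram, min_interval_s = 10,
                            min_amplitude_pct = 0.5, poly_order = 2) {
  fs <- attr(dff, "sample_rate_hz") %||% (1 / median(diff(dff$time_s)))
  bouts <- extract_bouts(hypnogram)
  bouts <- bouts[bouts$state == "NREM", ]
  if (nrow(bouts) == 0) abort("Hypnogram contains no NREM time.")
  total_nrem_s <- sum(bouts$duration_s)
  t0 <- dff$time_s[1]
  peaks <- purrr::map_dfr(seq_len(nrow(bouts)), function(i) {
    i0 <- max(1, floor((bouts$start_s[i] - t0) * fs) + 1)
    i1 <- min(nrow(dff), floor((bouts$end_s[i] - t0) * fs))
    if (i1 - i0 < poly_order + 2) return(NULL)
    seg <- detrend_segment(dff$dff_pct[i0:i1], poly_order)
    cand <- local_maxima(seg)
    if (length(cand) == 0) return(NULL)
    prom <- peak_prominence(seg, cand)
    keep <- prom >= min_amplitude_pct
    cand <- cand[keep]; prom <- prom[keep]
    if (length(cand) == 0) return(NULL)
    tt <- dff$time_s[i0 + cand - 1]
    sel <- suppress_peaks(tt, prom, min_interval_s)
    tibble(time_s = tt[sel], height_pct = prom[sel], bout = i)
  })
  if (is.null(peaks) || nrow(peaks) == 0) {
    peaks <- tibble(time_s = numeric(0), height_pct = numeric(0),
                    bout = integer(0))
  }
  attr(peaks, "peak_rate_hz") <- nrow(peaks) / total_nrem_s
  attr(peaks, "total_nrem_s") <- total_nrem_s
  peaks
}

#' Infraslow NE oscillation metrics
#'
#' Assembles the NREM-sleep NE oscillation summary: PSD amplitude (maximum
#' of the bout-averaged PSD within the analysis band), PSD peak frequency
#' (its argmax), infraslow band power (trapezoid integral of the averaged
#' PSD over the band), and the detected peak rate. Amplitude-vs-integral
#' ambiguity is resolved by emitting both.
#'
#' @param dff A `dff_trace`.
#' @param hypnogram Matching `hypnogram`.
#' @param band Infraslow analysis band in Hz (default 0.005-0.1).
#' @inheritParams nrem_psd
#' @inheritParams detect_ne_peaks
#' @return A one-row tibble of class `ne_metrics`: `psd_amplitude`,
#'   `psd_peak_freq_hz`, `infraslow_power`, `peak_rate_hz`, `n_bouts_used`.
#'   The averaged PSD is attached as `attr(, "psd")`.
#' @export
ne_metrics <- function(dff, hypnogram, band = c(0.005, 0.1),
                       min_bout_s = 120, window_s = 120,
                       overlap_frac = 0.5, poly_order = 2,
                       min_interval_s = 10, min_amplitude_pct = 0.5,
                       weighting = "duration") {
  psd <- nrem_psd(dff, hypnogram, min_bout_s, window_s, overlap_frac,
                  poly_order, weighting)
  peaks <- detect_ne_peaks(dff, hypnogram, min_interval_s,
                           min_amplitude_pct, poly_order)
  sel <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  if (!any(sel)) abort("No PSD bins inside the analysis band.")
  f <- psd$freq_hz[sel]; p <- psd$power[sel]
  out <- tibble(
    psd_amplitude = max(p),
    psd_peak_freq_hz = f[which.max(p)],
    infraslow_power = trapezoid(f, p),
    peak_rate_hz = attr(peaks, "peak_rate_hz"),
    n_bouts_used = attr(psd, "n_bouts_used")
  )
  class(out) <- c("ne_metrics", class(out))
  attr(out, "psd") <- psd
  attr(out, "peaks") <- peaks
  attr(out, "band") <- band
  out
}
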