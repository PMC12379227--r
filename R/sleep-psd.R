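# State-restricted EEG spectra, band power, and the slow-wave-activity
# (SWA) time course.

#' Welch EEG spectrum restricted to one vigilance state
#'
#' Computes a Welch PSD per qualifying bout of the requested state (bouts at
#' least one Welch window long) and averages them with bout-duration
#' weights.
#'
#' @param recording A `recording` with an `eeg` channel.
#' @param hypnogram Matching `hypnogram`.
#' @param state State to analyse (`"NREM"` by default, as for slow-wave
#'   spectra).
#' @param window_s Welch window length, seconds (4 s resolves 1 Hz delta
#'   bins by default).
#' @param overlap_frac Fractional window overlap.
#' @return A `somno_psd` tibble (`freq_hz`, `power`) with
#'   `attr(, "n_bouts")`.
#' @export
state_psd <- function(recording, hypnogram, state = "NREM",
                      window_s = 4, overlap_frac = 0.5) {
  require_channels(recording, "eeg")
  state <- match.arg(state, .states)
  fs <- sample_rate(recording)
  bouts <- extract_bouts(hypnogram)
  bouts <- bouts[bouts$state == state & bouts$duration_s >= window_s, ]
  if (nrow(bouts) == 0) {
    abort(paste0("Insufficient data: no ", state,
                 " bout of at least one Welch window (", window_s, " s)."))
  }
  t0 <- recording$time_s[1]
  psds <- purrr::map(seq_len(nrow(bouts)), function(i) {
    i0 <- max(1, floor((bouts$start_s[i] - t0) * fs) + 1)
    i1 <- min(nrow(recording), floor((bouts$end_s[i] - t0) * fs))
    welch_psd(recording$eeg[i0:i1], fs, window_s, overlap_frac)
  })
  average_psds(psds, weights = bouts$duration_s)
}

# Duration-weighted average of PSDs sharing window length and sampling
# rate; grids are interpolated onto the first PSD's grid if they differ.
average_psds <- function(psds, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(psds))
  grid <- psds[[1]]$freq_hz
  mat <- vapply(psds, function(p) {
    if (length(p$freq_hz) == length(grid) &&
        all(abs(p$freq_hz - grid) < 1e-12)) {
      p$power
    } else {
      approx(p$freq_hz, p$power, xout = grid, rule = 2)$y
    }
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  out <- tibble(freq_hz = grid,
                power = as.numeric(mat %*% (weights / sum(weights))))
  class(out) <- c("somno_psd", class(out))
  attr(out, "n_bouts") <- length(psds)
  attr(out, "bout_weights") <- weights
  out
}

#' Mean PSD power within a frequency band
#'
#' Arithmetic mean of the PSD bins with `f_lo <= f < f_hi` (half-open, so
#' delta 1-4 Hz and theta 4-8 Hz never share the 4 Hz bin).
#'
#' @param psd A PSD tibble (`freq_hz`, `power`).
#' @param f_lo,f_hi Band edges in Hz.
#' @return Mean power (scalar).
#' @export
band_power <- function(psd, f_lo, f_hi) {
  if (!(f_lo >= 0 && f_lo < f_hi)) abort("Require 0 <= f_lo < f_hi.")
  band_mean(psd$freq_hz, psd$power, f_lo, f_hi)
}

#' Slow-wave-activity time course
#'
#' Bins the recording into `bin_s`-long intervals and expresses each bin's
#' mean per-epoch NREM delta power as a percentage of a baseline delta
#' power. Because power scales with the square of amplitude, a 1.5x delta
#' amplitude rebound appears as ~225% SWA. Bins without any NREM epoch are
#' `NA`, not zero.
#'
#' @param recording A `recording` with an `eeg` channel.
#' @param hypnogram Matching `hypnogram`.
#' @param baseline Either a single reference delta-power value, or
#'   `c(start_s, end_s)` designating a baseline interval of this recording
#'   whose mean NREM delta power is used.
#' @param bin_s Bin width in seconds (1 h default).
#' @param epoch_length_s Epoch length used for per-epoch delta power;
#'   defaults to the hypnogram's.
#' @param band Delta band, Hz.
#' @return A tibble: `bin_start_s`, `n_nrem_epochs`, `delta_power`,
#'   `swa_pct`.
#' @export
swa_timecourse <- function(recording, hypnogram, baseline, bin_s = 3600,
                           epoch_length_s = NULL, band = c(1, 4)) {
  require_channels(recording, "eeg")
  el <- epoch_length_s %||% epoch_length(hypnogram)
  fs <- sample_rate(recording)
  npe <- round(el * fs)
  n_ep <- min(nrow(hypnogram), nrow(recording) %/% npe)
  delta <- vapply(seq_len(n_ep), function(i) {
    pg <- periodogram(recording$eeg[((i - 1) * npe + 1):(i * npe)], fs)
    band_mean(pg$freq_hz, pg$power, band[1], band[2])
  }, numeric(1))
  t_start <- hypnogram$t_start_s[seq_len(n_ep)]
  nrem <- hypnogram$state[seq_len(n_ep)] == "NREM"

  base_val <- if (length(baseline) == 2) {
    sel <- nrem & t_start >= baseline[1] & t_start < baseline[2]
    if (!any(sel)) abort("No NREM epochs inside the baseline interval.")
    mean(delta[sel])
  } else {
    as.numeric(baseline)
  }
  if (!is.finite(base_val) || base_val <= 0) {
    abort("Baseline delta power must be positive and finite.")
  }
  bin <- floor((t_start - t_start[1]) / bin_s)
  purrr::map_dfr(sort(unique(bin)), function(b) {
    sel <- bin == b & nrem
    dp <- if (any(sel)) mean(delta[sel]) else NA_real_
    tibble(bin_start_s = t_start[1] + b * bin_s,
           n_nrem_epochs = sum(sel),
           delta_power = dp,
           swa_pct = 100 * dp / base_val)
  })
}
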