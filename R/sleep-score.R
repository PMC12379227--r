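# Vigilance-state scoring: per-epoch spectral/EMG features and a
# transparent threshold tree over them.

#' Per-epoch EEG/EMG features
#'
#' Splits the recording into fixed-length epochs (trailing partial epoch
#' dropped) and computes, per epoch, delta (1-4 Hz) and theta (4-8 Hz) band
#' power from the raw periodogram, their ratios, EMG root-mean-square and
#' EEG RMS amplitude. Band intervals are half-open `[lo, hi)` so the shared
#' 4 Hz edge is counted once.
#'
#' @param recording A `recording` with channels `eeg` and `emg`.
#' @param epoch_length_s Epoch length in seconds (5 s standalone, 1 s when
#'   aligned with photometry).
#' @param bands Named list of `c(f_lo, f_hi)` band definitions; `delta` and
#'   `theta` are required for downstream scoring.
#' @return A tibble with one row per complete epoch: `epoch`, `t_start_s`,
#'   one `<band>_power` column per band, `theta_delta_ratio`, `emg_rms`,
#'   `eeg_amplitude`.
#' @export
epoch_features <- function(recording, epoch_length_s = 5,
                           bands = list(delta = c(1, 4), theta = c(4, 8))) {
  require_channels(recording, c("eeg", "emg"))
  fs <- sample_rate(recording)
  npe <- round(epoch_length_s * fs)
  n_ep <- nrow(recording) %/% npe
  if (n_ep < 1) abort("Recording shorter than one epoch.")
  stopifnot(all(c("delta", "theta") %in% names(bands)))

  rows <- purrr::map_dfr(seq_len(n_ep), function(i) {
    idx <- ((i - 1) * npe + 1):(i * npe)
    pg <- periodogram(recording$eeg[idx], fs)
    bp <- purrr::map_dbl(bands, function(b) {
      band_mean(pg$freq_hz, pg$power, b[1], b[2])
    })
    tibble(
      epoch = i,
      t_start_s = recording$time_s[idx[1]],
      !!!setNames(as.list(bp), paste0(names(bands), "_power")),
      emg_rms = sqrt(mean(recording$emg[idx]^2)),
      eeg_amplitude = sqrt(mean(recording$eeg[idx]^2))
    )
  })
  rows$theta_delta_ratio <- rows$theta_power / rows$delta_power
  attr(rows, "epoch_length_s") <- epoch_length_s
  rows
}

#' Score epochs with a threshold decision tree
#'
#' The rule mirrors standard manual criteria: high muscle tone means WAKE
#' regardless of the EEG; among atonic epochs, delta dominance
#' (`delta_power / theta_power` above threshold) means NREM; the remainder
#' (atonic, theta-dominated, low amplitude) is REM. When `thresholds` is
#' `NULL` each threshold is auto-calibrated as the midpoint between the two
#' 1-d k-means cluster centres of the relevant feature (EMG RMS on a log
#' scale over all epochs; the delta/theta ratio on a log scale over the
#' atonic epochs).
#'
#' @param features Output of [epoch_features()].
#' @param thresholds Optional named list with `emg_rms_hi`,
#'   `delta_ratio_hi` and (reserved for custom rule variants)
#'   `theta_ratio_hi`.
#' @return A `hypnogram` tibble; the thresholds used are stored in
#'   `attr(, "thresholds")`.
#' @export
score_epochs <- function(features, thresholds = NULL) {
  if (nrow(features) == 0) abort("Feature table is empty.")
  delta_ratio <- features$delta_power / features$theta_power
  if (is.null(thresholds)) {
    atonic <- features$emg_rms <=
      10^two_means_threshold(log10(features$emg_rms + 1e-12))
    thresholds <- list(
      emg_rms_hi = 10^two_means_threshold(log10(features$emg_rms + 1e-12)),
      delta_ratio_hi = if (any(atonic)) {
        10^two_means_threshold(log10(delta_ratio[atonic] + 1e-12))
      } else {
        1
      },
      theta_ratio_hi = NA_real_
    )
  }
  if (!all(is.finite(c(thresholds$emg_rms_hi, thresholds$delta_ratio_hi)))) {
    # +/-Inf thresholds are legal (they force fall-through); NA is not
    if (anyNA(c(thresholds$emg_rms_hi, thresholds$delta_ratio_hi))) {
      abort("Thresholds must not be NA.")
    }
  }
  state <- ifelse(features$emg_rms > thresholds$emg_rms_hi, "WAKE",
                  ifelse(delta_ratio > thresholds$delta_ratio_hi,
                         "NREM", "REM"))
  h <- hypnogram(state,
                 epoch_length_s = attr(features, "epoch_length_s") %||%
                   diff(features$t_start_s[1:2]),
                 start_time_s = features$t_start_s[1])
  attr(h, "thresholds") <- thresholds
  h
}

#' Score a recording end to end
#'
#' Convenience wrapper: [epoch_features()] then [score_epochs()].
#'
#' @inheritParams epoch_features
#' @inheritParams score_epochs
#' @return A `hypnogram`.
#' @export
score_recording <- function(recording, epoch_length_s = 5,
                            thresholds = NULL) {
  score_epochs(epoch_features(recording, epoch_length_s), thresholds)
}
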