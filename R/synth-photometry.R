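# Synthetic two-channel fiber photometry with ground-truth NE dynamics.

#' Simulate a two-channel (465/405 nm) photometry recording
#'
#' The isosbestic channel is an exponential bleaching baseline plus a slow
#' motion artefact plus white noise. The signal channel is the affine image
#' of the shared (noise-free) baseline — gain `true_gain_a`, offset
#' `true_offset_b` — scaled multiplicatively by the norepinephrine (NE)
#' component: a sinusoid at `osc_freq_hz` during NREM epochs (the infraslow
#' oscillation, ~0.02 Hz) and a raised plateau during WAKE. Because motion
#' enters both channels before the gain, isosbestic regression can remove it
#' exactly. The noiseless NE component (in %dF/F) is returned as ground
#' truth.
#'
#' @param hypnogram A `hypnogram` defining the state gating.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param bleach_tau_s Exponential bleaching time constant, seconds.
#' @param osc_freq_hz NREM infraslow oscillation frequency, Hz (must be
#'   below Nyquist).
#' @param osc_amp_pct Oscillation amplitude in %dF/F.
#' @param wake_level_pct WAKE plateau in %dF/F.
#' @param motion_amp Amplitude of the shared slow motion artefact
#'   (signal units).
#' @param noise_sd Per-channel white-noise SD (signal units).
#' @param true_gain_a,true_offset_b Affine coupling between channels.
#' @param f405_base Initial isosbestic level (signal units).
#' @param seed Integer seed.
#' @return A `recording` with channels `f465`, `f405` and the truth column
#'   `ne_true_pct`; `attr(, "truth")` holds gain/offset and the hypnogram.
#' @examples
#' h <- hypnogram(rep("NREM", 600), epoch_length_s = 1)
#' rec <- sim_photometry(h, sample_rate_hz = 20, seed = 1)
#' @export
sim_photometry <- function(hypnogram,
                           sample_rate_hz = 100,
                           bleach_tau_s = 3600,
                           osc_freq_hz = 0.02,
                           osc_amp_pct = 2,
                           wake_level_pct = 2,
                           motion_amp = 0,
                           noise_sd = 2e-4,
                           true_gain_a = 1.8,
                           true_offset_b = 0.2,
                           f405_base = 1,
                           seed = 1) {
  if (nrow(hypnogram) == 0) abort("Hypnogram is empty.")
  if (sample_rate_hz <= 0) abort("sample_rate_hz must be positive.")
  if (osc_freq_hz >= sample_rate_hz / 2) {
    abort("osc_freq_hz must be below the Nyquist frequency.")
  }
  if (osc_amp_pct < 0) abort("osc_amp_pct must be >= 0.")
  el <- epoch_length(hypnogram)
  n <- round(nrow(hypnogram) * el * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  state <- hypnogram$state[pmin(floor(t / el) + 1, nrow(hypnogram))]

  ne <- numeric(n)
  nrem <- state == "NREM"
  ne[nrem] <- osc_amp_pct * sin(2 * pi * osc_freq_hz * t[nrem])
  ne[state == "WAKE"] <- wake_level_pct

  ch <- with_seed_(seed, {
    bleach <- f405_base * exp(-t / bleach_tau_s)
    motion <- if (motion_amp > 0) {
      # slow artefact: AR(1)-smoothed noise, scaled to the requested RMS
      m <- as.numeric(stats::filter(rnorm(n), 0.999, method = "recursive"))
      motion_amp * m / max(sd(m), .Machine$double.eps)
    } else {
      numeric(n)
    }
    shared <- bleach + motion
    list(
      f405 = shared + noise_sd * rnorm(n),
      f465 = (true_gain_a * shared + true_offset_b) * (1 + ne / 100) +
        noise_sd * rnorm(n)
    )
  })
  rec <- recording(
    tibble(f465 = ch$f465, f405 = ch$f405, ne_true_pct = ne),
    sample_rate_hz)
  attr(rec, "truth") <- list(true_gain_a = true_gain_a,
                             true_offset_b = true_offset_b,
                             osc_freq_hz = osc_freq_hz,
                             osc_amp_pct = osc_amp_pct,
                             wake_level_pct = wake_level_pct,
                             hypnogram = hypnogram)
  rec
}
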