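# Synthetic sleep data: Markov hypnograms and state-conditioned EEG/EMG.

#' Simulate a hypnogram from a first-order Markov chain
#'
#' States evolve per epoch according to a row-stochastic transition matrix
#' over (WAKE, NREM, REM). The default matrix produces mouse-like inactive
#' phase architecture: long consolidated NREM, brief REM entered only from
#' NREM, and intermittent wake.
#'
#' @param total_duration_s Total duration in seconds; must be a positive
#'   multiple of `epoch_length_s`.
#' @param epoch_length_s Epoch length in seconds (5 s for standalone sleep
#'   scoring, 1 s when aligned with photometry).
#' @param transition_matrix 3x3 row-stochastic matrix in state order
#'   WAKE, NREM, REM.
#' @param initial_state Starting state.
#' @param seed Integer seed; generation is a pure function of the spec and
#'   seed.
#' @return A `hypnogram` tibble.
#' @examples
#' h <- sim_hypnogram(3600, seed = 1)
#' table(h$state)
#' @export
sim_hypnogram <- function(total_duration_s,
                          epoch_length_s = 5,
                          transition_matrix = default_transition_matrix(),
                          initial_state = "WAKE",
                          seed = 1) {
  if (epoch_length_s <= 0) abort("epoch_length_s must be positive.")
  n <- total_duration_s / epoch_length_s
  if (total_duration_s <= 0 || abs(n - round(n)) > 1e-9) {
    abort("total_duration_s must be a positive multiple of epoch_length_s.")
  }
  n <- as.integer(round(n))
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(3, 3)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9)) {
    abort("transition_matrix must be 3x3 row-stochastic (rows sum to 1).")
  }
  initial_state <- match.arg(initial_state, .states)
  idx <- with_seed_(seed, {
    s <- integer(n)
    s[1] <- match(initial_state, .states)
    if (n > 1) {
      u <- runif(n - 1)
      cp <- t(apply(P, 1, cumsum))
      for (i in 2:n) {
        s[i] <- 1L + sum(u[i - 1] > cp[s[i - 1], ])
      }
    }
    s
  })
  hypnogram(.states[idx], epoch_length_s = epoch_length_s)
}

#' @rdname sim_hypnogram
#' @export
default_transition_matrix <- function() {
  matrix(c(0.90, 0.10, 0.00,
           0.05, 0.90, 0.05,
           0.20, 0.30, 0.50),
         nrow = 3, byrow = TRUE,
         dimnames = list(.states, .states))
}

#' Simulate an EEG/EMG recording from a hypnogram
#'
#' Each epoch's EEG is a sum of a delta-band (1-4 Hz) and a theta-band
#' (4-8 Hz) sinusoid with random per-epoch frequency and phase plus white
#' noise, with state-dependent amplitudes: NREM is delta-dominated and high
#' amplitude, REM theta-dominated, WAKE broadband and low amplitude. EMG is
#' white noise whose RMS is high in WAKE and near-floor in sleep. The
#' generating hypnogram is attached as ground truth.
#'
#' @param hypnogram A `hypnogram`.
#' @param sample_rate_hz Sampling rate (>= 200 Hz).
#' @param seed Integer seed.
#' @param amplitudes Named list of per-state component amplitudes; see
#'   `default_eeg_amplitudes()`.
#' @param delta_gain Scalar or per-epoch vector multiplying the delta
#'   component amplitude (used e.g. to emulate slow-wave-activity rebound).
#' @return A `recording` with channels `eeg` and `emg`; the truth hypnogram
#'   is in `attr(, "hypnogram")`.
#' @export
sim_eeg_emg <- function(hypnogram, sample_rate_hz = 512, seed = 1,
                        amplitudes = default_eeg_amplitudes(),
                        delta_gain = 1) {
  if (nrow(hypnogram) == 0) abort("Hypnogram is empty.")
  if (sample_rate_hz < 200) abort("sample_rate_hz must be >= 200 Hz.")
  el <- epoch_length(hypnogram)
  npe <- round(el * sample_rate_hz)
  n_ep <- nrow(hypnogram)
  delta_gain <- rep_len(delta_gain, n_ep)
  sig <- with_seed_(seed, {
    eeg <- numeric(n_ep * npe)
    emg <- numeric(n_ep * npe)
    tt <- (seq_len(npe) - 1) / sample_rate_hz
    for (i in seq_len(n_ep)) {
      a <- amplitudes[[hypnogram$state[i]]]
      # keep the tones inside their bands: the 0.2 Hz periodogram grid of a
      # 5-s epoch leaks boundary tones across the shared 4 Hz edge
      f_d <- runif(1, 1.5, 3.5)
      f_t <- runif(1, 4.5, 7.5)
      ph <- runif(2, 0, 2 * pi)
      idx <- ((i - 1) * npe + 1):(i * npe)
      eeg[idx] <- delta_gain[i] * a$delta * sin(2 * pi * f_d * tt + ph[1]) +
        a$theta * sin(2 * pi * f_t * tt + ph[2]) +
        a$noise * rnorm(npe)
      emg[idx] <- a$emg_rms * rnorm(npe)
    }
    list(eeg = eeg, emg = emg)
  })
  rec <- recording(tibble(eeg = sig$eeg, emg = sig$emg), sample_rate_hz)
  attr(rec, "hypnogram") <- hypnogram
  rec
}

#' @rdname sim_eeg_emg
#' @export
default_eeg_amplitudes <- function() {
  list(
    WAKE = list(delta = 0.2, theta = 0.3, noise = 1.0, emg_rms = 1.0),
    NREM = list(delta = 2.0, theta = 0.3, noise = 0.3, emg_rms = 0.05),
    REM  = list(delta = 0.3, theta = 1.5, noise = 0.3, emg_rms = 0.05)
  )
}
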