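# Internal numerical helpers shared across modules.

#' Welch power spectral density estimate
#'
#' Estimates a one-sided power spectral density by averaging modified
#' periodograms of overlapping, Hann-tapered, per-segment demeaned windows.
#' Power is normalised so that the integral of the density over frequency
#' approximates the series variance (Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds.
#' @param overlap_frac Fractional overlap between consecutive segments
#'   (0 to <1).
#' @return A tibble with columns `freq_hz` and `power` (units of
#'   `x`^2 per Hz), of class `somno_psd`.
#' @examples
#' t <- seq(0, 60, by = 1 / 50)
#' psd <- welch_psd(sin(2 * pi * 2 * t), fs = 50, window_s = 4)
#' psd$freq_hz[which.max(psd$power)]
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap_frac = 0.5) {
  stopifnot(is.numeric(x), fs > 0, window_s > 0,
            overlap_frac >= 0, overlap_frac < 1)
  nper <- round(window_s * fs)
  if (nper < 4) abort("Welch window shorter than 4 samples.")
  if (length(x) < nper) {
    abort("Series shorter than one Welch segment: insufficient data.")
  }
  step <- max(1L, round(nper * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann_window(nper)
  u <- sum(w^2)                       # window power normalisation
  nfreq <- nper %/% 2 + 1L
  seg <- vapply(starts, function(s) {
    xs <- x[s:(s + nper - 1L)]
    xs <- (xs - mean(xs)) * w
    (Mod(fft(xs))^2 / (fs * u))[seq_len(nfreq)]
  }, numeric(nfreq))
  p <- rowMeans(seg)
  # fold negative frequencies into the one-sided density
  if (nper %% 2 == 0) {
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  } else {
    p[2:nfreq] <- 2 * p[2:nfreq]
  }
  out <- tibble(freq_hz = (seq_len(nfreq) - 1) * fs / nper, power = p)
  class(out) <- c("somno_psd", class(out))
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  attr(out, "n_segments") <- length(starts)
  out
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# One-sided raw periodogram (rectangular window); used for per-epoch band
# power where exact sinusoid bin alignment matters.
periodogram <- function(x, fs) {
  n <- length(x)
  nfreq <- n %/% 2 + 1L
  p <- (Mod(fft(x))^2 / (fs * n))[seq_len(nfreq)]
  if (n %% 2 == 0) p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  else p[2:nfreq] <- 2 * p[2:nfreq]
  list(freq_hz = (seq_len(nfreq) - 1) * fs / n, power = p)
}

# Mean power over [f_lo, f_hi); half-open so the shared 4 Hz edge between
# delta and theta is counted once.
band_mean <- function(freq_hz, power, f_lo, f_hi) {
  sel <- freq_hz >= f_lo & freq_hz < f_hi
  if (!any(sel)) abort("No frequency bins fall inside the requested band.")
  mean(power[sel])
}

#' Polynomial detrending of a signal segment
#'
#' Fits a least-squares polynomial of the given order against time and
#' returns the residual. With an intercept in the fit the residual mean is
#' zero to machine precision.
#'
#' @param x Numeric segment.
#' @param poly_order Polynomial order (0 = remove mean only).
#' @return Numeric residual of the same length as `x`.
#' @export
detrend_segment <- function(x, poly_order = 2) {
  n <- length(x)
  if (!is.numeric(x) || n <= poly_order + 1) {
    abort("Segment too short for the requested polynomial order.")
  }
  if (poly_order == 0) return(x - mean(x))
  tt <- seq(0, 1, length.out = n)
  basis <- stats::poly(tt, degree = poly_order, raw = FALSE)
  stats::lm.fit(cbind(1, basis), x)$residuals
}

# Indices of strict local maxima; plateaus contribute their first sample.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of each candidate peak: height above the higher of
# the two key saddles (lowest point between the peak and the nearest
# higher terrain on each side; the segment edge if none).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1) x[1:(p - 1)] else numeric(0)
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    saddle <- function(side, rev_side) {
      v <- if (rev_side) rev(side) else side
      higher <- which(v > h)
      if (length(higher) == 0) min(v, h) else min(v[seq_len(higher[1] - 1)], h)
    }
    lmin <- if (length(left)) saddle(left, rev_side = TRUE) else h
    rmin <- if (length(right)) saddle(right, rev_side = FALSE) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

# Greedy minimum-interval suppression: tallest first (ties -> earlier),
# keep a candidate only if it sits >= min_interval from every kept one.
suppress_peaks <- function(times, heights, min_interval) {
  ord <- order(-heights, times)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(times[i] - times[kept]) >= min_interval)) kept <- c(kept, i)
  }
  sort(kept)
}

# Midpoint between the two 1-d k-means cluster centres; deterministic
# (centres seeded at the data range).
two_means_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) return(max(x))
  km <- kmeans(x, centers = matrix(range(x), ncol = 1))
  mean(km$centers)
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Seed guard: all generators funnel randomness through this.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) abort("A seed is required for reproducible generation.")
  withr::with_seed(as.integer(seed), code)
}
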