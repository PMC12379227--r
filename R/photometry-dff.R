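# Isosbestic correction: least-squares scaling of the 405 nm channel and
# dF/F computation.

#' Fit the scaled isosbestic (405 nm) channel
#'
#' Ordinary least squares of the 465 nm signal channel on the 405 nm
#' isosbestic channel, giving the slope `a` and intercept `b` of the scaled
#' control channel `a * f405 + b`. Because bleaching and motion artefacts
#' appear in both channels, this affine fit captures the NE-independent
#' component of the signal.
#'
#' @param data A data frame with columns `f465` and `f405`, or a numeric
#'   vector of 465 nm values (then `f405` must be supplied).
#' @param f405 Optional numeric 405 nm vector when `data` is a vector.
#' @return An object of class `isosbestic_fit` with elements `a`, `b`,
#'   `residual_sd`, `r_squared`, `n`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' fit_isosbestic(data.frame(f405 = 1:10, f465 = 2 * (1:10) + 1))
#' @export
fit_isosbestic <- function(data, f405 = NULL) {
  if (is.data.frame(data)) {
    require_channels(data, c("f465", "f405"))
    y <- data$f465; x <- data$f405
  } else {
    y <- data; x <- f405
  }
  if (length(x) != length(y) || length(x) < 2) {
    abort("f465 and f405 must be equal-length series of length >= 2.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("Channels must be finite.")
  }
  vx <- var(x)
  if (vx <= .Machine$double.eps * max(1, mean(x)^2)) {
    abort("Singular fit: the 405 nm channel is constant.")
  }
  a <- cov(x, y) / vx
  b <- mean(y) - a * mean(x)
  res <- y - (a * x + b)
  vy <- var(y)
  structure(
    list(a = a, b = b,
         residual_sd = sd(res),
         r_squared = if (vy > 0) 1 - var(res) / vy else NA_real_,
         n = length(x)),
    class = "isosbestic_fit")
}

#' @export
print.isosbestic_fit <- function(x, ...) {
  cat(sprintf(
    "Isosbestic fit: scaled405 = %.6g * f405 + %.6g  (n = %d, R2 = %.4f)\n",
    x$a, x$b, x$n, x$r_squared))
  invisible(x)
}

#' Compute the dF/F trace
#'
#' `fitted_405` subtracts and divides by the scaled isosbestic channel:
#' `dF/F(%) = (f465 - (a*f405 + b)) * 100 / (a*f405 + b)`. `self_median`
#' uses the median of the signal channel itself as the baseline:
#' `dF/F(%) = (f465 - median(f465)) * 100 / median(f465)`.
#'
#' @param data A data frame with `f465`, `f405` (and optionally `time_s`)
#'   columns, e.g. a photometry `recording`.
#' @param method `"fitted_405"` (default) or `"self_median"`.
#' @param fit Optional precomputed [fit_isosbestic()] result.
#' @return A tibble of class `dff_trace` with columns `time_s` and
#'   `dff_pct`; the fit and method are stored as attributes.
#' @export
compute_dff <- function(data, method = c("fitted_405", "self_median"),
                        fit = NULL) {
  method <- match.arg(method)
  require_channels(data, "f465")
  fs <- attr(data, "sample_rate_hz") %||%
    (if ("time_s" %in% names(data)) 1 / median(diff(data$time_s)) else 1)
  time_s <- if ("time_s" %in% names(data)) data$time_s
            else (seq_len(nrow(data)) - 1) / fs
  if (method == "fitted_405") {
    require_channels(data, "f405")
    fit <- fit %||% fit_isosbestic(data)
    baseline <- fit$a * data$f405 + fit$b
  } else {
    baseline <- rep(median(data$f465), nrow(data))
  }
  bad <- which(baseline <= 0)
  if (length(bad)) {
    abort(paste0("Scaled baseline channel is <= 0 at sample index ", bad[1],
                 "; cannot divide."))
  }
  out <- tibble(time_s = time_s,
                dff_pct = (data$f465 - baseline) * 100 / baseline)
  class(out) <- c("dff_trace", class(out))
  attr(out, "sample_rate_hz") <- fs
  attr(out, "method") <- method
  attr(out, "fit") <- fit
  out
}
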