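# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an isosbestic fit
#'
#' @param x An `isosbestic_fit`.
#' @param ... Unused.
#' @return One row per coefficient (`slope`, `intercept`).
#' @method tidy isosbestic_fit
#' @export
tidy.isosbestic_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"), estimate = c(x$a, x$b))
}

#' @rdname tidy.isosbestic_fit
#' @return `glance()`: a one-row model summary.
#' @method glance isosbestic_fit
#' @export
glance.isosbestic_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, residual_sd = x$residual_sd, n = x$n)
}

#' Tidy a permutation t-test result
#'
#' @param x A `perm_ttest`.
#' @param ... Unused.
#' @return `tidy()`: the per-protein table as a plain tibble; `glance()`:
#'   a one-row summary (counts, s0, permutations used).
#' @method tidy perm_ttest
#' @export
tidy.perm_ttest <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "perm_ttest")
  as_tibble(out)
}

#' @rdname tidy.perm_ttest
#' @method glance perm_ttest
#' @export
glance.perm_ttest <- function(x, ...) {
  tibble(n_proteins = nrow(x),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$log2fc > 0),
         n_down = sum(x$significant & x$log2fc < 0),
         s0 = attr(x, "s0"),
         fdr_threshold = attr(x, "fdr_threshold"),
         n_permutations_used = attr(x, "n_permutations_used"),
         exhaustive = attr(x, "exhaustive"))
}

#' Tidy NE oscillation metrics
#'
#' @param x An `ne_metrics` row.
#' @param ... Unused.
#' @return `glance()`: the one-row metric record as a plain tibble.
#' @method glance ne_metrics
#' @export
glance.ne_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ne_metrics")
  as_tibble(out)
}
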