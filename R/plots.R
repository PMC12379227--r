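# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_hline geom_vline scale_y_log10 labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' @param object A `somno_psd` tibble.
#' @param log_power Log-scale the power axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot somno_psd
#' @export
autoplot.somno_psd <- function(object, log_power = TRUE, ...) {
  p <- ggplot(object, aes(x = .data$freq_hz, y = .data$power)) +
    geom_line() +
    labs(x = "Frequency (Hz)", y = expression(Power ~ (a.u.^2 / Hz))) +
    theme_minimal()
  if (log_power) p <- p + scale_y_log10()
  p
}

#' Plot a dF/F trace
#'
#' @param object A `dff_trace`.
#' @param peaks Optional peak table from [detect_ne_peaks()] to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dff_trace
#' @export
autoplot.dff_trace <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$dff_pct)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Time (s)", y = expression(Delta * "F/F (%)")) +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    at <- object$dff_pct[findInterval(peaks$time_s, object$time_s)]
    p <- p + geom_point(data = tibble(time_s = peaks$time_s, dff_pct = at),
                        colour = "red", size = 1)
  }
  p
}

#' Hypnogram state plot
#'
#' @param object A `hypnogram`.
#' @param ... Unused.
#' @return A ggplot (step trace over WAKE/NREM/REM).
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  d <- mutate(object,
              level = match(.data$state, c("REM", "NREM", "WAKE")))
  ggplot(d, aes(x = .data$t_start_s, y = .data$level)) +
    geom_step() +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = c("REM", "NREM", "WAKE"),
                                limits = c(0.5, 3.5)) +
    labs(x = "Time (s)", y = NULL) +
    theme_minimal()
}

#' Volcano plot of a differential result
#'
#' Points are the s0-moderated statistic's fold change versus q-value;
#' significant proteins are coloured by direction, with a |log2FC| = 1
#' guide (2-fold) drawn for orientation only — significance is governed by
#' the permutation FDR.
#'
#' @param object A `perm_ttest`.
#' @param fc_guide Absolute log2FC guide line (set `NULL` to omit).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perm_ttest
#' @export
autoplot.perm_ttest <- function(object, fc_guide = 1, ...) {
  d <- mutate(as_tibble(object),
              neglog_q = -log10(pmax(.data$q_value, 1e-16)),
              direction = dplyr::case_when(
                .data$significant & .data$log2fc > 0 ~ "up",
                .data$significant & .data$log2fc < 0 ~ "down",
                TRUE ~ "ns"))
  p <- ggplot(d, aes(x = .data$log2fc, y = .data$neglog_q,
                     colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "red", down = "blue", ns = "grey60")) +
    geom_hline(yintercept = -log10(attr(object, "fdr_threshold")),
               linetype = 2, colour = "grey40") +
    labs(x = expression(log[2] ~ "fold change"),
         y = expression(-log[10] ~ "q")) +
    theme_minimal()
  if (!is.null(fc_guide)) {
    p <- p + geom_vline(xintercept = c(-fc_guide, fc_guide),
                        linetype = 3, colour = "grey40")
  }
  p
}
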