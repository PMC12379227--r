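# Tidy containers: a hypnogram is a tibble (epoch, t_start_s, state) with an
# `epoch_length_s` attribute; a recording is a tibble (time_s, <channels>)
# with a `sample_rate_hz` attribute. Both survive round-trips through TSV.

#' Construct a hypnogram
#'
#' @param states Character vector of vigilance-state labels
#'   (`"WAKE"`, `"NREM"`, `"REM"`).
#' @param epoch_length_s Epoch length in seconds.
#' @param start_time_s Time of the first epoch's start, seconds.
#' @return A tibble of class `hypnogram` with columns `epoch`, `t_start_s`
#'   and `state`.
#' @export
hypnogram <- function(states, epoch_length_s = 5, start_time_s = 0) {
  states <- as.character(states)
  if (length(states) == 0) abort("A hypnogram needs at least one epoch.")
  bad <- setdiff(unique(states), .states)
  if (length(bad)) {
    abort(paste0("Unknown state label(s): ", paste(bad, collapse = ", ")))
  }
  if (epoch_length_s <= 0) abort("epoch_length_s must be positive.")
  out <- tibble(
    epoch = seq_along(states),
    t_start_s = start_time_s + (seq_along(states) - 1) * epoch_length_s,
    state = states
  )
  attr(out, "epoch_length_s") <- epoch_length_s
  class(out) <- c("hypnogram", class(out))
  out
}

epoch_length <- function(h) {
  el <- attr(h, "epoch_length_s")
  if (!is.null(el)) return(el)
  if (nrow(h) > 1) return(diff(h$t_start_s[1:2]))
  abort("Cannot infer epoch length from a single-epoch hypnogram.")
}

#' Construct a recording
#'
#' @param data Data frame of uniformly sampled channels; must contain a
#'   `time_s` column or one is synthesised from `sample_rate_hz`.
#' @param sample_rate_hz Sampling rate in Hz (shared by all channels).
#' @return A tibble of class `recording`.
#' @export
recording <- function(data, sample_rate_hz) {
  if (sample_rate_hz <= 0) abort("sample_rate_hz must be positive.")
  data <- as_tibble(data)
  if (!"time_s" %in% names(data)) {
    data <- dplyr::bind_cols(
      tibble(time_s = (seq_len(nrow(data)) - 1) / sample_rate_hz), data)
  }
  if (anyNA(data)) abort("Recording channels must not contain NA.")
  attr(data, "sample_rate_hz") <- sample_rate_hz
  class(data) <- c("recording", class(data))
  data
}

sample_rate <- function(rec) {
  fs <- attr(rec, "sample_rate_hz")
  if (!is.null(fs)) return(fs)
  1 / median(diff(rec$time_s))
}

require_channels <- function(rec, channels) {
  missing <- setdiff(channels, names(rec))
  if (length(missing)) {
    abort(paste0("Recording is missing channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(rec)
}

#' Read / write package TSV files
#'
#' TSV writers prepend `#`-prefixed provenance lines (package version, seed,
#' parameter hash) so every artefact records how it was produced; the reader
#' skips them.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @param meta Named list written as `# key: value` header lines.
#' @return `read_somno_tsv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_somno_tsv <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("somnoflow ", packageVersion("somnoflow"))),
            meta)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, function(v) paste(format(v), collapse = " "),
                        character(1)))
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_somno_tsv
#' @export
read_somno_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Read a hypnogram from TSV
#'
#' Expects columns `epoch_index`/`epoch`, `t_start_s` and `label`/`state`,
#' the layout written by [write_hypnogram_tsv()]. Externally scored
#' hypnograms in this layout are ingested verbatim.
#'
#' @param path TSV file path.
#' @return A `hypnogram` tibble.
#' @export
read_hypnogram_tsv <- function(path) {
  d <- read_somno_tsv(path)
  nm <- names(d)
  state_col <- intersect(c("label", "state"), nm)[1]
  if (is.na(state_col) || !"t_start_s" %in% nm) {
    abort("Hypnogram TSV needs columns t_start_s and label/state.")
  }
  el <- if (nrow(d) > 1) diff(d$t_start_s[1:2]) else 1
  hypnogram(d[[state_col]], epoch_length_s = el,
            start_time_s = d$t_start_s[1])
}

#' @rdname read_hypnogram_tsv
#' @param h Hypnogram to write.
#' @param meta Extra provenance entries.
#' @export
write_hypnogram_tsv <- function(h, path, meta = list()) {
  write_somno_tsv(
    tibble(epoch_index = h$epoch, t_start_s = h$t_start_s, label = h$state),
    path, c(list(epoch_length_s = epoch_length(h)), meta))
}

#' Read a recording from TSV
#'
#' @param path TSV with a `time_s` column plus channel columns.
#' @param sample_rate_hz Optional; inferred from `time_s` when omitted.
#' @return A `recording` tibble.
#' @export
read_recording_tsv <- function(path, sample_rate_hz = NULL) {
  d <- read_somno_tsv(path)
  if (!"time_s" %in% names(d)) abort("Recording TSV needs a time_s column.")
  fs <- sample_rate_hz %||% (1 / median(diff(d$time_s)))
  recording(d, fs)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("Package 'fgsea' is required to read GMT files.")
  }
  fgsea::gmtPathways(path)
}
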