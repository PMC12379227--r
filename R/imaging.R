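# Histology quantification: size-binned particle analysis of binarized
# microglia images and the AQP4 vascular polarization index.

#' Label connected components of a binary image
#'
#' Foreground pixels (value > 0) are grouped into connected components
#' (8-connectivity by default, matching common particle-analysis tools;
#' 4-connectivity available) via the pixel adjacency graph.
#'
#' @param image Numeric/logical matrix; > 0 is foreground.
#' @param connectivity 8 or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(image, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) abort("connectivity must be 4 or 8.")
  img <- matrix(as.numeric(image) > 0, nrow(image), ncol(image))
  lab <- matrix(0L, nrow(img), ncol(img))
  fg <- which(img)
  if (length(fg) == 0) return(lab)
  nr <- nrow(img)
  nc <- ncol(img)
  ri <- ((fg - 1) %% nr) + 1
  ci <- ((fg - 1) %/% nr) + 1
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  edges <- purrr::map_dfr(offs, function(o) {
    rr <- ri + o[1]; cc <- ci + o[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    to <- (cc[ok] - 1) * nr + rr[ok]
    ok2 <- img[to]
    tibble(from = fg[ok][ok2], to = to[ok2])
  })
  gr <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = as.character(fg)))
  comp <- igraph::components(gr)$membership
  lab[as.integer(names(comp))] <- as.integer(comp)
  lab
}

#' Size-binned particle analysis
#'
#' Labels connected components and bins their physical areas: components of
#' 30-90 um^2 (closed interval) count as microglial cells, 5-30 um^2
#' (half-open `[5, 30)`) as microglial ramifications, components below
#' 5 um^2 are excluded from quantification, and components above 90 um^2
#' are tallied separately. Densities are per mm^2 of image area.
#'
#' @param image Binary matrix (> 0 = foreground), e.g. from [binarize()]
#'   or [sim_particle_image()].
#' @param pixel_size_um Pixel edge length in micrometres (required).
#' @param bins Named numeric vector `c(min = 5, cell_lo = 30,
#'   cell_hi = 90)` of bin edges in um^2.
#' @param connectivity 8 (default) or 4.
#' @return A one-row tibble of class `particle_summary`: `n_cells`,
#'   `n_ramifications`, `n_excluded`, `n_oversize`, `cells_per_mm2`,
#'   `ramifications_per_cell` (`NA` when there are no cells). Per-particle
#'   areas are in `attr(, "particles")`.
#' @export
particle_analysis <- function(image, pixel_size_um,
                              bins = c(min = 5, cell_lo = 30, cell_hi = 90),
                              connectivity = 8) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um is required and must be positive.")
  }
  lab <- label_components(image, connectivity)
  areas_px <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  area_um2 <- areas_px * pixel_size_um^2
  bin <- ifelse(area_um2 < bins[["min"]], "excluded",
         ifelse(area_um2 < bins[["cell_lo"]], "ramification",
         ifelse(area_um2 <= bins[["cell_hi"]], "cell", "oversize")))
  n_cells <- sum(bin == "cell")
  n_ram <- sum(bin == "ramification")
  image_mm2 <- nrow(image) * ncol(image) * pixel_size_um^2 / 1e6
  out <- tibble(
    n_cells = n_cells,
    n_ramifications = n_ram,
    n_excluded = sum(bin == "excluded"),
    n_oversize = sum(bin == "oversize"),
    cells_per_mm2 = n_cells / image_mm2,
    ramifications_per_cell = if (n_cells > 0) n_ram / n_cells else NA_real_
  )
  class(out) <- c("particle_summary", class(out))
  attr(out, "particles") <- tibble(label = seq_along(area_um2),
                                   area_um2 = area_um2, bin = bin)
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Read a grayscale image from TIFF or PNG
#'
#' Returns the image as a plain numeric matrix (multichannel images are
#' averaged to grayscale), suitable for [binarize()] and
#' [particle_analysis()].
#'
#' @param path Image file path (`.tif`, `.tiff` or `.png`).
#' @return Numeric matrix of intensities in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Package 'tiff' is required to read TIFF images.")
    }
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Package 'png' is required to read PNG images.")
    }
    png::readPNG(path)
  } else {
    abort(paste0("Unsupported image format: .", ext))
  }
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img
}

#' Binarize a grayscale image
#'
#' Fixed-threshold binarization (`image > threshold`); with
#' `threshold = "otsu"` the Otsu threshold is computed via EBImage.
#'
#' @param image Numeric matrix with intensities in any range (Otsu expects
#'   \[0, 1\]).
#' @param threshold Numeric cutoff or `"otsu"`.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(image, threshold) {
  if (identical(threshold, "otsu")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("Package 'EBImage' is required for Otsu thresholding.")
    }
    threshold <- EBImage::otsu(EBImage::Image(image))
  }
  matrix(as.integer(image > threshold), nrow(image), ncol(image))
}

#' AQP4 vascular polarization index
#'
#' Per vessel line profile: the corrected peak is the maximum intensity
#' minus the perivascular background, taken as the mean of the (linearly
#' interpolated) intensities exactly `background_offset_um` on either side
#' of the peak — one-sided when the profile only extends that far on one
#' side (with `background = "band"`, the mean over all samples at least
#' that far from the peak is used instead). The per-image index is the mean
#' over its vessels, and the normalized index expresses each image relative
#' to the cohort maximum, so exactly one image scores 1.
#'
#' @param profiles Long tibble with columns `vessel`, `position_um`,
#'   `intensity` and optionally `image` (defaults to a single image).
#' @param background_offset_um Background distance from the peak (5 um).
#' @param background `"point"` (default) or `"band"`.
#' @return A tibble of class `aqp4_result`: `image`, `index`, `index_norm`,
#'   `n_vessels`; per-vessel values in `attr(, "vessels")`, skipped vessels
#'   in `attr(, "skipped")`.
#' @export
aqp4_polarization <- function(profiles, background_offset_um = 5,
                              background = c("point", "band")) {
  background <- match.arg(background)
  profiles <- as_tibble(profiles)
  stopifnot(all(c("vessel", "position_um", "intensity") %in% names(profiles)))
  if (!"image" %in% names(profiles)) profiles$image <- 1L

  per_vessel <- profiles |>
    dplyr::group_by(.data$image, .data$vessel) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$position_um)
      if (is.unsorted(d$position_um, strictly = TRUE)) {
        abort("Profile positions must be strictly increasing.")
      }
      pk <- which.max(d$intensity)
      p0 <- d$position_um[pk]
      lo <- p0 - background_offset_um
      hi <- p0 + background_offset_um
      vals <- if (background == "point") {
        c(if (lo >= min(d$position_um))
            approx(d$position_um, d$intensity, xout = lo)$y,
          if (hi <= max(d$position_um))
            approx(d$position_um, d$intensity, xout = hi)$y)
      } else {
        d$intensity[abs(d$position_um - p0) >= background_offset_um]
      }
      tibble(peak_position_um = p0,
             peak_intensity = d$intensity[pk],
             background_intensity = if (length(vals)) mean(vals) else NA_real_,
             corrected_peak = if (length(vals))
               d$intensity[pk] - mean(vals) else NA_real_)
    }) |>
    dplyr::ungroup()

  skipped <- per_vessel[is.na(per_vessel$corrected_peak), c("image", "vessel")]
  if (nrow(skipped)) {
    warn(paste0(nrow(skipped), " vessel profile(s) too short for the ",
                background_offset_um, " um background offset; skipped."))
  }
  ok <- per_vessel[!is.na(per_vessel$corrected_peak), ]
  per_image <- ok |>
    dplyr::group_by(.data$image) |>
    dplyr::summarise(index = mean(.data$corrected_peak),
                     n_vessels = dplyr::n(), .groups = "drop")
  empty <- setdiff(unique(per_vessel$image), per_image$image)
  if (length(empty)) {
    abort(paste0("Image(s) with no usable vessel profile: ",
                 paste(empty, collapse = ", ")))
  }
  per_image$index_norm <- per_image$index / max(per_image$index)
  class(per_image) <- c("aqp4_result", class(per_image))
  attr(per_image, "vessels") <- per_vessel
  attr(per_image, "skipped") <- skipped
  per_image
}
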