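# Synthetic histology fixtures: particle images and vessel line profiles.

#' Simulate a binary particle image with known component areas
#'
#' Places compact connected blobs with the requested areas (in square
#' micrometres, converted to whole pixels) at random positions such that no
#' two blobs touch, even diagonally — so connected-component areas equal the
#' requested areas up to pixel quantisation under either 4- or
#' 8-connectivity.
#'
#' @param particle_areas_um2 Target areas in square micrometres (may be
#'   empty, yielding an all-background image).
#' @param shape_px Image dimensions `c(rows, cols)`.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per particle before giving up.
#' @return A list of class `particle_image`: `image` (0/1 integer matrix),
#'   `pixel_size_um`, and `truth` (tibble `particle`, `area_um2`,
#'   `area_px`).
#' @examples
#' img <- sim_particle_image(c(50, 20, 3), seed = 1)
#' sum(img$image)
#' @export
sim_particle_image <- function(particle_areas_um2,
                               shape_px = c(128, 128),
                               pixel_size_um = 1,
                               seed = 1,
                               max_tries = 200) {
  if (length(particle_areas_um2) && any(particle_areas_um2 <= 0)) {
    abort("Particle areas must be positive.")
  }
  if (pixel_size_um <= 0) abort("pixel_size_um must be positive.")
  nr <- shape_px[1]; nc <- shape_px[2]
  img <- matrix(0L, nr, nc)
  areas_px <- as.integer(round(particle_areas_um2 / pixel_size_um^2))
  if (any(areas_px < 1 & length(areas_px) > 0)) {
    abort("A requested area is below one pixel at this pixel size.")
  }
  truth <- tibble(particle = seq_along(areas_px),
                  area_um2 = areas_px * pixel_size_um^2,
                  area_px = areas_px)
  if (length(areas_px) == 0) {
    return(structure(list(image = img, pixel_size_um = pixel_size_um,
                          truth = truth), class = "particle_image"))
  }
  with_seed_(seed, {
    # forbidden = foreground dilated by one pixel (8-neighbourhood), so
    # placed blobs never touch existing ones
    for (k in seq_along(areas_px)) {
      shape <- blob_offsets(areas_px[k])
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sample.int(nr, 1); c0 <- sample.int(nc, 1)
        rr <- r0 + shape[, 1]; cc <- c0 + shape[, 2]
        if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) next
        # check the blob plus its 1-pixel halo against existing foreground
        halo_r <- pmax(1, pmin(nr, rep(rr, 9) + rep(-1:1, each = 3 * nrow(shape))))
        halo_c <- pmax(1, pmin(nc, rep(cc, 9) + rep(rep(-1:1, each = nrow(shape)), 3)))
        if (any(img[cbind(halo_r, halo_c)] > 0)) next
        img[cbind(rr, cc)] <- 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        abort("Could not place all particles without contact; reduce count or enlarge the image.")
      }
    }
  })
  structure(list(image = img, pixel_size_um = pixel_size_um, truth = truth),
            class = "particle_image")
}

# Compact blob of n pixels: grow outward from the origin in a spiral-like
# order (sorted by distance), guaranteeing 4-connectivity.
blob_offsets <- function(n_px) {
  r <- ceiling(sqrt(n_px))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[order(g$dr^2 + g$dc^2, abs(g$dr), abs(g$dc)), ]
  as.matrix(g[seq_len(n_px), , drop = FALSE])
}

#' Simulate vessel line-intensity profiles with known polarization
#'
#' Each profile is a Gaussian bump (vessel-wall AQP4 signal) on a flat
#' background, sampled along a line ROI. The analytic corrected peak —
#' `peak_height - background_level` (the Gaussian is negligible 5 um away at
#' the default width) — is returned as ground truth.
#'
#' @param profiles Tibble or data frame with columns `peak_height`,
#'   `background_level` and `peak_position_um` (one row per vessel).
#' @param length_um Profile length in micrometres.
#' @param step_um Sampling step along the line.
#' @param sigma_um Gaussian SD of the vessel-wall bump.
#' @param noise_sd Additive intensity noise SD.
#' @param seed Integer seed.
#' @return A list of class `vessel_sim`: `profiles` (long tibble `vessel`,
#'   `position_um`, `intensity`) and `truth` (tibble `vessel`,
#'   `corrected_peak`).
#' @export
sim_vessel_profiles <- function(profiles,
                                length_um = 20,
                                step_um = 0.25,
                                sigma_um = 1,
                                noise_sd = 0,
                                seed = 1) {
  profiles <- as_tibble(profiles)
  stopifnot(all(c("peak_height", "background_level", "peak_position_um")
                %in% names(profiles)))
  if (any(profiles$peak_position_um < 0 |
          profiles$peak_position_um > length_um)) {
    abort("peak_position_um must lie within [0, length_um].")
  }
  x <- seq(0, length_um, by = step_um)
  long <- with_seed_(seed, {
    purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
      p <- profiles[i, ]
      y <- p$background_level +
        (p$peak_height - p$background_level) *
          exp(-(x - p$peak_position_um)^2 / (2 * sigma_um^2)) +
        noise_sd * rnorm(length(x))
      tibble(vessel = i, position_um = x, intensity = y)
    })
  })
  structure(
    list(profiles = long,
         truth = tibble(vessel = seq_len(nrow(profiles)),
                        corrected_peak = profiles$peak_height -
                          profiles$background_level)),
    class = "vessel_sim")
}
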