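#' Acquisition settings for a synthetic confocal field
#'
#' Describes the virtual microscope: lateral calibration, z sampling, frame
#' size, point-spread function width, and the camera noise model (Poisson
#' shot noise at \code{photon_scale} photons per intensity unit, followed by
#' additive Gaussian read noise).
#'
#' The default lateral calibration of 0.1038 um/px corresponds to a 60 px
#' line spanning 6.23 um; the default of 30 z slices matches a conventional
#' spinning-disk z-stack of a yeast field. The z step is instrument-specific
#' and defaults to 0.3 um.
#'
#' @param pixel_size_xy lateral pixel size, um/pixel.
#' @param z_step axial step between slices, um.
#' @param n_slices number of z slices (>= 1).
#' @param frame_shape integer c(nx, ny) frame size in pixels.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations, um.
#'   Set to 0 to disable blurring.
#' @param noise_read_sd additive Gaussian read noise sd, intensity units.
#'   Set to 0 to disable.
#' @param photon_scale photons per intensity unit for shot noise. Set to 0
#'   (or \code{Inf}) to disable shot noise.
#' @return an object of class \code{acquisition_spec}.
#' @examples
#' spec <- acquisition_spec(frame_shape = c(128, 128), n_slices = 5)
#' spec$pixel_size_xy
#' @export
acquisition_spec <- function(pixel_size_xy = 0.1038,
                             z_step = 0.3,
                             n_slices = 30L,
                             frame_shape = c(512L, 512L),
                             psf_sigma_xy = 0.15,
                             psf_sigma_z = 0.35,
                             noise_read_sd = 0.02,
                             photon_scale = 50) {
  stopifnot(pixel_size_xy > 0, z_step > 0, n_slices >= 1,
            length(frame_shape) == 2, all(frame_shape >= 8),
            psf_sigma_xy >= 0, psf_sigma_z >= 0,
            noise_read_sd >= 0, photon_scale >= 0)
  structure(list(
    pixel_size_xy = pixel_size_xy,
    z_step = z_step,
    n_slices = as.integer(n_slices),
    frame_shape = as.integer(frame_shape),
    psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z,
    noise_read_sd = noise_read_sd,
    photon_scale = photon_scale
  ), class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf(
    "acquisition_spec: %d x %d px, %d slices, %.4f um/px, dz %.2f um\n",
    x$frame_shape[1], x$frame_shape[2], x$n_slices, x$pixel_size_xy, x$z_step))
  cat(sprintf("  PSF sigma xy/z: %.3f/%.3f um; photon scale %.3g; read sd %.3g\n",
              x$psf_sigma_xy, x$psf_sigma_z, x$photon_scale, x$noise_read_sd))
  invisible(x)
}

#' Physical frame extent in micrometres
#' @param spec an \code{acquisition_spec}.
#' @return numeric c(x_um, y_um, z_um).
#' @keywords internal
frame_extent_um <- function(spec) {
  c(spec$frame_shape[1] * spec$pixel_size_xy,
    spec$frame_shape[2] * spec$pixel_size_xy,
    spec$n_slices * spec$z_step)
}

LOCALIZATION_CLASSES <- c("cytoplasmic", "nuclear", "punctate",
                          "mitochondrial", "periphery")

#' Specification of one synthetic cell
#'
#' A yeast-like cell is a sphere with a GFP distribution drawn from one of
#' five localization classes: uniform cytoplasmic signal, nuclear enrichment,
#' discrete cytoplasmic puncta, a mitochondrial tubule network, or a
#' cell-periphery shell. \code{intensity_scale} multiplies every GFP level of
#' the cell, so per-cell mean intensity scales linearly with it.
#'
#' @param center numeric c(x, y, z) position of the cell centre, um.
#' @param diameter cell diameter, um (> 0).
#' @param localization_class one of \code{"cytoplasmic"}, \code{"nuclear"},
#'   \code{"punctate"}, \code{"mitochondrial"}, \code{"periphery"}.
#' @param intensity_scale nonnegative multiplier of the GFP levels.
#' @param n_puncta number of Gaussian foci (punctate class only).
#' @param tubule_n number of mitochondrial tubules (ignored when
#'   \code{mito_volume_um3} is set).
#' @param tubule_length mean tubule length, um.
#' @param tubule_radius tubule radius, um.
#' @param mito_volume_um3 optional target mitochondrial volume, um^3:
#'   tubules are added segment by segment until the rasterized network
#'   reaches this voxel volume, so the injected volume factor is realized
#'   in the ground truth irrespective of tubule overlap.
#' @param nucleus_diameter_fraction nucleus diameter as a fraction of the
#'   cell diameter, in (0, 1).
#' @return an object of class \code{cell_spec}.
#' @export
cell_spec <- function(center, diameter,
                      localization_class = "cytoplasmic",
                      intensity_scale = 1,
                      n_puncta = 8L,
                      tubule_n = 4L,
                      tubule_length = 2.5,
                      tubule_radius = 0.25,
                      mito_volume_um3 = NULL,
                      nucleus_diameter_fraction = 0.35) {
  localization_class <- match.arg(localization_class, LOCALIZATION_CLASSES)
  stopifnot(length(center) == 3, diameter > 0, intensity_scale >= 0,
            n_puncta >= 0, tubule_n >= 0, tubule_length > 0,
            tubule_radius > 0,
            is.null(mito_volume_um3) || mito_volume_um3 > 0,
            nucleus_diameter_fraction > 0, nucleus_diameter_fraction < 1)
  structure(list(
    center = as.numeric(center),
    diameter = diameter,
    localization_class = localization_class,
    intensity_scale = intensity_scale,
    n_puncta = as.integer(n_puncta),
    tubule_n = as.integer(tubule_n),
    tubule_length = tubule_length,
    tubule_radius = tubule_radius,
    mito_volume_um3 = mito_volume_um3,
    nucleus_diameter_fraction = nucleus_diameter_fraction
  ), class = "cell_spec")
}

#' Place cells on a jittered grid
#'
#' Deterministic (given the seed) non-overlapping layout: cells are placed on
#' a regular grid with uniform jitter, at the mid-plane of the stack, with
#' diameters drawn uniformly from \code{diameter_range}. Errors if the frame
#' cannot hold \code{n} cells at the requested pitch.
#'
#' @param n number of cells.
#' @param spec an \code{acquisition_spec}.
#' @param diameter_range numeric c(lo, hi) cell diameter, um.
#' @param class localization class for every cell, or a vector recycled over
#'   cells.
#' @param intensity_scale intensity multiplier, recycled over cells.
#' @param seed integer seed.
#' @param margin_um extra clearance between grid sites, um.
#' @param mito_volume_um3 optional per-cell target mitochondrial volume,
#'   recycled over cells.
#' @param ... further arguments passed to \code{\link{cell_spec}}.
#' @return a list of \code{cell_spec} objects.
#' @export
layout_cells <- function(n, spec, diameter_range = c(3.6, 4.4),
                         class = "cytoplasmic", intensity_scale = 1,
                         seed = 1L, margin_um = 0.6,
                         mito_volume_um3 = NULL, ...) {
  stopifnot(n >= 1)
  ext <- frame_extent_um(spec)
  pitch <- max(diameter_range) + margin_um
  ncol_grid <- floor(ext[1] / pitch)
  nrow_grid <- floor(ext[2] / pitch)
  if (ncol_grid * nrow_grid < n) {
    stop(sprintf(
      "frame too small: %d x %d grid sites at pitch %.2f um < %d cells",
      ncol_grid, nrow_grid, pitch, n))
  }
  class <- rep_len(class, n)
  intensity_scale <- rep_len(intensity_scale, n)
  if (!is.null(mito_volume_um3)) mito_volume_um3 <- rep_len(mito_volume_um3, n)
  with_seed(seed, {
    sites <- expand.grid(i = seq_len(ncol_grid), j = seq_len(nrow_grid))
    sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
    jmax <- margin_um / 2
    lapply(seq_len(n), function(k) {
      d <- stats::runif(1, diameter_range[1], diameter_range[2])
      cx <- (sites$i[k] - 0.5) * pitch + stats::runif(1, -jmax, jmax)
      cy <- (sites$j[k] - 0.5) * pitch + stats::runif(1, -jmax, jmax)
      cz <- ext[3] / 2
      cell_spec(center = c(cx, cy, cz), diameter = d,
                localization_class = class[k],
                intensity_scale = intensity_scale[k],
                mito_volume_um3 = mito_volume_um3[k], ...)
    })
  })
}
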