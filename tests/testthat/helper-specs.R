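# Shared fixture builders: tiny acquisition settings with and without
# optics/noise, and a convenience for cropping one cell's sub-volume.

tiny_spec <- function(nx = 64, nz = 30, ...) {
  acquisition_spec(frame_shape = c(nx, nx), n_slices = nz, ...)
}

clean_spec <- function(nx = 64, nz = 30, ...) {
  acquisition_spec(frame_shape = c(nx, nx), n_slices = nz,
                   psf_sigma_xy = 0, psf_sigma_z = 0,
                   noise_read_sd = 0, photon_scale = 0, ...)
}

# sub-volume of `vol` over the bounding box of cell `i` in `labels`
crop_cell <- function(vol, labels, i) {
  ijk <- which(labels == i, arr.ind = TRUE)
  rng <- apply(ijk, 2, range)
  vol[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3],
      drop = FALSE]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
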