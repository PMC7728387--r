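# Low-level rasterization and optics helpers for the field simulator.
# Volumes are numeric arrays with dim = c(nx, ny, nz); voxel (i, j, k)
# (1-based) has its centre at ((i - 0.5) px, (j - 0.5) px, (k - 0.5) dz) um.

voxel_centers <- function(idx, step) (idx - 0.5) * step

# Index range of voxels whose centres can fall within `radius` of `center_um`
# along one axis of `n` voxels with spacing `step`.
axis_range <- function(center_um, radius, step, n) {
  lo <- max(1L, floor((center_um - radius) / step - 1) + 1L)
  hi <- min(n, ceiling((center_um + radius) / step + 1))
  if (lo > hi) integer(0) else lo:hi
}

# Shift an array along one dimension, filling with zeros.
shift_zero <- function(a, s, dim) {
  d <- dim(a)
  n <- d[dim]
  if (s == 0) return(a)
  out <- array(0, d)
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  if (dim == 1) out[dst, , ] <- a[src, , , drop = FALSE]
  else if (dim == 2) out[, dst, ] <- a[, src, , drop = FALSE]
  else out[, , dst] <- a[, , src, drop = FALSE]
  out
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k / sum(k)
}

#' Separable anisotropic Gaussian blur of a 3D volume
#'
#' Convolves with a normalized, zero-padded Gaussian along each axis; total
#' intensity is conserved except for mass truncated at the frame boundary.
#'
#' @param a numeric array, dim c(nx, ny, nz).
#' @param sigma_vox numeric length-3 sigma in voxels per axis.
#' @return blurred array of the same dim.
#' @keywords internal
gauss_blur3d <- function(a, sigma_vox) {
  for (d in 1:3) {
    k <- gauss_kernel(sigma_vox[d])
    if (length(k) == 1) next
    half <- (length(k) - 1) / 2
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      out <- out + k[j] * shift_zero(a, j - 1 - half, d)
    }
    a <- out
  }
  a
}

# Rasterize a sphere; returns list(ix, iy, iz ranges and logical bbox mask).
sphere_bbox <- function(spec, center, radius) {
  ix <- axis_range(center[1], radius, spec$pixel_size_xy, spec$frame_shape[1])
  iy <- axis_range(center[2], radius, spec$pixel_size_xy, spec$frame_shape[2])
  iz <- axis_range(center[3], radius, spec$z_step, spec$n_slices)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(list(ix = ix, iy = iy, iz = iz, mask = NULL, r2 = NULL))
  }
  dx2 <- (voxel_centers(ix, spec$pixel_size_xy) - center[1])^2
  dy2 <- (voxel_centers(iy, spec$pixel_size_xy) - center[2])^2
  dz2 <- (voxel_centers(iz, spec$z_step) - center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  list(ix = ix, iy = iy, iz = iz, mask = r2 <= radius^2, r2 = r2)
}

# Assign `value` into volume `vol` where bbox mask is TRUE (by reference
# semantics emulated via return).
paint <- function(vol, bb, where, value) {
  sub <- vol[bb$ix, bb$iy, bb$iz, drop = FALSE]
  sub[where] <- value
  vol[bb$ix, bb$iy, bb$iz] <- sub
  vol
}

# Sub-grid coverage of a flat-capped cylinder over given voxel index
# ranges. Returns a numeric sub-array in [0, 1]: the fraction of sub-voxel
# sample points (5 per axis, 125 per voxel) that lie within radius r of the
# axis AND within the axial extent of segment a-b (flat end caps, so the
# voxel count tracks the analytic pi r^2 L volume).
segment_coverage <- function(spec, a, b, r, ix, iy, iz, n_xy = 5L, n_z = 5L) {
  step <- c(spec$pixel_size_xy, spec$pixel_size_xy, spec$z_step)
  sub_offs <- function(n) (seq_len(n) - (n + 1) / 2) / n
  offs_xy <- sub_offs(n_xy)
  offs_z <- sub_offs(n_z)
  cov <- array(0, c(length(ix), length(iy), length(iz)))
  xs0 <- voxel_centers(ix, step[1])
  ys0 <- voxel_centers(iy, step[2])
  zs0 <- voxel_centers(iz, step[3])
  ab <- b - a
  ab2 <- sum(ab^2)
  if (ab2 == 0) ab2 <- .Machine$double.eps
  for (ox in offs_xy) for (oy in offs_xy) for (oz in offs_z) {
    xs <- xs0 + ox * step[1]
    ys <- ys0 + oy * step[2]
    zs <- zs0 + oz * step[3]
    px <- array(xs, dim(cov))
    py <- aperm(array(ys, dim(cov)[c(2, 1, 3)]), c(2, 1, 3))
    pz <- aperm(array(zs, dim(cov)[c(3, 2, 1)]), c(3, 2, 1))
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / ab2
    tc <- pmin(pmax(t, 0), 1)
    d2 <- (px - (a[1] + tc * ab[1]))^2 +
          (py - (a[2] + tc * ab[2]))^2 +
          (pz - (a[3] + tc * ab[3]))^2
    cov <- cov + (d2 <= r^2 & t >= 0 & t <= 1)
  }
  cov / (n_xy * n_xy * n_z)
}

# Convert a fractional-coverage array into a binary mask that preserves
# volume: per xy column, include round(sum of coverages) voxels, choosing
# the most-covered slices (ties to the lower z index). Column-wise rounding
# errors carry varied fractional parts and average out, so the voxel count
# tracks the covered volume even when structures are thinner than the
# axial step.
mask_from_coverage <- function(cov) {
  d <- dim(cov)
  out <- array(FALSE, d)
  tot <- rowSums(cov, dims = 2)
  hit <- which(tot > 0, arr.ind = TRUE)
  for (h in seq_len(nrow(hit))) {
    i <- hit[h, 1]
    j <- hit[h, 2]
    n <- round(tot[i, j])
    if (n < 1) next
    cz <- cov[i, j, ]
    ord <- order(-cz, seq_len(d[3]))
    out[i, j, ord[seq_len(min(n, sum(cz > 0)))]] <- TRUE
  }
  out
}

#' Voxelize a capped cylinder (volume-preserving)
#'
#' Rasterizes the flat-capped cylinder of radius \code{r} around the
#' segment \code{a}-\code{b}: per-voxel coverage is estimated on a 5x5x5
#' sub-grid and converted to a binary mask column by column so that the
#' voxel count times the voxel volume tracks the analytic
#' \eqn{\pi r^2 L}, even when the radius is comparable to the axial step.
#'
#' @param spec an \code{acquisition_spec} (calibration and frame size).
#' @param a,b segment endpoints, um.
#' @param r cylinder radius, um.
#' @return logical array dim c(nx, ny, nz).
#' @export
cylinder_mask <- function(spec, a, b, r) {
  vol <- array(FALSE, c(spec$frame_shape, spec$n_slices))
  pad <- r + max(spec$pixel_size_xy, spec$z_step)
  lo <- pmin(a, b) - pad
  hi <- pmax(a, b) + pad
  ix <- axis_range((lo[1] + hi[1]) / 2, (hi[1] - lo[1]) / 2,
                   spec$pixel_size_xy, spec$frame_shape[1])
  iy <- axis_range((lo[2] + hi[2]) / 2, (hi[2] - lo[2]) / 2,
                   spec$pixel_size_xy, spec$frame_shape[2])
  iz <- axis_range((lo[3] + hi[3]) / 2, (hi[3] - lo[3]) / 2,
                   spec$z_step, spec$n_slices)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  cov <- segment_coverage(spec, a, b, r, ix, iy, iz)
  vol[ix, iy, iz] <- mask_from_coverage(cov)
  vol
}

# One random-walk tubule polyline for a mitochondrial cell: a persistent
# random walk of total length ~ tubule_length, confined to 0.8 x cell
# radius. Tubules run mostly in-plane. The caller's RNG state drives all
# draws.
tubule_polyline <- function(cell, step_um = 0.5, persistence = 0.75) {
  r_conf <- 0.4 * cell$diameter
  n_steps <- max(1L, round(cell$tubule_length / step_um))
  p <- cell$center + stats::runif(3, -0.5, 0.5) * r_conf
  dir <- stats::rnorm(3)
  dir[3] <- dir[3] * 0.4
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- p
  for (s in seq_len(n_steps)) {
    turn <- stats::rnorm(3)
    turn[3] <- turn[3] * 0.4
    dir <- persistence * dir + (1 - persistence) * turn
    dir <- dir / sqrt(sum(dir^2))
    q <- p + dir * step_um
    # reflect back towards the centre when leaving the confinement sphere
    if (sqrt(sum((q - cell$center)^2)) > r_conf) {
      dir <- (cell$center - p)
      dir <- dir / sqrt(sum(dir^2))
      q <- p + dir * step_um
    }
    pts[s + 1, ] <- q
    p <- q
  }
  pts
}

# Apply the camera model in place: Poisson shot noise then Gaussian read
# noise, clamped at zero. Caller seeds the RNG.
apply_noise <- function(vol, spec) {
  if (spec$photon_scale > 0 && is.finite(spec$photon_scale)) {
    vol[] <- stats::rpois(length(vol), spec$photon_scale * pmax(vol, 0)) /
      spec$photon_scale
  }
  if (spec$noise_read_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), 0, spec$noise_read_sd)
  }
  pmax(vol, 0)
}
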