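# GFP levels per localization class, in camera intensity units before the
# per-cell intensity_scale multiplier. Chosen so that the per-cell mean
# scales linearly with intensity_scale and so that, without noise, nuclear
# cells have a nucleus/cytoplasm mean ratio well above 2 while cytoplasmic
# cells sit at 1.
GFP_LEVELS <- list(
  cytoplasmic   = list(cyto = 1.0),
  nuclear       = list(cyto = 0.6, nucleus = 2.4),
  punctate      = list(cyto = 0.5, punctum_amp = 6, punctum_sigma = 0.15),
  mitochondrial = list(cyto = 0.3, mito = 3.0),
  periphery     = list(cyto = 0.5, shell = 2.5, shell_thickness = 0.25)
)

BRIGHTFIELD_BG <- 1.0
BRIGHTFIELD_INTERIOR <- 0.55
BRIGHTFIELD_RIM <- 1.8
BRIGHTFIELD_RIM_HALFWIDTH <- 0.15  # um on either side of the cell boundary
DAPI_LEVEL <- 2.0

#' Render one synthetic multi-channel field with ground truth
#'
#' Rasterizes a set of yeast-like cells into a calibrated z-stack: the GFP
#' channel renders each cell's localization class (uniform cytoplasm,
#' nuclear sphere, Gaussian puncta, mitochondrial tubule network, or
#' peripheral shell), is convolved with the anisotropic Gaussian PSF and
#' passed through the Poisson + Gaussian camera model; the brightfield
#' channel renders each cell as a dark interior with a bright rim; the DAPI
#' channel renders the nuclei. The returned ground truth carries voxel label
#' volumes for cells, nuclei and mitochondria plus a per-cell table of true
#' class, true mean GFP (noise-free, post-PSF), and true volumes.
#'
#' @param spec an \code{\link{acquisition_spec}}.
#' @param cells list of \code{\link{cell_spec}} objects.
#' @param seed integer seed; identical (spec, cells, seed) give bit-identical
#'   output.
#' @param channels character subset of c("gfp", "brightfield", "dapi").
#' @param genotype,gene,field_index metadata carried on the field.
#' @param max_overlap maximum tolerated pairwise overlap, as a fraction of
#'   the sum of two cells' radii (0 = strictly non-overlapping).
#' @return a list with elements \code{field} (class \code{field_image}:
#'   channels, spec, metadata) and \code{truth} (class \code{ground_truth}:
#'   label volumes and per-cell table).
#' @examples
#' spec <- acquisition_spec(frame_shape = c(64, 64), n_slices = 5)
#' cells <- list(cell_spec(c(3.3, 3.3, 0.75), 4))
#' fg <- generate_field(spec, cells, seed = 1)
#' fg$truth$cells$true_cell_volume
#' @export
generate_field <- function(spec, cells, seed,
                           channels = c("gfp", "brightfield", "dapi"),
                           genotype = "WT", gene = NA_character_,
                           field_index = 1L, max_overlap = 0) {
  stopifnot(inherits(spec, "acquisition_spec"), length(cells) >= 1)
  channels <- match.arg(channels, several.ok = TRUE)
  ext <- frame_extent_um(spec)
  for (cl in cells) {
    r <- cl$diameter / 2
    if (cl$center[1] - r < 0 || cl$center[1] + r > ext[1] ||
        cl$center[2] - r < 0 || cl$center[2] + r > ext[2]) {
      stop(sprintf("frame too small: cell at (%.1f, %.1f) um, radius %.2f um, exceeds the %g x %g um frame",
                   cl$center[1], cl$center[2], r, ext[1], ext[2]))
    }
  }
  if (length(cells) > 1) {
    ctr <- t(vapply(cells, function(c) c$center, numeric(3)))
    rad <- vapply(cells, function(c) c$diameter / 2, numeric(1))
    d <- as.matrix(stats::dist(ctr))
    lim <- outer(rad, rad, "+") * (1 - max_overlap)
    diag(d) <- Inf
    if (any(d < lim)) {
      stop("overlapping-cell budget exceeded: cell placement violates the maximum overlap fraction")
    }
  }

  dims <- c(spec$frame_shape, spec$n_slices)
  voxvol <- spec$pixel_size_xy^2 * spec$z_step
  cell_lab <- array(0L, dims)
  nuc_lab <- array(0L, dims)
  mito_lab <- array(0L, dims)
  gfp <- array(0, dims)

  truth_rows <- vector("list", length(cells))
  with_seed(seed, {
    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      lv <- GFP_LEVELS[[cl$localization_class]]
      r <- cl$diameter / 2
      bb <- sphere_bbox(spec, cl$center, r)
      if (is.null(bb$mask)) stop("cell lies entirely outside the stack")
      cell_lab <- paint(cell_lab, bb, bb$mask, i)
      gfp <- paint(gfp, bb, bb$mask, lv$cyto * cl$intensity_scale)

      # nucleus (rendered for every class; only the nuclear class lights it
      # up in GFP, DAPI lights it up for all)
      rn <- cl$nucleus_diameter_fraction * r
      nb <- sphere_bbox(spec, cl$center, rn)
      if (!is.null(nb$mask)) nuc_lab <- paint(nuc_lab, nb, nb$mask, i)

      if (cl$localization_class == "nuclear" && !is.null(nb$mask)) {
        # dome-shaped nucleoplasmic signal (brightest at the centre), as
        # nuclear GFP appears in projected stacks; mean level ~ lv$nucleus
        q <- nb$r2 / rn^2
        dome <- lv$nucleus * cl$intensity_scale * (0.7 + 0.75 * (1 - q))
        sub <- gfp[nb$ix, nb$iy, nb$iz, drop = FALSE]
        sub[nb$mask] <- dome[nb$mask]
        gfp[nb$ix, nb$iy, nb$iz] <- sub
      } else if (cl$localization_class == "periphery") {
        shell <- bb$mask & bb$r2 > (r - lv$shell_thickness)^2
        gfp <- paint(gfp, bb, shell, lv$shell * cl$intensity_scale)
      } else if (cl$localization_class == "punctate" && cl$n_puncta > 0) {
        s2 <- lv$punctum_sigma^2
        xs <- voxel_centers(bb$ix, spec$pixel_size_xy)
        ys <- voxel_centers(bb$iy, spec$pixel_size_xy)
        zs <- voxel_centers(bb$iz, spec$z_step)
        add <- array(0, dim(bb$mask))
        for (p in seq_len(cl$n_puncta)) {
          u <- stats::rnorm(3)
          # puncta are cytoplasmic: placed outside the nuclear sphere,
          # inside ~0.75 of the cell radius
          rad <- stats::runif(1, max(0.45, cl$nucleus_diameter_fraction + 0.1),
                              0.75) * r
          u <- u / sqrt(sum(u^2)) * rad
          pc <- cl$center + u
          d2 <- outer(outer((xs - pc[1])^2, (ys - pc[2])^2, "+"),
                      (zs - pc[3])^2, "+")
          add <- add + lv$punctum_amp * cl$intensity_scale * exp(-d2 / (2 * s2))
        }
        sub <- gfp[bb$ix, bb$iy, bb$iz, drop = FALSE]
        sub[bb$mask] <- sub[bb$mask] + add[bb$mask]
        gfp[bb$ix, bb$iy, bb$iz] <- sub
      } else if (cl$localization_class == "mitochondrial" &&
                 (cl$tubule_n > 0 || !is.null(cl$mito_volume_um3))) {
        covmax <- array(0, dim(bb$mask))
        pad <- cl$tubule_radius + max(spec$pixel_size_xy, spec$z_step)
        # mitochondria stay out of the nucleus: coverage inside the nuclear
        # sphere is discarded before the volume budget is counted
        nuc_excl <- bb$r2 <= (cl$nucleus_diameter_fraction * r)^2
        target_vox <- if (is.null(cl$mito_volume_um3)) Inf else
          cl$mito_volume_um3 / voxvol
        cov_total <- 0
        n_tub <- 0L
        repeat {
          if (is.finite(target_vox)) {
            if (cov_total >= target_vox || n_tub >= 200L) break
          } else if (n_tub >= cl$tubule_n) break
          n_tub <- n_tub + 1L
          pl <- tubule_polyline(cl)
          for (s in seq_len(nrow(pl) - 1)) {
            if (is.finite(target_vox) && cov_total >= target_vox) break
            a <- pl[s, ]; b <- pl[s + 1, ]
            # restrict to the segment's own bounding box within the cell's
            sx <- intersect(bb$ix, axis_range((a[1] + b[1]) / 2,
                    abs(a[1] - b[1]) / 2 + pad, spec$pixel_size_xy,
                    spec$frame_shape[1]))
            sy <- intersect(bb$iy, axis_range((a[2] + b[2]) / 2,
                    abs(a[2] - b[2]) / 2 + pad, spec$pixel_size_xy,
                    spec$frame_shape[2]))
            sz <- intersect(bb$iz, axis_range((a[3] + b[3]) / 2,
                    abs(a[3] - b[3]) / 2 + pad, spec$z_step, spec$n_slices))
            if (!length(sx) || !length(sy) || !length(sz)) next
            cov <- segment_coverage(spec, a, b, cl$tubule_radius, sx, sy, sz,
                                    n_xy = 3L)
            ii <- match(sx, bb$ix); jj <- match(sy, bb$iy); kk <- match(sz, bb$iz)
            cov[nuc_excl[ii, jj, kk]] <- 0
            old <- covmax[ii, jj, kk]
            new <- pmax(old, cov)
            cov_total <- cov_total + sum(new) - sum(old)
            covmax[ii, jj, kk] <- new
          }
        }
        mmask <- mask_from_coverage(covmax) & bb$mask
        mito_lab <- paint(mito_lab, bb, mmask, i)
        gfp <- paint(gfp, bb, mmask, lv$mito * cl$intensity_scale)
      }
    }

    # optics: anisotropic PSF on the noise-free GFP volume
    sig_vox <- c(spec$psf_sigma_xy / spec$pixel_size_xy,
                 spec$psf_sigma_xy / spec$pixel_size_xy,
                 spec$psf_sigma_z / spec$z_step)
    gfp_ideal <- if (any(sig_vox > 0)) gauss_blur3d(gfp, sig_vox) else gfp

    true_mean <- vapply(seq_along(cells), function(i) {
      v <- gfp_ideal[cell_lab == i]
      if (length(v)) mean(v) else 0
    }, numeric(1))

    out_channels <- list()
    if ("gfp" %in% channels) out_channels$gfp <- apply_noise(gfp_ideal, spec)
    if ("brightfield" %in% channels) {
      bf <- array(BRIGHTFIELD_BG, dims)
      for (i in seq_along(cells)) {
        cl <- cells[[i]]
        r <- cl$diameter / 2
        bb <- sphere_bbox(spec, cl$center, r + BRIGHTFIELD_RIM_HALFWIDTH)
        inner <- bb$r2 <= (r - BRIGHTFIELD_RIM_HALFWIDTH)^2
        rim <- bb$mask & !inner
        bf <- paint(bf, bb, inner, BRIGHTFIELD_INTERIOR)
        bf <- paint(bf, bb, rim, BRIGHTFIELD_RIM)
      }
      bf <- gauss_blur3d(bf, c(1, 1, 0))
      out_channels$brightfield <- apply_noise(bf, spec)
    }
    if ("dapi" %in% channels) {
      dp <- array(0, dims)
      dp[nuc_lab > 0] <- DAPI_LEVEL
      dp <- if (any(sig_vox > 0)) gauss_blur3d(dp, sig_vox) else dp
      out_channels$dapi <- apply_noise(dp, spec)
    }

    truth_cells <- data.frame(
      label = seq_along(cells),
      class = vapply(cells, function(c) c$localization_class, character(1)),
      intensity_scale = vapply(cells, function(c) c$intensity_scale, numeric(1)),
      diameter_um = vapply(cells, function(c) c$diameter, numeric(1)),
      centroid_x_px = vapply(cells, function(c) c$center[1], numeric(1)) /
        spec$pixel_size_xy - 0.5,
      centroid_y_px = vapply(cells, function(c) c$center[2], numeric(1)) /
        spec$pixel_size_xy - 0.5,
      true_mean_gfp = true_mean,
      true_cell_volume = vapply(seq_along(cells), function(i)
        sum(cell_lab == i), numeric(1)) * voxvol,
      true_mito_volume = vapply(seq_along(cells), function(i)
        sum(mito_lab == i), numeric(1)) * voxvol,
      stringsAsFactors = FALSE
    )

    list(
      field = structure(list(channels = out_channels, spec = spec,
                             genotype = genotype, gene = gene,
                             field_index = as.integer(field_index)),
                        class = "field_image"),
      truth = structure(list(cell_label_volume = cell_lab,
                             nucleus_label_volume = nuc_lab,
                             mito_label_volume = mito_lab,
                             cells = truth_cells),
                        class = "ground_truth")
    )
  })
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("field_image: %s / %s field %d; %d x %d x %d; channels: %s\n",
              x$gene, x$genotype, x$field_index, d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a field and its ground truth to disk
#'
#' One multi-page 32-bit float TIFF per channel (z slices as pages), a JSON
#' metadata sidecar with the acquisition calibration, a 16-bit TIFF per
#' ground-truth label volume, and the per-cell truth table as CSV.
#'
#' @param fg list returned by \code{\link{generate_field}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_field <- function(fg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fg$field$spec
  for (ch in names(fg$field$channels)) {
    vol <- fg$field$channels[[ch]]
    # tiff expects y-x matrices in [0, 1]; store a scale factor in metadata
    mx <- max(vol, 1e-12)
    pages <- lapply(seq_len(dim(vol)[3]), function(k) t(vol[, , k]) / mx)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L)
    meta <- sprintf(
      paste0('{"channel": "%s", "scale": %.10g, "pixel_size_xy_um": %g, ',
             '"z_step_um": %g, "genotype": "%s", "gene": "%s", "field_index": %d}'),
      ch, mx, spec$pixel_size_xy, spec$z_step, fg$field$genotype,
      fg$field$gene, fg$field$field_index)
    writeLines(meta, file.path(dir, paste0(ch, ".json")))
  }
  for (lb in c("cell_label_volume", "nucleus_label_volume", "mito_label_volume")) {
    vol <- fg$truth[[lb]]
    pages <- lapply(seq_len(dim(vol)[3]), function(k) t(vol[, , k]) / 65535)
    tiff::writeTIFF(pages, file.path(dir, paste0(lb, ".tif")),
                    bits.per.sample = 16L)
  }
  utils::write.csv(fg$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  invisible(dir)
}
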