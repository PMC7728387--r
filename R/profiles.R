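#' Nucleus-centered intensity line profile
#'
#' Samples the projected GFP image along a fixed-length line centered on the
#' nucleus centroid, by bilinear interpolation. With the default 60 samples
#' at the default 0.1038 um/px calibration the line spans 6.23 um and the
#' centre sample (index 30, 0-based) lies on the nucleus centroid. Samples
#' falling outside the frame are NA.
#'
#' @param image 2D numeric matrix (e.g. \code{project_z} of the GFP stack).
#' @param centroid numeric c(x, y), 0-based pixel coordinates of the
#'   nucleus centroid.
#' @param angle line angle, radians (0 = horizontal).
#' @param length_px number of samples (default 60).
#' @param cell_label,replicate metadata carried on the profile.
#' @return object of class \code{line_profile}: list(positions (pixel
#'   offsets from the centre), values, cell_label, replicate).
#' @export
line_profile <- function(image, centroid, angle = 0, length_px = 60L,
                         cell_label = NA_integer_, replicate = 1L) {
  if (any(is.na(centroid))) stop("nucleus centroid is absent")
  stopifnot(length(dim(image)) == 2, length_px >= 2)
  offsets <- seq_len(length_px) - 1 - floor(length_px / 2)
  px <- centroid[1] + offsets * cos(angle)
  py <- centroid[2] + offsets * sin(angle)
  values <- bilinear_sample(image, px, py)
  structure(list(positions = offsets, values = values,
                 cell_label = cell_label, replicate = replicate),
            class = "line_profile")
}

# Bilinear interpolation at 0-based continuous coordinates; NA outside.
bilinear_sample <- function(image, x, y) {
  nx <- nrow(image)
  ny <- ncol(image)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  ok <- x0 >= 0 & x0 <= nx - 2 + 1e-9 & y0 >= 0 & y0 <= ny - 2 + 1e-9
  # clamp the upper edge so points exactly on the last pixel interpolate
  x0 <- pmin(pmax(x0, 0), nx - 2)
  y0 <- pmin(pmax(y0, 0), ny - 2)
  v <- (1 - fx) * (1 - fy) * image[cbind(x0 + 1, y0 + 1)] +
       fx * (1 - fy) * image[cbind(x0 + 2, y0 + 1)] +
       (1 - fx) * fy * image[cbind(x0 + 1, y0 + 2)] +
       fx * fy * image[cbind(x0 + 2, y0 + 2)]
  v[!ok] <- NA_real_
  v
}

#' Mean line profile across replicates
#'
#' Pointwise mean of the per-replicate mean curves, so replicates are
#' weighted equally regardless of how many cells each contributed.
#'
#' @param profiles list of \code{line_profile} objects.
#' @return list(mean (numeric curve), replicate_means (matrix, one row per
#'   replicate), per_cell (matrix, one row per profile), positions).
#' @export
mean_profile <- function(profiles) {
  if (!length(profiles)) stop("empty profile group")
  vals <- t(vapply(profiles, function(p) p$values,
                   numeric(length(profiles[[1]]$values))))
  reps <- vapply(profiles, function(p) as.character(p$replicate), character(1))
  rep_means <- t(vapply(split(seq_along(profiles), reps), function(i) {
    colMeans(vals[i, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(vals))))
  list(mean = colMeans(rep_means, na.rm = TRUE),
       replicate_means = rep_means,
       per_cell = vals,
       positions = profiles[[1]]$positions)
}

# in-plane erosion of a 3D mask by one voxel (4-neighbourhood per slice)
erode_xy <- function(m) {
  m & shift_zero(m * 1, 1, 1) > 0 & shift_zero(m * 1, -1, 1) > 0 &
      shift_zero(m * 1, 1, 2) > 0 & shift_zero(m * 1, -1, 2) > 0
}

#' Per-cell localization features
#'
#' For every labeled cell, measures the feature set used by the
#' localization-change classifier: mean GFP in the nucleus, in a peripheral
#' shell (cell voxels within \code{shell_um} of the lateral cell boundary),
#' and in the remaining cytoplasm; the nuclear/cytoplasmic ratio; the number
#' of discrete puncta (connected components of the projection above 2x the
#' cell median, with area between \code{puncta_area_um2[1]} and
#' \code{[2]}); the coefficient of variation of the projected signal inside
#' the cell; and (optionally) the total mitochondrial skeleton length per
#' cell area.
#'
#' @param gfp_volume numeric 3D array.
#' @param cell_labels 3D integer cell label volume (ground truth or an
#'   expanded segmentation).
#' @param nucleus_labels 3D integer nucleus label volume.
#' @param spec an \code{acquisition_spec}.
#' @param shell_um peripheral shell thickness, um (default 0.3).
#' @param puncta_area_um2 punctum area window, um^2 (the upper bound admits
#'   small merged foci while still excluding whole-cell blobs).
#' @param skeleton compute mitochondrial skeleton features (slower).
#' @param rl_iters Richardson-Lucy iterations applied to the sub-volume
#'   before structure segmentation for the skeleton features (0 = none).
#' @return data.frame, one row per cell: label, nuclear_mean,
#'   cytoplasmic_mean, peripheral_mean, nc_ratio, n_puncta, punctate_cv,
#'   skeleton_length_um, mito_likeness, cell_area_um2.
#' @export
localization_features <- function(gfp_volume, cell_labels, nucleus_labels,
                                  spec, shell_um = 0.3,
                                  puncta_area_um2 = c(0.05, 2.0),
                                  skeleton = TRUE, rl_iters = 10L) {
  stopifnot(all(dim(gfp_volume) == dim(cell_labels)))
  proj <- project_z(gfp_volume, "max")
  labs <- sort(unique(cell_labels[cell_labels > 0]))
  n_erode <- max(1L, round(shell_um / spec$pixel_size_xy))
  voxdims <- c(spec$pixel_size_xy, spec$pixel_size_xy, spec$z_step)
  px_area <- spec$pixel_size_xy^2
  rows <- lapply(labs, function(l) {
    sel <- cell_labels == l
    ijk <- which(sel, arr.ind = TRUE)
    rng <- apply(ijk, 2, range)
    ix <- rng[1, 1]:rng[2, 1]; iy <- rng[1, 2]:rng[2, 2]; iz <- rng[1, 3]:rng[2, 3]
    cm <- sel[ix, iy, iz, drop = FALSE]
    gv <- gfp_volume[ix, iy, iz, drop = FALSE]
    nm <- nucleus_labels[ix, iy, iz, drop = FALSE] == l
    core <- cm
    for (k in seq_len(n_erode)) core <- erode_xy(core)
    shell <- cm & !core
    cyto <- core & !nm
    nuclear_mean <- if (any(nm)) mean(gv[nm]) else NA_real_
    cytoplasmic_mean <- if (any(cyto)) mean(gv[cyto]) else NA_real_
    peripheral_mean <- if (any(shell)) mean(gv[shell]) else NA_real_
    # 2D features on the projection
    lab2d_cell <- apply(cm, c(1, 2), any)
    p2 <- proj[ix, iy, drop = FALSE]
    cell_px <- p2[lab2d_cell]
    med <- stats::median(cell_px)
    pm <- lab2d_cell & p2 > 2 * med
    n_puncta <- 0L
    if (any(pm)) {
      bl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(pm)))
      areas <- tabulate(bl[bl > 0]) * px_area
      n_puncta <- sum(areas >= puncta_area_um2[1] & areas <= puncta_area_um2[2])
    }
    punctate_cv <- stats::sd(cell_px) / mean(cell_px)
    skeleton_length <- NA_real_
    if (skeleton) {
      gd <- if (rl_iters > 0) deconvolve_rl(gv, spec, rl_iters) else gv
      # stricter than the morphometry defaults: deconvolution sharpens shot
      # noise on structureless cells into speckles, so require stronger
      # contrast and at least ~0.1 um^3 per component
      mmask <- segment_mito_voxels(gd, spec, min_contrast = 3,
                                   min_voxels = max(5, round(0.1 / prod(voxdims))))
      mmask <- mmask & cm
      # a "structure" filling most of the cell is just uniform signal, not
      # a filamentous network: no skeleton (also avoids thinning huge blobs)
      if (sum(mmask) > 0.5 * sum(cm)) {
        skeleton_length <- 0
      } else {
        skeleton_length <- elongation_features(mmask, voxdims)$skeleton_total_length
      }
    }
    cell_area <- sum(lab2d_cell) * px_area
    data.frame(label = l, nuclear_mean = nuclear_mean,
               cytoplasmic_mean = cytoplasmic_mean,
               peripheral_mean = peripheral_mean,
               nc_ratio = nuclear_mean / cytoplasmic_mean,
               n_puncta = n_puncta, punctate_cv = punctate_cv,
               skeleton_length_um = skeleton_length,
               mito_likeness = skeleton_length / cell_area,
               cell_area_um2 = cell_area)
  })
  do.call(rbind, rows)
}

#' Nuclear-enrichment flag and percent-nuclear summary
#'
#' A cell is nuclear-enriched when its nuclear/cytoplasmic mean ratio
#' exceeds \code{ratio_cut}. \code{percent_nuclear} reports 100 x
#' flagged/total per replicate; cells with zero cytoplasmic mean are
#' excluded with a warning. The percentage is invariant to global intensity
#' scaling.
#'
#' @param features data.frame from \code{\link{localization_features}}.
#' @param ratio_cut nuclear/cytoplasmic ratio cut-off (default 1.5).
#' @return logical vector, one per row of \code{features}.
#' @export
nuclear_enrichment <- function(features, ratio_cut = 1.5) {
  bad <- !is.na(features$cytoplasmic_mean) & features$cytoplasmic_mean == 0
  if (any(bad)) {
    warning(sprintf("%d cells with zero cytoplasmic mean excluded", sum(bad)))
  }
  flag <- features$nc_ratio > ratio_cut
  flag[bad] <- NA
  flag
}

#' @rdname nuclear_enrichment
#' @param replicate replicate id per cell (default: single replicate).
#' @param min_cells minimum cells per replicate (default 50; fewer warns).
#' @return \code{percent_nuclear}: data.frame(replicate, percent, n).
#' @export
percent_nuclear <- function(features, replicate = NULL, ratio_cut = 1.5,
                            min_cells = 50L) {
  flag <- nuclear_enrichment(features, ratio_cut)
  if (is.null(replicate)) replicate <- rep(1L, nrow(features))
  keep <- !is.na(flag)
  out <- do.call(rbind, lapply(split(which(keep), replicate[keep]), function(i) {
    data.frame(n = length(i), percent = 100 * mean(flag[i]))
  }))
  out$replicate <- rownames(out)
  rownames(out) <- NULL
  if (any(out$n < min_cells)) {
    warning(sprintf("replicates with fewer than %d cells counted", min_cells))
  }
  out[, c("replicate", "percent", "n")]
}

#' Classifier configuration for localization changes
#'
#' @param puncta_delta minimum increase in mean puncta count.
#' @param cv_rise minimum multiplicative rise of the punctate CV.
#' @param nc_cut nuclear/cytoplasmic ratio boundary crossed in a
#'   nucleus-cytoplasm transition.
#' @param periph_cut peripheral/cytoplasmic ratio boundary for a
#'   periphery-to-cytoplasm transition.
#' @param skel_rise minimum multiplicative rise of skeleton length for
#'   mitochondrial elongation.
#' @param fold_band fold-change band considered "no abundance change".
#' @return named list of thresholds.
#' @export
classify_config <- function(puncta_delta = 3, cv_rise = 1.5, nc_cut = 1.5,
                            periph_cut = 1.2, skel_rise = 1.5,
                            fold_band = c(0.7, 1.3)) {
  list(puncta_delta = puncta_delta, cv_rise = cv_rise, nc_cut = nc_cut,
       periph_cut = periph_cut, skel_rise = skel_rise, fold_band = fold_band)
}

#' Mean feature summary of a cell population
#'
#' @param features data.frame from \code{\link{localization_features}}.
#' @return named list of feature means.
#' @export
summarize_features <- function(features) {
  num <- vapply(features, is.numeric, logical(1))
  as.list(colMeans(features[, num & names(features) != "label", drop = FALSE],
                   na.rm = TRUE))
}

#' Classify a paired WT/mutant localization change
#'
#' Applies a fixed, ordered rule list to the two populations' mean feature
#' summaries: (1) cytoplasm-to-punctate when the mean puncta count rises by
#' at least \code{puncta_delta} and the punctate CV by \code{cv_rise}; (2/3)
#' nucleus-to-cytoplasm / cytoplasm-to-nucleus when the mean
#' nuclear/cytoplasmic ratio crosses \code{nc_cut} downward/upward; (4)
#' periphery-to-cytoplasm when the peripheral/cytoplasmic ratio drops below
#' \code{periph_cut} from above; (5) mitochondrial elongation when the mean
#' skeleton length rises by \code{skel_rise}; (6) otherwise
#' increased/decreased abundance when the fold change is outside
#' \code{fold_band}; else "no change".
#'
#' @param wt_summary,mut_summary named lists from
#'   \code{\link{summarize_features}}.
#' @param fold_change mutant/WT intensity fold change.
#' @param config thresholds from \code{\link{classify_config}}.
#' @return category string.
#' @export
classify_change <- function(wt_summary, mut_summary, fold_change,
                            config = classify_config()) {
  w <- wt_summary
  m <- mut_summary
  if ((m$n_puncta - w$n_puncta) >= config$puncta_delta &&
      !is.na(m$punctate_cv) && !is.na(w$punctate_cv) &&
      m$punctate_cv >= config$cv_rise * w$punctate_cv) {
    return("cytoplasm to punctate")
  }
  if (!is.na(w$nc_ratio) && !is.na(m$nc_ratio)) {
    if (w$nc_ratio > config$nc_cut && m$nc_ratio < config$nc_cut) {
      return("nucleus to cytoplasm")
    }
    if (w$nc_ratio < config$nc_cut && m$nc_ratio > config$nc_cut) {
      return("cytoplasm to nucleus")
    }
  }
  pr_w <- w$peripheral_mean / w$cytoplasmic_mean
  pr_m <- m$peripheral_mean / m$cytoplasmic_mean
  if (!is.na(pr_w) && !is.na(pr_m) &&
      pr_w >= config$periph_cut && pr_m < config$periph_cut) {
    return("cell periphery to cytoplasm")
  }
  if (!is.na(w$skeleton_length_um) && !is.na(m$skeleton_length_um) &&
      w$skeleton_length_um > 0 &&
      m$skeleton_length_um >= config$skel_rise * w$skeleton_length_um) {
    return("mitochondrial elongation")
  }
  if (fold_change > config$fold_band[2]) return("increased abundance")
  if (fold_change < config$fold_band[1]) return("decreased abundance")
  "no change"
}
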