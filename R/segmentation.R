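#' Sphere-approximated cell volume from two diameter measurements
#'
#' Averages the two orthogonal diameter measurements and returns the volume
#' of the sphere with that mean diameter: \eqn{V = 4/3 \pi r^3} with
#' \eqn{r = (d_a + d_b) / 4}.
#'
#' @param diameter_a,diameter_b diameters, um (> 0); vectors are accepted
#'   elementwise.
#' @return volume(s), um^3.
#' @examples
#' estimate_cell_volume(4, 4)      # 33.51 um^3
#' estimate_cell_volume(3, 5)      # same: mean diameter 4 um
#' @export
estimate_cell_volume <- function(diameter_a, diameter_b) {
  if (any(diameter_a <= 0) || any(diameter_b <= 0)) {
    stop("cell diameters must be positive")
  }
  r <- (diameter_a + diameter_b) / 4
  4 / 3 * pi * r^3
}

# Otsu threshold of a numeric vector (256-bin histogram between min and max).
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  h <- as.numeric(tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                                n_bins), n_bins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  tot_w <- w[n_bins]
  tot_mu <- mu[n_bins]
  between <- (tot_mu * w - tot_w * mu)^2 / (w * (tot_w - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / n_bins * diff(rng)
}

#' Segment cells from the brightfield channel
#'
#' The mid-stack brightfield slice is median filtered, converted to an edge
#' magnitude (Sobel), thresholded by Otsu, hole-filled, opened to drop
#' speckles, shrunk to compensate for the bright rim straddling the cell
#' boundary, and split into touching cells by a distance-transform
#' watershed. Regions outside the area bounds are removed and regions
#' touching the frame border are flagged. All stages are intensity-scale
#' invariant (the slice is normalized before thresholding).
#'
#' @param brightfield_volume numeric array c(nx, ny, nz) (or a 2D matrix).
#' @param spec an \code{acquisition_spec} (calibration for diameters).
#' @param min_area,max_area region area bounds in pixels (defaults 100 and
#'   5000 px^2 at the default 0.1038 um/px calibration; scale them when
#'   using other calibrations).
#' @param median_radius median filter radius, px.
#' @param shrink_px erosion steps applied after hole filling, px.
#' @param watershed_tol tolerance of the distance-map watershed.
#' @return list with \code{labels} (2D integer label map, matrix nx x ny)
#'   and \code{cells}: a data.frame with columns label, centroid_x_px,
#'   centroid_y_px (0-based), diameter_a_um, diameter_b_um (best-fit ellipse
#'   major/minor axes), area_px, cell_volume_um3, border_touching.
#' @export
segment_cells <- function(brightfield_volume, spec,
                          min_area = 100, max_area = 5000,
                          median_radius = 2L, shrink_px = 0L,
                          watershed_tol = 1) {
  bf <- if (length(dim(brightfield_volume)) == 3) {
    brightfield_volume[, , ceiling(dim(brightfield_volume)[3] / 2)]
  } else {
    brightfield_volume
  }
  mx <- max(bf)
  if (mx <= 0) {
    warning("empty brightfield image: no cells found")
    return(empty_cell_table(dim(bf)))
  }
  img <- EBImage::Image(bf / mx)
  img <- EBImage::medianFilter(img, median_radius)
  sob_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(img, sob_x)
  gy <- EBImage::filter2(img, t(sob_x))
  edge <- sqrt(gx^2 + gy^2)
  edge <- edge / max(edge)
  thr <- otsu_threshold(as.numeric(edge))
  mask <- EBImage::fillHull(edge > thr)
  brush <- EBImage::makeBrush(3, shape = "diamond")
  mask <- EBImage::opening(mask, brush)
  for (i in seq_len(shrink_px)) mask <- EBImage::erode(mask, brush)
  if (!any(mask)) {
    warning("no regions above threshold: no cells found")
    return(empty_cell_table(dim(bf)))
  }
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tol)
  labels <- EBImage::imageData(labels)

  ft_m <- EBImage::computeFeatures.moment(labels)
  ft_s <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(ft_m))) ft_m <- matrix(ft_m, nrow = 1,
                                         dimnames = list(NULL, names(ft_m)))
  if (is.null(dim(ft_s))) ft_s <- matrix(ft_s, nrow = 1,
                                         dimnames = list(NULL, names(ft_s)))
  area <- ft_s[, "s.area"]
  keep <- which(area >= min_area & area <= max_area)
  # relabel compactly, dropping filtered regions
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]

  if (!length(keep)) {
    warning("all regions outside area bounds: no cells found")
    return(empty_cell_table(dim(bf)))
  }
  border <- vapply(seq_along(keep), function(i) {
    any(labels[1, ] == i) || any(labels[dim(labels)[1], ] == i) ||
      any(labels[, 1] == i) || any(labels[, dim(labels)[2]] == i)
  }, logical(1))
  # best-fit ellipse axes: m.majoraxis is the full major axis length (px);
  # minor axis from eccentricity
  major_px <- ft_m[keep, "m.majoraxis"]
  minor_px <- major_px * sqrt(1 - ft_m[keep, "m.eccentricity"]^2)
  da <- major_px * spec$pixel_size_xy
  db <- minor_px * spec$pixel_size_xy
  cells <- data.frame(
    label = seq_along(keep),
    centroid_x_px = ft_m[keep, "m.cx"] - 1,   # report 0-based coordinates
    centroid_y_px = ft_m[keep, "m.cy"] - 1,
    diameter_a_um = da,
    diameter_b_um = db,
    area_px = as.numeric(area[keep]),
    cell_volume_um3 = estimate_cell_volume(da, db),
    border_touching = border,
    stringsAsFactors = FALSE
  )
  list(labels = labels, cells = cells)
}

#' Match predicted to ground-truth labels by intersection-over-union
#'
#' For each ground-truth region, finds the predicted region with the
#' largest overlap and reports their IoU (0 when nothing overlaps).
#'
#' @param truth_labels,pred_labels integer label maps (3D truth volumes are
#'   projected by per-pixel maximum first).
#' @return data.frame: truth_label, matched_label, iou.
#' @export
match_labels <- function(truth_labels, pred_labels) {
  if (length(dim(truth_labels)) == 3) truth_labels <- project_z(truth_labels, "max")
  if (length(dim(pred_labels)) == 3) pred_labels <- project_z(pred_labels, "max")
  stopifnot(all(dim(truth_labels) == dim(pred_labels)))
  tl <- sort(unique(truth_labels[truth_labels > 0]))
  out <- lapply(tl, function(l) {
    sel <- truth_labels == l
    cand <- pred_labels[sel]
    cand <- cand[cand > 0]
    if (!length(cand)) {
      return(data.frame(truth_label = l, matched_label = NA_integer_, iou = 0))
    }
    tab <- table(cand)
    best <- as.integer(names(tab)[which.max(tab)])
    inter <- max(tab)
    union <- sum(sel) + sum(pred_labels == best) - inter
    data.frame(truth_label = l, matched_label = best, iou = inter / union)
  })
  do.call(rbind, out)
}

empty_cell_table <- function(d) {
  list(labels = matrix(0L, d[1], d[2]),
       cells = data.frame(label = integer(0), centroid_x_px = numeric(0),
                          centroid_y_px = numeric(0), diameter_a_um = numeric(0),
                          diameter_b_um = numeric(0), area_px = numeric(0),
                          cell_volume_um3 = numeric(0),
                          border_touching = logical(0)))
}

#' Detect at most one nucleus per cell from the DAPI channel
#'
#' Max-projects the DAPI stack, Otsu-thresholds the normalized projection,
#' labels the blobs, and assigns to each cell the blob with the largest
#' overlap area inside that cell (ties broken by the lower blob label).
#' Cells without any DAPI blob are flagged nucleus-absent.
#'
#' @param dapi_volume numeric array (3D) or matrix; error if NULL/missing.
#' @param cell_labels 2D integer label map from \code{\link{segment_cells}}
#'   (or a projected ground-truth label volume).
#' @return data.frame with columns label, has_nucleus, nucleus_x_px,
#'   nucleus_y_px (0-based centroids, NA when absent), nucleus_area_px; plus
#'   attribute \code{"nucleus_mask"} (logical matrix).
#' @export
detect_nuclei <- function(dapi_volume, cell_labels) {
  if (is.null(dapi_volume)) {
    stop("DAPI channel missing: supply dapi_volume or use ground-truth nuclei")
  }
  if (length(dim(cell_labels)) == 3) cell_labels <- project_z(cell_labels, "max")
  proj <- project_z(dapi_volume, "max")
  if (!all(dim(proj) == dim(cell_labels))) {
    stop("DAPI and label shapes differ")
  }
  labs <- sort(unique(cell_labels[cell_labels > 0]))
  out <- data.frame(label = labs, has_nucleus = FALSE,
                    nucleus_x_px = NA_real_, nucleus_y_px = NA_real_,
                    nucleus_area_px = NA_real_)
  mx <- max(proj)
  if (mx <= 0) {
    attr(out, "nucleus_mask") <- matrix(FALSE, nrow(proj), ncol(proj))
    return(out)
  }
  thr <- otsu_threshold(as.numeric(proj / mx))
  mask <- proj / mx > thr
  blobs <- EBImage::bwlabel(EBImage::Image(mask))
  blobs <- EBImage::imageData(blobs)
  for (i in seq_along(labs)) {
    inside <- blobs[cell_labels == labs[i]]
    inside <- inside[inside > 0]
    if (!length(inside)) next
    tab <- table(inside)
    best <- as.integer(names(tab)[which(tab == max(tab))])
    best <- min(best)  # tie: lower blob label
    sel <- blobs == best & cell_labels == labs[i]
    ij <- which(sel, arr.ind = TRUE)
    out$has_nucleus[i] <- TRUE
    out$nucleus_x_px[i] <- mean(ij[, 1]) - 1
    out$nucleus_y_px[i] <- mean(ij[, 2]) - 1
    out$nucleus_area_px[i] <- nrow(ij)
  }
  attr(out, "nucleus_mask") <- mask
  out
}
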