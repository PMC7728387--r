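# 26-connectivity neighbour offsets (excluding the centre), as a 26 x 3
# matrix of (dx, dy, dz).
NEIGH26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

as_vol3d <- function(mask) {
  if (is.null(dim(mask))) stop("mask must be an array")
  if (length(dim(mask)) == 2) dim(mask) <- c(dim(mask), 1L)
  mask
}

#' Label connected components of a 3D binary mask (26-connectivity)
#'
#' @param mask logical array (2D masks are treated as single-slice volumes).
#' @return integer array of component labels (0 = background), same dim as
#'   the input.
#' @export
label3d <- function(mask) {
  mask <- as_vol3d(mask)
  d <- dim(mask)
  out <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) {
    if (d[3] == 1) dim(out) <- d[1:2]
    return(out)
  }
  co <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  edges <- NULL
  # forward offsets only (13), so each neighbour pair appears once
  fwd <- NEIGH26[NEIGH26[, 3] > 0 |
                 (NEIGH26[, 3] == 0 & (NEIGH26[, 2] > 0 |
                  (NEIGH26[, 2] == 0 & NEIGH26[, 1] > 0))), , drop = FALSE]
  el <- vector("list", nrow(fwd))
  for (k in seq_len(nrow(fwd))) {
    nx <- co[, 1] + fwd[k, 1]
    ny <- co[, 2] + fwd[k, 2]
    nz <- co[, 3] + fwd[k, 3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nid <- id_of[cbind(nx[ok], ny[ok], nz[ok])]
    src <- which(ok)[nid > 0]
    if (!length(src)) next
    el[[k]] <- cbind(src, nid[nid > 0])
  }
  edges <- do.call(rbind, el)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  out[idx] <- as.integer(memb)
  if (d[3] == 1) dim(out) <- d[1:2]
  out
}

#' Segment mitochondrial voxels within one cell's GFP sub-volume
#'
#' Foreground voxels are those above a per-cell automatic threshold.  The
#' default \code{"halfmax"} rule places the threshold halfway between the
#' sub-volume's background level (its median) and its structure peak (the
#' 99.9th percentile), which tracks the half-maximum contour of
#' PSF-broadened tubules and so keeps the segmented volume close to the
#' underlying structure.  The \code{"otsu"} rule uses the Otsu threshold of
#' the sub-volume floored at (background mean + 3 background sd), the
#' background being the population at or below the Otsu split.  Components
#' smaller than \code{min_voxels} are removed as speckles. A structureless
#' (near-constant) sub-volume yields an empty mask.
#'
#' @param gfp_subvolume numeric array cropped to the cell's bounding box.
#' @param spec an \code{acquisition_spec} (unused by the threshold itself;
#'   kept for interface symmetry and future calibration-aware filters).
#' @param min_voxels speckle filter: minimum component size (default 5).
#' @param method threshold rule: \code{"halfmax"} (default) or
#'   \code{"otsu"}.
#' @param min_contrast minimum ratio of the mean foreground intensity to
#'   twice the sub-volume median for the mask to count as real structure; a
#'   sub-volume whose bright tail is just noise on a uniform signal yields
#'   an empty mask.
#' @return logical array of the same dim.
#' @export
segment_mito_voxels <- function(gfp_subvolume, spec = NULL, min_voxels = 5L,
                                method = c("halfmax", "otsu"),
                                min_contrast = 2) {
  method <- match.arg(method)
  v <- as.numeric(gfp_subvolume)
  if (all(v == 0) || stats::sd(v) < 1e-12) {
    return(array(FALSE, dim(gfp_subvolume)))
  }
  if (method == "halfmax") {
    bg <- stats::median(v)
    pk <- stats::quantile(v, 0.999, names = FALSE)
    thr <- bg + 0.5 * (pk - bg)
  } else {
    thr <- otsu_threshold(v)
    bg <- v[v <= thr]
    if (length(bg) >= 2) {
      thr <- max(thr, mean(bg) + 3 * stats::sd(bg))
    }
  }
  mask <- as_vol3d(gfp_subvolume > thr)
  if (any(mask) &&
      mean(v[mask]) < min_contrast * stats::median(v)) {
    mask[] <- FALSE
  }
  if (!any(mask)) {
    out <- mask
  } else {
    lab <- as_vol3d(label3d(mask))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_voxels)
    out <- array(lab %in% keep, dim(lab))
  }
  if (length(dim(gfp_subvolume)) == 2) dim(out) <- dim(gfp_subvolume)
  out
}

#' Mitochondrial voxel volume
#'
#' @param mask logical array.
#' @param voxel_dims numeric c(dx, dy, dz), um.
#' @return volume, um^3 (voxel count x voxel volume).
#' @export
mito_volume <- function(mask, voxel_dims) {
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  sum(mask) * prod(voxel_dims)
}

#' Mitochondrial surface area by voxel-face counting
#'
#' Counts mask faces exposed to background (or the volume boundary) along
#' each axis and weights them by the corresponding anisotropic face area.
#' For smooth shapes this systematically overestimates the true surface by
#' up to ~1.5x, deterministically.
#'
#' @inheritParams mito_volume
#' @return surface area, um^2.
#' @export
mito_surface_area <- function(mask, voxel_dims) {
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  m <- as_vol3d(mask)
  face_area <- c(voxel_dims[2] * voxel_dims[3],   # faces normal to x
                 voxel_dims[1] * voxel_dims[3],   # normal to y
                 voxel_dims[1] * voxel_dims[2])   # normal to z
  total <- 0
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- shift_zero(m * 1, s, ax)  # neighbour occupancy, 0 outside
      total <- total + sum(m & nb == 0) * face_area[ax]
    }
  }
  total
}

#' Richardson-Lucy deconvolution with the acquisition PSF
#'
#' Iterative maximum-likelihood deconvolution of a (sub)volume against the
#' separable anisotropic Gaussian PSF of the acquisition. Restoring the
#' tubule cross-sections before thresholding removes most of the axial
#' PSF halo, which otherwise inflates voxel-counted volumes and does so
#' unequally between sparse and dense networks.
#'
#' @param vol numeric 3D array.
#' @param spec the \code{acquisition_spec} whose PSF blurred the data.
#' @param iters number of RL iterations (default 15).
#' @return deconvolved array, same dim.
#' @export
deconvolve_rl <- function(vol, spec, iters = 15L) {
  sv <- c(spec$psf_sigma_xy / spec$pixel_size_xy,
          spec$psf_sigma_xy / spec$pixel_size_xy,
          spec$psf_sigma_z / spec$z_step)
  if (all(sv <= 0)) return(vol)
  est <- array(mean(vol), dim(vol))
  for (i in seq_len(iters)) {
    conv <- gauss_blur3d(est, sv)
    conv[conv < 1e-9] <- 1e-9
    est <- est * gauss_blur3d(vol / conv, sv)
  }
  est
}

#' Measure mitochondria of every cell in a field
#'
#' Pipeline step over one field: crops each cell's bounding box from the
#' GFP stack (using the given cell label volume), optionally deconvolves it
#' (\code{\link{deconvolve_rl}}), segments mitochondrial voxels
#' (\code{\link{segment_mito_voxels}}), and measures volume, surface area
#' and (optionally) elongation features.
#'
#' @param gfp_volume numeric 3D array.
#' @param cell_labels 3D integer cell label volume (ground truth or an
#'   expanded segmentation).
#' @param spec the \code{acquisition_spec}.
#' @param deconvolve run RL deconvolution before thresholding (default
#'   TRUE).
#' @param features compute skeleton/branch/component features (slower).
#' @param ... passed to \code{\link{segment_mito_voxels}}.
#' @return data.frame per cell: label, mito_volume_um3,
#'   mito_surface_area_um2 and, when \code{features}, skeleton_length_um,
#'   n_branches, n_components.
#' @export
measure_mito <- function(gfp_volume, cell_labels, spec, deconvolve = TRUE,
                         features = FALSE, ...) {
  stopifnot(all(dim(gfp_volume) == dim(cell_labels)))
  voxdims <- c(spec$pixel_size_xy, spec$pixel_size_xy, spec$z_step)
  labs <- sort(unique(cell_labels[cell_labels > 0]))
  rows <- lapply(labs, function(l) {
    sel <- cell_labels == l
    ijk <- which(sel, arr.ind = TRUE)
    rng <- apply(ijk, 2, range)
    gv <- gfp_volume[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                     rng[1, 3]:rng[2, 3], drop = FALSE]
    if (deconvolve) gv <- deconvolve_rl(gv, spec)
    mk <- segment_mito_voxels(gv, spec, ...)
    mk <- mk & sel[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                   rng[1, 3]:rng[2, 3], drop = FALSE]
    row <- data.frame(label = l,
                      mito_volume_um3 = mito_volume(mk, voxdims),
                      mito_surface_area_um2 = mito_surface_area(mk, voxdims))
    if (features) {
      ef <- elongation_features(mk, voxdims)
      row$skeleton_length_um <- ef$skeleton_total_length
      row$n_branches <- ef$n_branches
      row$n_components <- ef$n_components
    }
    row
  })
  do.call(rbind, rows)
}

#' Per-cell mitochondrial fraction
#'
#' Each cell's mitochondrial volume divided by the strain's mean estimated
#' cell volume (the strain-average sphere-approximated volume, not the
#' individual cell's own volume; set \code{per_cell = TRUE} for the latter).
#'
#' @param mito_volumes numeric vector of per-cell mitochondrial volumes,
#'   um^3.
#' @param cell_volumes numeric vector of the strain's estimated per-cell
#'   volumes, um^3 (e.g. \code{cell_volume_um3} from
#'   \code{\link{segment_cells}} or ground truth).
#' @param per_cell divide by each cell's own volume instead of the strain
#'   mean (requires equal lengths).
#' @param min_cells minimum cells for an unflagged summary (default 50).
#' @return list with \code{fractions} (per cell), \code{mean}, \code{sd},
#'   \code{n}, \code{flagged} (TRUE when n < min_cells).
#' @export
mitochondrial_fraction <- function(mito_volumes, cell_volumes,
                                   per_cell = FALSE, min_cells = 50L) {
  stopifnot(all(mito_volumes >= 0), all(cell_volumes > 0))
  if (per_cell) {
    stopifnot(length(mito_volumes) == length(cell_volumes))
    fr <- mito_volumes / cell_volumes
  } else {
    fr <- mito_volumes / mean(cell_volumes)
  }
  flagged <- length(fr) < min_cells
  if (flagged) {
    warning(sprintf("only %d cells (< %d): mitochondrial fraction summary flagged",
                    length(fr), min_cells))
  }
  list(fractions = fr, mean = mean(fr), sd = stats::sd(fr),
       n = length(fr), flagged = flagged)
}

# --- 3D topological skeleton ------------------------------------------------

# Precomputed adjacency inside a 3x3x3 neighbourhood, used by the
# simple-point test: 27 positions (centre = 14), each with its 26- and
# 6-neighbour position lists.
N27 <- local({
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  adj26 <- lapply(seq_len(27), function(i) {
    d <- abs(sweep(g, 2, g[i, ]))
    which(apply(d, 1, max) == 1 & rowSums(d) > 0)
  })
  adj6 <- lapply(seq_len(27), function(i) {
    d <- abs(sweep(g, 2, g[i, ]))
    which(rowSums(d) == 1)
  })
  dist18 <- lapply(seq_len(27), function(i) {
    d <- abs(sweep(g, 2, g[i, ]))
    which(apply(d, 1, max) == 1 & rowSums(d) <= 2 & rowSums(d) > 0)
  })
  list(grid = g, adj26 = adj26, adj6 = adj6, adj18 = dist18,
       center = 14L, six_of_center = which(rowSums(abs(g)) == 1))
})

# Connected-component count over a subset of the 27 positions using the
# given adjacency lists (small BFS).
local_components <- function(present, adj, seeds = NULL) {
  nodes <- which(present)
  if (!length(nodes)) return(0L)
  if (!is.null(seeds)) {
    seeds <- intersect(seeds, nodes)
    if (!length(seeds)) return(0L)
  }
  seen <- logical(27)
  ncomp <- 0L
  start_set <- if (is.null(seeds)) nodes else seeds
  for (s in start_set) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[present[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}

# Is the centre voxel of a 3x3x3 foreground patch a simple point (its
# removal preserves local topology)? Standard characterization: exactly one
# 26-connected foreground component in N26, and exactly one 6-connected
# background component in N18 that touches the centre's 6-neighbours.
is_simple_point <- function(patch) {
  fg <- patch
  fg[N27$center] <- FALSE
  if (local_components(fg, N27$adj26) != 1L) return(FALSE)
  bg <- !patch
  bg[N27$center] <- FALSE
  # restrict to the 18-neighbourhood for the background condition
  in18 <- logical(27)
  in18[c(N27$adj18[[N27$center]])] <- TRUE
  bg18 <- bg & in18
  local_components(bg18, lapply(N27$adj6, function(a) a),
                   seeds = N27$six_of_center) == 1L
}

#' Topology-preserving 3D skeleton by sequential thinning
#'
#' Iteratively deletes simple border points (six directional sub-passes per
#' iteration, in a fixed deterministic order), never deleting endpoints
#' (voxels with at most one foreground 26-neighbour), until stable. The
#' result is a unit-width centerline preserving the mask's connectivity and
#' holes.
#'
#' @param mask logical array (2D accepted; treated as one slice).
#' @return logical array of the same dim: the skeleton.
#' @export
skeletonize3d <- function(mask) {
  m <- as_vol3d(mask)
  d <- dim(m)
  # pad so every voxel has a full 3x3x3 neighbourhood
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0),
                c(0, -1, 0), c(1, 0, 0), c(-1, 0, 0))
  repeat {
    removed_any <- FALSE
    for (dd in seq_len(nrow(dirs))) {
      idx <- which(p)
      if (!length(idx)) break
      co <- arrayInd(idx, dim(p))
      nb <- co + matrix(dirs[dd, ], nrow(co), 3, byrow = TRUE)
      border <- !p[nb]
      cand <- idx[border]
      cand_co <- co[border, , drop = FALSE]
      if (!length(cand)) next
      for (i in seq_along(cand)) {
        cc <- cand_co[i, ]
        patch <- p[(cc[1] - 1):(cc[1] + 1),
                   (cc[2] - 1):(cc[2] + 1),
                   (cc[3] - 1):(cc[3] + 1)]
        if (!patch[N27$center]) next
        nfg <- sum(patch) - 1
        if (nfg <= 1) next          # endpoint: keep
        if (is_simple_point(as.logical(patch))) {
          p[cc[1], cc[2], cc[3]] <- FALSE
          removed_any <- TRUE
        }
      }
    }
    if (!removed_any) break
  }
  out <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  dim(out) <- d
  if (length(dim(mask)) == 2) dim(out) <- dim(mask)
  out
}

#' Mitochondrial elongation features
#'
#' Skeletonizes the mask, measures total skeleton length as the weight of a
#' minimum spanning forest over skeleton voxels (edges between 26-neighbour
#' voxels, weighted by anisotropic centre-to-centre distance), counts branch
#' points (skeleton voxels with >= 3 skeleton 26-neighbours), and counts
#' 26-connected components of the original mask.
#'
#' @param mask logical array.
#' @param voxel_dims numeric c(dx, dy, dz), um.
#' @return list(skeleton_total_length, n_branches, n_components).
#' @export
elongation_features <- function(mask, voxel_dims) {
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  m <- as_vol3d(mask)
  if (!any(m)) {
    return(list(skeleton_total_length = 0, n_branches = 0L, n_components = 0L))
  }
  ncomp <- max(as_vol3d(label3d(m)))
  sk <- as_vol3d(skeletonize3d(m))
  d <- dim(sk)
  idx <- which(sk)
  if (length(idx) <= 1) {
    return(list(skeleton_total_length = 0, n_branches = 0L,
                n_components = as.integer(ncomp)))
  }
  co <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  fwd <- NEIGH26[NEIGH26[, 3] > 0 |
                 (NEIGH26[, 3] == 0 & (NEIGH26[, 2] > 0 |
                  (NEIGH26[, 2] == 0 & NEIGH26[, 1] > 0))), , drop = FALSE]
  edges <- NULL
  wts <- NULL
  deg <- integer(length(idx))
  for (k in seq_len(nrow(fwd))) {
    nx <- co[, 1] + fwd[k, 1]
    ny <- co[, 2] + fwd[k, 2]
    nz <- co[, 3] + fwd[k, 3]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    nid <- integer(length(idx))
    nid[ok] <- id_of[cbind(nx[ok], ny[ok], nz[ok])]
    hit <- which(nid > 0)
    if (!length(hit)) next
    deg[hit] <- deg[hit] + 1L
    deg[nid[hit]] <- deg[nid[hit]] + 1L
    w <- sqrt(sum((fwd[k, ] * voxel_dims)^2))
    edges <- rbind(edges, cbind(hit, nid[hit]))
    wts <- c(wts, rep(w, length(hit)))
  }
  if (is.null(edges)) {
    return(list(skeleton_total_length = 0, n_branches = 0L,
                n_components = as.integer(ncomp)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, t(edges), weight = wts)
  forest <- igraph::mst(g, weights = igraph::E(g)$weight)
  list(skeleton_total_length = sum(igraph::E(forest)$weight),
       n_branches = as.integer(sum(deg >= 3)),
       n_components = as.integer(ncomp))
}

#' Compare groups of per-cell measurements
#'
#' Two groups: Welch's t-test. More than two: one-way ANOVA with Tukey HSD
#' pairwise adjusted p-values. Delegates to \code{\link{welch_t}} and
#' \code{\link{anova_tukey}}.
#'
#' @param groups named list of numeric vectors (one per group).
#' @return for two groups, the \code{\link{welch_t}} result; otherwise the
#'   \code{\link{anova_tukey}} result.
#' @export
compare_populations <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (length(groups) == 2) {
    welch_t(groups[[1]], groups[[2]],
            names = names(groups) %||% c("group1", "group2"))
  } else {
    anova_tukey(groups)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
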