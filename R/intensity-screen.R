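#' Per-cell mean GFP intensity
#'
#' Projects the GFP z-stack (maximum, sum, or mean over z) and averages the
#' projected pixel values over each labeled cell region; background
#' (label 0) is excluded. This is the screen's per-cell abundance measure
#' (mean grey value per cell), which is insensitive to cell-size differences
#' between genotypes.
#'
#' @param gfp_volume numeric array c(nx, ny, nz) (or a 2D matrix, used
#'   as-is).
#' @param labels integer label map: either 2D c(nx, ny) or a 3D label volume
#'   (projected to 2D by taking each pixel's maximum label over z).
#' @param projection one of "max", "sum", "mean".
#' @return named numeric vector of mean intensities, names = cell labels.
#' @export
mean_intensity_per_cell <- function(gfp_volume, labels,
                                    projection = c("max", "sum", "mean")) {
  projection <- match.arg(projection)
  proj <- project_z(gfp_volume, projection)
  lab2d <- if (length(dim(labels)) == 3) project_z(labels, "max") else labels
  if (!all(dim(proj) == dim(lab2d))) {
    stop("label map and GFP volume have mismatched x-y shapes")
  }
  keep <- lab2d > 0
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  means <- tapply(proj[keep], lab2d[keep], mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Project a z-stack to 2D
#' @param vol 3D array or 2D matrix.
#' @param projection "max", "sum" or "mean".
#' @return 2D matrix.
#' @export
project_z <- function(vol, projection = c("max", "sum", "mean")) {
  projection <- match.arg(projection)
  if (is.null(dim(vol)) || length(dim(vol)) == 2) return(vol)
  d <- dim(vol)
  m <- matrix(vol, d[1] * d[2], d[3])
  out <- switch(projection,
                max = do.call(pmax, as.data.frame(m)),
                sum = rowSums(m),
                mean = rowMeans(m))
  matrix(out, d[1], d[2])
}

#' Paired mutant/WT fold change of mean cell intensity
#'
#' The average of per-cell mean intensities over mutant cells divided by the
#' same average over paired wild-type cells. With multiple fields per
#' genotype, supply lists of per-field vectors: fields are paired in order
#' (1 with 1, 2 with 2, ...) and the per-pair ratios averaged.
#'
#' @param per_cell_mut,per_cell_wt numeric vectors of per-cell means, or
#'   lists of such vectors (one per field).
#' @param min_cells minimum cells required on each side of a pair; pairs
#'   with fewer are low-coverage and yield NA with a warning.
#' @return fold change (scalar), NA if no pair had coverage.
#' @export
field_fold_change <- function(per_cell_mut, per_cell_wt, min_cells = 35) {
  if (!is.list(per_cell_mut)) per_cell_mut <- list(per_cell_mut)
  if (!is.list(per_cell_wt)) per_cell_wt <- list(per_cell_wt)
  if (length(per_cell_mut) != length(per_cell_wt)) {
    stop("mutant and WT must have the same number of fields")
  }
  ratios <- vapply(seq_along(per_cell_mut), function(k) {
    m <- per_cell_mut[[k]]
    w <- per_cell_wt[[k]]
    if (length(m) < min_cells || length(w) < min_cells) {
      warning(sprintf("field pair %d low-coverage (%d mutant, %d WT cells < %d)",
                      k, length(m), length(w), min_cells))
      return(NA_real_)
    }
    mw <- mean(w)
    if (mw == 0) stop("WT mean intensity is zero; fold change undefined")
    mean(m) / mw
  }, numeric(1))
  if (all(is.na(ratios))) return(NA_real_)
  mean(ratios, na.rm = TRUE)
}

#' Rank genes and call primary hits
#'
#' Sorts genes by fold change (descending, ties broken by gene name
#' ascending) and flags primary hits with strict cut-offs: fold > up_cut is
#' an "up" hit, fold < down_cut a "down" hit; boundary values are not hits.
#'
#' @param fold_changes named numeric vector (names = genes) of positive,
#'   finite mutant/WT fold changes.
#' @param up_cut,down_cut hit cut-offs (defaults 1.3 and 0.7).
#' @return a \code{screen_result} data.frame with columns gene,
#'   fold_change, rank, primary_hit, direction.
#' @examples
#' rank_and_call(c(GSY2 = 1.65, ACO2 = 0.51, YFG1 = 1.02))
#' @export
rank_and_call <- function(fold_changes, up_cut = 1.3, down_cut = 0.7) {
  stopifnot(!is.null(names(fold_changes)), all(nzchar(names(fold_changes))))
  fc <- fold_changes[!is.na(fold_changes)]
  if (!all(is.finite(fc) & fc > 0)) {
    stop("fold changes must be finite and positive")
  }
  ord <- order(-fc, names(fc), method = "radix")
  fc <- fc[ord]
  res <- data.frame(
    gene = names(fc),
    fold_change = as.numeric(fc),
    rank = seq_along(fc),
    primary_hit = fc > up_cut | fc < down_cut,
    direction = ifelse(fc > up_cut, "up", ifelse(fc < down_cut, "down", "none")),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("screen_result", "data.frame")
  res
}

#' Confirm primary hits against a second round
#'
#' A hit is confirmed when it is a primary hit in round 1 and is again a hit
#' with the same direction in round 2. Genes missing from round 2 get
#' \code{confirmed = NA} with a warning.
#'
#' @param primary,second_round \code{screen_result} objects from
#'   \code{\link{rank_and_call}}.
#' @return \code{primary} with a logical \code{confirmed} column.
#' @export
confirm_hits <- function(primary, second_round) {
  stopifnot(inherits(primary, "data.frame"), inherits(second_round, "data.frame"))
  idx <- match(primary$gene, second_round$gene)
  confirmed <- rep(NA, nrow(primary))
  have <- !is.na(idx)
  confirmed[have] <- primary$primary_hit[have] &
    second_round$primary_hit[idx[have]] &
    primary$direction[have] == second_round$direction[idx[have]]
  missing_hits <- primary$primary_hit & !have
  if (any(missing_hits)) {
    warning(sprintf("%d primary hits missing from the second round: %s",
                    sum(missing_hits),
                    paste(utils::head(primary$gene[missing_hits], 5), collapse = ", ")))
  }
  confirmed[!primary$primary_hit & !is.na(confirmed)] <- FALSE
  primary$confirmed <- confirmed
  primary
}
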