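#' Acquisition settings used for localization profiling
#'
#' The default lateral calibration (0.1038 um/px, so a 60-sample line spans
#' 6.23 um) with a light 7-slice stack; fine enough to resolve nuclei,
#' puncta and peripheral shells.
#'
#' @param ... overrides forwarded to \code{\link{acquisition_spec}}.
#' @return an \code{acquisition_spec}.
#' @export
loc_acquisition_spec <- function(...) {
  args <- list(pixel_size_xy = 0.1038, z_step = 0.5, n_slices = 7L,
               frame_shape = c(304L, 304L))
  args[names(list(...))] <- list(...)
  do.call(acquisition_spec, args)
}

#' Simulate one cell population and extract localization features
#'
#' Renders a field of cells of one localization class (or a mix) and
#' measures per-cell localization features and mean GFP intensities against
#' the ground-truth labels.
#'
#' @param class localization class, recycled over cells (a vector gives a
#'   mixed population).
#' @param n number of cells.
#' @param spec an \code{acquisition_spec}.
#' @param seed integer seed.
#' @param intensity_scale per-cell intensity multiplier (recycled).
#' @param skeleton compute skeleton features (default TRUE).
#' @param ... extra \code{\link{cell_spec}} arguments (tubule geometry
#'   etc.).
#' @return list: \code{fg} (the \code{generate_field} result),
#'   \code{features} (\code{\link{localization_features}} data.frame),
#'   \code{mean_intensity} (per-cell mean GFP over the max projection).
#' @export
simulate_population <- function(class, n, spec = loc_acquisition_spec(),
                                seed = 1L, intensity_scale = 1,
                                skeleton = TRUE, ...) {
  cells <- layout_cells(n, spec, class = class,
                        intensity_scale = intensity_scale,
                        seed = seed, ...)
  fg <- generate_field(spec, cells, seed = child_seed(seed, 1),
                       channels = "gfp")
  feats <- localization_features(fg$field$channels$gfp,
                                 fg$truth$cell_label_volume,
                                 fg$truth$nucleus_label_volume,
                                 spec, skeleton = skeleton)
  mi <- mean_intensity_per_cell(fg$field$channels$gfp,
                                fg$truth$cell_label_volume, "max")
  list(fg = fg, features = feats, mean_intensity = mi)
}

LOCALIZATION_CATEGORIES <- c("increased abundance", "cytoplasm to punctate",
                             "nucleus to cytoplasm", "cytoplasm to nucleus",
                             "cell periphery to cytoplasm",
                             "mitochondrial elongation")

# generator configuration for each benchmark category: WT and mutant class
# plus intensity fold and tubule geometry
benchmark_plan <- function() {
  list(
    "increased abundance" =
      list(wt = list(class = "cytoplasmic"),
           mut = list(class = "cytoplasmic", scale = 1.65)),
    "cytoplasm to punctate" =
      list(wt = list(class = "cytoplasmic"),
           mut = list(class = "punctate", scale = 1.65)),
    "nucleus to cytoplasm" =
      list(wt = list(class = "nuclear"),
           mut = list(class = "cytoplasmic")),
    "cytoplasm to nucleus" =
      list(wt = list(class = "cytoplasmic"),
           mut = list(class = "nuclear")),
    "cell periphery to cytoplasm" =
      list(wt = list(class = "periphery"),
           mut = list(class = "cytoplasmic")),
    "mitochondrial elongation" =
      list(wt = list(class = "mitochondrial", tubule_n = 3L,
                     tubule_length = 1.2),
           mut = list(class = "mitochondrial", tubule_n = 4L,
                      tubule_length = 5.0))
  )
}

#' Run the six-category localization-change benchmark
#'
#' For each change category, simulates a paired WT/mutant gene set with the
#' corresponding generator configuration (class switch, abundance fold, or
#' tubule elongation), extracts features, measures the intensity fold
#' change, and classifies the pair with \code{\link{classify_change}}.
#'
#' @param seed master seed.
#' @param cells_per_population cells per genotype (default 30).
#' @param spec an \code{acquisition_spec}.
#' @param config classifier thresholds (\code{\link{classify_config}}).
#' @return data.frame: category (generated), predicted, correct,
#'   fold_change.
#' @export
run_localization_benchmark <- function(seed = 1L, cells_per_population = 30L,
                                       spec = loc_acquisition_spec(),
                                       config = classify_config()) {
  plan <- benchmark_plan()
  rows <- lapply(seq_along(plan), function(i) {
    cat_name <- names(plan)[i]
    cfg <- plan[[i]]
    sim_side <- function(side, k) {
      args <- cfg[[side]]
      scale <- args$scale %||% 1
      extra <- args[setdiff(names(args), c("class", "scale"))]
      do.call(simulate_population,
              c(list(class = args$class, n = cells_per_population,
                     spec = spec, seed = child_seed(seed, 10 * i + k),
                     intensity_scale = scale),
                extra))
    }
    wt <- sim_side("wt", 1)
    mut <- sim_side("mut", 2)
    fold <- mean(mut$mean_intensity) / mean(wt$mean_intensity)
    pred <- classify_change(summarize_features(wt$features),
                            summarize_features(mut$features),
                            fold, config)
    data.frame(category = cat_name, predicted = pred,
               correct = pred == cat_name, fold_change = fold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent-nuclear recovery experiment
#'
#' Simulates replicates of a population with a known nuclear-class
#' fraction and recovers the percentage of nuclear-enriched cells from the
#' rendered images.
#'
#' @param nuclear_fraction true fraction of nuclear-class cells.
#' @param cells_per_replicate cells per replicate.
#' @param n_replicates number of replicates.
#' @param spec an \code{acquisition_spec}.
#' @param seed master seed.
#' @param ratio_cut nuclear/cytoplasmic ratio cut-off.
#' @return data.frame from \code{\link{percent_nuclear}} plus the true
#'   percentage as attribute \code{"true_percent"}.
#' @export
run_percent_nuclear <- function(nuclear_fraction = 0.8,
                                cells_per_replicate = 50L,
                                n_replicates = 3L,
                                spec = loc_acquisition_spec(
                                  frame_shape = c(400L, 400L)),
                                seed = 1L, ratio_cut = 1.5) {
  feats <- lapply(seq_len(n_replicates), function(r) {
    n_nuc <- round(nuclear_fraction * cells_per_replicate)
    classes <- with_seed(child_seed(seed, 100 + r),
                         sample(rep(c("nuclear", "cytoplasmic"),
                                    c(n_nuc, cells_per_replicate - n_nuc))))
    pop <- simulate_population(classes, cells_per_replicate, spec,
                               seed = child_seed(seed, r), skeleton = FALSE)
    cbind(pop$features, replicate = r)
  })
  feats <- do.call(rbind, feats)
  out <- percent_nuclear(feats, replicate = feats$replicate,
                         ratio_cut = ratio_cut,
                         min_cells = cells_per_replicate)
  attr(out, "true_percent") <- 100 * nuclear_fraction
  out
}
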