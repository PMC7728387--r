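#' Acquisition settings used for whole-screen simulations
#'
#' A coarser calibration than the single-field default so that a several
#' hundred gene paired screen renders in minutes: 0.25 um/px, 3 z slices of
#' 1 um, and a 38 x 38 um frame that holds 35+ non-overlapping cells.
#'
#' @param ... overrides forwarded to \code{\link{acquisition_spec}}.
#' @return an \code{acquisition_spec}.
#' @export
screen_acquisition_spec <- function(...) {
  args <- list(pixel_size_xy = 0.25, z_step = 1.0, n_slices = 3L,
               frame_shape = c(152L, 152L))
  args[names(list(...))] <- list(...)
  do.call(acquisition_spec, args)
}

#' Define the injected effects of a simulated screen
#'
#' @param gene character gene names (unique).
#' @param fold mutant/WT intensity fold factors (> 0).
#' @param class_wt,class_mut localization classes in the two genotypes.
#' @return data.frame hit plan for \code{\link{generate_screen_dataset}}.
#' @export
screen_hit_plan <- function(gene, fold,
                            class_wt = "cytoplasmic", class_mut = class_wt) {
  if (anyDuplicated(gene)) stop("duplicate gene names in hit plan")
  if (any(fold <= 0)) stop("fold factors must be positive")
  data.frame(gene = gene, fold = fold,
             class_wt = rep_len(class_wt, length(gene)),
             class_mut = rep_len(class_mut, length(gene)),
             stringsAsFactors = FALSE)
}

screen_gene_table <- function(n_genes, hit_plan) {
  if (is.null(hit_plan)) hit_plan <- screen_hit_plan(character(0), numeric(0))
  if (anyDuplicated(hit_plan$gene)) stop("duplicate gene names in hit plan")
  if (nrow(hit_plan) > n_genes) stop("hit plan has more genes than n_genes")
  n_null <- n_genes - nrow(hit_plan)
  null_genes <- setdiff(sprintf("gene%04d", seq_len(n_genes + nrow(hit_plan))),
                        hit_plan$gene)[seq_len(n_null)]
  rbind(hit_plan,
        data.frame(gene = null_genes, fold = 1,
                   class_wt = "cytoplasmic", class_mut = "cytoplasmic",
                   stringsAsFactors = FALSE))
}

# Render the paired fields of one screen gene. Cell-to-cell expression
# heterogeneity is log-normal (sdlog cell_cv); the mutant's per-cell
# intensity scale is multiplied by the injected fold and its diameter by
# mut_diameter_scale (enlarged mutant cells).
screen_gene_fields <- function(row, spec, gene_seed, cells_per_field,
                               n_fields, mut_diameter_scale, cell_cv,
                               channels = "gfp") {
  one_side <- function(genotype, class, scale_base, dscale, offset) {
    lapply(seq_len(n_fields), function(f) {
      fseed <- child_seed(gene_seed, offset + f)
      scales <- with_seed(child_seed(fseed, 1),
                          scale_base * stats::rlnorm(cells_per_field,
                                                     -cell_cv^2 / 2, cell_cv))
      cells <- layout_cells(cells_per_field, spec,
                            diameter_range = c(3.6, 4.4) * dscale,
                            class = class, intensity_scale = scales,
                            seed = child_seed(fseed, 2))
      generate_field(spec, cells, seed = child_seed(fseed, 3),
                     channels = channels, genotype = genotype,
                     gene = row$gene, field_index = f)
    })
  }
  list(wt = one_side("WT", row$class_wt, 1, 1, 0),
       mut = one_side("mut", row$class_mut, row$fold, mut_diameter_scale,
                      n_fields))
}

#' Generate a paired WT/mutant screen dataset
#'
#' Emulates a paired GFP-collection screen: for each gene, \code{n_fields}
#' fields per genotype are rendered; genes in the hit plan have their mutant
#' per-cell intensity distribution scaled by the planned fold and/or their
#' localization class switched, all other genes draw both genotypes from
#' identical distributions.
#'
#' @param n_genes total number of genes.
#' @param hit_plan data.frame from \code{\link{screen_hit_plan}} (or NULL
#'   for a null screen).
#' @param spec an \code{acquisition_spec}; see
#'   \code{\link{screen_acquisition_spec}}.
#' @param seed master integer seed.
#' @param cells_per_field cells rendered per field (default 35).
#' @param n_fields fields per genotype per gene (default 2).
#' @param mut_diameter_scale mutant cell diameter multiplier (default 1.26,
#'   i.e. roughly doubled volume).
#' @param cell_cv log-scale sd of cell-to-cell expression heterogeneity.
#' @param channels channels to render.
#' @return named list (per gene) of lists with elements \code{wt} and
#'   \code{mut}, each a list of \code{generate_field} results.
#' @export
generate_screen_dataset <- function(n_genes, hit_plan = NULL, spec, seed,
                                    cells_per_field = 35L, n_fields = 2L,
                                    mut_diameter_scale = 1.26,
                                    cell_cv = 0.15, channels = "gfp") {
  genes <- screen_gene_table(n_genes, hit_plan)
  out <- lapply(seq_len(nrow(genes)), function(g) {
    screen_gene_fields(genes[g, ], spec, child_seed(seed, g),
                       cells_per_field, n_fields, mut_diameter_scale,
                       cell_cv, channels)
  })
  names(out) <- genes$gene
  out
}

#' Run a paired intensity screen end to end
#'
#' Streams over genes: renders the paired fields, measures per-cell mean GFP
#' over the (ground-truth) cell labels, computes the per-gene paired fold
#' change, ranks and calls primary hits, then renders an independent second
#' round for the primary hits and confirms them. Images are discarded as
#' soon as each gene is measured, so screens of hundreds of genes run in
#' bounded memory.
#'
#' @inheritParams generate_screen_dataset
#' @param up_cut,down_cut hit cut-offs (see \code{\link{rank_and_call}}).
#' @param projection z projection for per-cell means.
#' @param min_cells minimum cells per field pair.
#' @param confirm run the second confirmation round (default TRUE).
#' @return a \code{screen_result} data.frame (see
#'   \code{\link{rank_and_call}}), with a \code{confirmed} column when
#'   \code{confirm} is TRUE and a \code{true_fold} column carrying the
#'   injected effect.
#' @export
run_screen <- function(n_genes, hit_plan = NULL, spec = screen_acquisition_spec(),
                       seed = 1L, cells_per_field = 35L, n_fields = 2L,
                       mut_diameter_scale = 1.26, cell_cv = 0.15,
                       up_cut = 1.3, down_cut = 0.7,
                       projection = "max", min_cells = 35L,
                       confirm = TRUE) {
  genes <- screen_gene_table(n_genes, hit_plan)
  measure_round <- function(rows, round_offset) {
    fc <- vapply(seq_len(nrow(rows)), function(g) {
      gseed <- child_seed(seed, round_offset + match(rows$gene[g], genes$gene))
      fg <- screen_gene_fields(rows[g, ], spec, gseed, cells_per_field,
                               n_fields, mut_diameter_scale, cell_cv)
      wt <- lapply(fg$wt, function(x)
        mean_intensity_per_cell(x$field$channels$gfp,
                                x$truth$cell_label_volume, projection))
      mut <- lapply(fg$mut, function(x)
        mean_intensity_per_cell(x$field$channels$gfp,
                                x$truth$cell_label_volume, projection))
      field_fold_change(mut, wt, min_cells = min_cells)
    }, numeric(1))
    stats::setNames(fc, rows$gene)
  }
  res <- rank_and_call(measure_round(genes, 0), up_cut, down_cut)
  if (confirm) {
    hits <- res$gene[res$primary_hit]
    if (length(hits)) {
      second <- rank_and_call(
        measure_round(genes[genes$gene %in% hits, , drop = FALSE],
                      1000000L),
        up_cut, down_cut)
      res <- confirm_hits(res, second)
      res$confirmed[is.na(res$confirmed)] <- FALSE
    } else {
      res$confirmed <- FALSE
    }
  }
  res$true_fold <- genes$fold[match(res$gene, genes$gene)]
  res
}
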