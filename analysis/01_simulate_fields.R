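#!/usr/bin/env Rscript
# Render one example multi-channel z-stack field with ground truth and
# write it to disk, as a miniature of the screen's acquisitions: a mixed
# population of cells covering all five localization classes.

library(phenoscope)
dir.create("results", showWarnings = FALSE)

spec <- loc_acquisition_spec(frame_shape = c(256L, 256L))
classes <- rep(c("cytoplasmic", "nuclear", "punctate", "mitochondrial",
                 "periphery"), each = 4)
cells <- layout_cells(length(classes), spec, class = classes, seed = 1)
fg <- generate_field(spec, cells, seed = 2)

# channel/label TIFFs are bulky; keep them in scratch/, tables in results/
write_field(fg, "scratch/example_field")
write.csv(fg$truth$cells, "results/example_field_truth.csv",
          row.names = FALSE)

cat(sprintf("Rendered a %d x %d x %d field with %d cells (5 classes).\n",
            spec$frame_shape[1], spec$frame_shape[2], spec$n_slices,
            length(cells)))
cat(sprintf("Mean true GFP per class:\n"))
print(aggregate(true_mean_gfp ~ class, fg$truth$cells, mean))
cat("Wrote channels + label volumes to scratch/example_field/\n")
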