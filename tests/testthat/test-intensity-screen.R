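test_that("per-cell means reproduce uniform values and scale linearly", {
  labels <- array(0L, c(20, 20, 3))
  labels[2:8, 2:8, ] <- 1L
  labels[12:18, 12:18, ] <- 2L
  gfp <- array(3.7, c(20, 20, 3))
  m <- mean_intensity_per_cell(gfp, labels, "max")
  expect_equal(unname(m), c(3.7, 3.7))
  gfp2 <- gfp
  gfp2[12:18, 12:18, ] <- 1.2
  m1 <- mean_intensity_per_cell(gfp2, labels, "mean")
  m2 <- mean_intensity_per_cell(2 * gfp2, labels, "mean")
  expect_equal(unname(m2), 2 * unname(m1))
  expect_error(mean_intensity_per_cell(gfp, labels[1:10, , ]), "mismatch")
})

test_that("per-cell mean estimates are unbiased against ground truth", {
  # single-slice stacks so the projected ROI mean equals the 3D cell mean
  spec <- acquisition_spec(pixel_size_xy = 0.25, z_step = 1, n_slices = 1,
                           frame_shape = c(152, 152))
  ratios <- unlist(lapply(1:3, function(k) {
    cells <- layout_cells(35, spec, seed = 40 + k)
    fg <- generate_field(spec, cells, seed = 50 + k, channels = "gfp")
    est <- mean_intensity_per_cell(fg$field$channels$gfp,
                                   fg$truth$cell_label_volume, "mean")
    est[as.character(fg$truth$cells$label)] / fg$truth$cells$true_mean_gfp
  }))
  expect_gte(length(ratios), 100)
  expect_equal(mean(ratios), 1, tolerance = 0.02)
})

test_that("paired fold change behaves as a ratio of population means", {
  a <- rep(c(1, 2, 3), 5)
  expect_equal(field_fold_change(a, a, min_cells = 10), 1)
  b <- a * 2.5
  f <- field_fold_change(b, a, min_cells = 10)
  expect_equal(field_fold_change(a, b, min_cells = 10), 1 / f)
  # scale invariance
  expect_equal(field_fold_change(b * 13, a * 13, min_cells = 10), f)
  expect_error(field_fold_change(b, a * 0, min_cells = 10), "zero")
  expect_warning(out <- field_fold_change(b[1:3], a, min_cells = 10),
                 "low-coverage")
  expect_true(is.na(out))
})

test_that("an injected 3.77-fold effect is estimated within 5%", {
  spec <- screen_acquisition_spec()
  hp <- screen_hit_plan("DUR12", 3.77)
  # equal cell sizes isolate the fold estimator from slab-dilution effects
  fg <- phenoscope:::screen_gene_fields(hp[1, ], spec, 61L, 35L, 2L, 1,
                                        0.15)
  per_cell <- function(side) lapply(side, function(x)
    mean_intensity_per_cell(x$field$channels$gfp,
                            x$truth$cell_label_volume, "mean"))
  f <- field_fold_change(per_cell(fg$mut), per_cell(fg$wt))
  expect_equal(f, 3.77, tolerance = 0.05)
})

test_that("ranking and hit calls use strict 1.3/0.7 cut-offs", {
  fc <- c(GSY2 = 1.65, ACO2 = 0.51, EXACT = 1.30, LOW = 0.70, MID = 1.02)
  res <- rank_and_call(fc)
  expect_equal(sort(res$rank), 1:5)
  expect_equal(res$gene[1], "GSY2")
  gy <- res[res$gene == "GSY2", ]
  expect_true(gy$primary_hit && gy$direction == "up")
  ac <- res[res$gene == "ACO2", ]
  expect_true(ac$primary_hit && ac$direction == "down")
  expect_false(res$primary_hit[res$gene == "EXACT"])
  expect_false(res$primary_hit[res$gene == "LOW"])
  # ties broken lexicographically
  res2 <- rank_and_call(c(B = 2, A = 2, C = 1))
  expect_equal(res2$gene, c("A", "B", "C"))
  expect_error(rank_and_call(c(A = -1)), "positive")
})

test_that("monotonicity: a larger injected fold never ranks worse", {
  fc <- c(A = 1.1, B = 1.4, C = 2.0, D = 0.9)
  r1 <- rank_and_call(fc)
  fc["B"] <- 2.5
  r2 <- rank_and_call(fc)
  expect_lte(r2$rank[r2$gene == "B"], r1$rank[r1$gene == "B"])
})

test_that("confirmation requires the same direction in both rounds", {
  r1 <- rank_and_call(c(A = 1.8, B = 1.5, C = 0.5, D = 1.0))
  r2 <- rank_and_call(c(A = 1.7, B = 1.1, C = 0.4, D = 1.0))
  out <- confirm_hits(r1, r2)
  expect_true(out$confirmed[out$gene == "A"])
  expect_false(out$confirmed[out$gene == "B"])   # hit up then fc 1.1
  expect_true(out$confirmed[out$gene == "C"])
  expect_false(out$confirmed[out$gene == "D"])
  # missing primary hit in round 2 warns and leaves NA
  expect_warning(out2 <- confirm_hits(r1, rank_and_call(c(B = 1.5, D = 1))),
                 "missing")
  expect_true(is.na(out2$confirmed[out2$gene == "A"]))
})

test_that("a null screen confirms essentially nothing", {
  res <- run_screen(120, NULL, seed = 71)
  expect_lte(sum(res$confirmed), 2)
  expect_equal(nrow(res), 120)
  expect_equal(sort(res$rank), 1:120)
})
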