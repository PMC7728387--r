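vox_default <- c(0.1038, 0.1038, 0.3)

test_that("voxel volume and surface area follow the counting rules", {
  m <- array(FALSE, c(20, 20, 10))
  m[1:10, 1:10, 1:10] <- TRUE   # 1000 voxels
  expect_equal(mito_volume(m, c(0.1, 0.1, 0.3)), 3.0)
  s <- array(FALSE, c(5, 5, 5))
  s[3, 3, 3] <- TRUE
  dx <- 0.1; dy <- 0.12; dz <- 0.3
  expect_equal(mito_surface_area(s, c(dx, dy, dz)),
               2 * dx * dy + 2 * dx * dz + 2 * dy * dz)
})

test_that("volume is additive over disjoint masks and tracks calibration", {
  set.seed(9)
  a <- array(runif(8000) > 0.7, c(20, 20, 20))
  b <- array(runif(8000) > 0.7, c(20, 20, 20))
  b[a] <- FALSE
  expect_equal(mito_volume(a | b, vox_default),
               mito_volume(a, vox_default) + mito_volume(b, vox_default))
  expect_equal(mito_volume(a, c(0.1038, 0.1038, 0.6)),
               2 * mito_volume(a, vox_default))
})

test_that("voxelized cylinders match the analytic volume within 10%", {
  spec <- acquisition_spec(frame_shape = c(128, 128), n_slices = 30)
  set.seed(17)
  for (r in c(0.25, 0.5)) for (L in c(2, 8)) {
    ctr <- c(6.6, 6.6, 4.5) + c(runif(2, -0.3, 0.3), runif(1, -0.15, 0.15))
    th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th), 0) * L / 2
    mk <- cylinder_mask(spec, ctr - u, ctr + u, r)
    expect_equal(mito_volume(mk, vox_default), pi * r^2 * L,
                 tolerance = 0.1)
  }
})

test_that("mito segmentation is exact without optics and empty on uniform input", {
  spec0 <- mito_acquisition_spec(psf_sigma_xy = 0, psf_sigma_z = 0,
                                 noise_read_sd = 0, photon_scale = 0,
                                 frame_shape = c(128L, 128L))
  cells <- layout_cells(4, spec0, class = "mitochondrial", seed = 7,
                        mito_volume_um3 = 1.8)
  fg <- generate_field(spec0, cells, seed = 8, channels = "gfp")
  for (i in fg$truth$cells$label) {
    gv <- crop_cell(fg$field$channels$gfp, fg$truth$cell_label_volume, i)
    mk <- segment_mito_voxels(gv, spec0)
    tm <- crop_cell(fg$truth$mito_label_volume, fg$truth$cell_label_volume,
                    i) == i
    expect_gte(dice_coef(mk, tm), 0.8)
    expect_identical(mk, segment_mito_voxels(gv, spec0))  # deterministic
  }
  expect_equal(sum(segment_mito_voxels(array(2.5, c(10, 10, 5)))), 0)
})

test_that("mito segmentation stays faithful under full optics after deconvolution", {
  spec <- mito_acquisition_spec(frame_shape = c(128L, 128L))
  cells <- layout_cells(4, spec, class = "mitochondrial", seed = 7,
                        mito_volume_um3 = 1.8)
  fg <- generate_field(spec, cells, seed = 8, channels = "gfp")
  dice <- vapply(fg$truth$cells$label, function(i) {
    gv <- crop_cell(fg$field$channels$gfp, fg$truth$cell_label_volume, i)
    mk <- segment_mito_voxels(deconvolve_rl(gv, spec), spec)
    tm <- crop_cell(fg$truth$mito_label_volume, fg$truth$cell_label_volume,
                    i) == i
    dice_coef(mk, tm)
  }, numeric(1))
  expect_gte(min(dice), 0.6)
})

test_that("skeleton features recover a straight cylinder's geometry", {
  spec <- mito_acquisition_spec(frame_shape = c(96L, 96L))
  vox <- c(0.15, 0.15, 0.3)
  mk <- cylinder_mask(spec, c(2, 7.2, 2.4), c(7, 7.2, 2.4), 0.25)
  ef <- elongation_features(mk, vox)
  expect_equal(ef$skeleton_total_length, 5, tolerance = 0.1)
  expect_equal(ef$n_branches, 0)
  expect_equal(ef$n_components, 1)
  e0 <- elongation_features(array(FALSE, c(5, 5, 5)), vox)
  expect_equal(unlist(e0), c(skeleton_total_length = 0, n_branches = 0,
                             n_components = 0))
})

test_that("fragmented networks have more components at equal volume", {
  spec <- mito_acquisition_spec()
  vox <- c(0.15, 0.15, 0.3)
  frag <- layout_cells(6, spec, class = "mitochondrial", seed = 9,
                       mito_volume_um3 = 1.5, tubule_length = 0.6)
  fus <- layout_cells(6, spec, class = "mitochondrial", seed = 9,
                      mito_volume_um3 = 1.5, tubule_length = 4)
  f1 <- generate_field(spec, frag, seed = 10, channels = "gfp")
  f2 <- generate_field(spec, fus, seed = 10, channels = "gfp")
  ncomp <- function(fg) vapply(fg$truth$cells$label, function(i) {
    tm <- crop_cell(fg$truth$mito_label_volume, fg$truth$cell_label_volume,
                    i) == i
    elongation_features(tm, vox)$n_components
  }, integer(1))
  expect_gt(mean(ncomp(f1)), mean(ncomp(f2)))
  expect_equal(mean(f1$truth$cells$true_mito_volume),
               mean(f2$truth$cells$true_mito_volume), tolerance = 0.1)
})

test_that("mitochondrial fractions divide by the strain mean cell volume", {
  fr <- mitochondrial_fraction(rep(3, 60), rep(30, 60))
  expect_equal(fr$mean, 0.1)
  expect_false(fr$flagged)
  fr0 <- mitochondrial_fraction(rep(0, 60), rep(30, 60))
  expect_true(all(fr0$fractions == 0))
  expect_warning(frs <- mitochondrial_fraction(1:10, rep(30, 10)),
                 "flagged")
  expect_true(frs$flagged)
  # per-cell mode divides elementwise
  frp <- mitochondrial_fraction(c(3, 6), c(30, 30), per_cell = TRUE,
                                min_cells = 2)
  expect_equal(frp$fractions, c(0.1, 0.2))
})

test_that("population comparisons dispatch to Welch t and ANOVA + Tukey", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  two <- compare_populations(g)
  expect_equal(two$statistic, 0)
  expect_equal(two$p_value, 1)
  set.seed(5)
  big <- list(a = rnorm(50), b = rnorm(50, 5))
  expect_lt(compare_populations(big)$p_value, 1e-6)
  three <- compare_populations(list(a = rnorm(10), b = rnorm(10),
                                    c = rnorm(10)))
  expect_true(all(c("F", "p_value", "tukey") %in% names(three)))
  expect_equal(nrow(three$tukey), 3)
  expect_error(compare_populations(list(a = 1, b = c(1, 2))), "'a'")
  expect_error(compare_populations(list(a = c(2, 2), b = c(1, 2))), "'a'")
})
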