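test_that("a zero-intensity cell renders an identically zero GFP channel", {
  spec <- clean_spec()
  fg <- generate_field(spec, list(cell_spec(c(3.3, 3.3, 4.5), 4,
                                            intensity_scale = 0)),
                       seed = 1, channels = "gfp")
  expect_true(all(fg$field$channels$gfp == 0))
})

test_that("voxelized cell volume matches the sphere closed form", {
  spec <- clean_spec()
  fg <- generate_field(spec, list(cell_spec(c(3.3, 3.3, 4.5), 4)), seed = 1,
                       channels = "gfp")
  v_true <- 4 / 3 * pi * 2^3
  # within one voxel shell of the analytic volume, and exactly equal to
  # voxel count x voxel volume
  shell <- 4 * pi * 2^2 * spec$z_step
  expect_lt(abs(fg$truth$cells$true_cell_volume - v_true), shell)
  voxvol <- spec$pixel_size_xy^2 * spec$z_step
  expect_equal(fg$truth$cells$true_cell_volume,
               sum(fg$truth$cell_label_volume == 1) * voxvol)
})

test_that("identical spec, cells and seed give bit-identical fields", {
  spec <- tiny_spec(nz = 5)
  cells <- list(cell_spec(c(3.3, 3.3, 0.75), 4, "punctate"))
  fg1 <- generate_field(spec, cells, seed = 42)
  fg2 <- generate_field(spec, cells, seed = 42)
  expect_identical(fg1, fg2)
  fg3 <- generate_field(spec, cells, seed = 43)
  expect_false(identical(fg1$field$channels$gfp, fg3$field$channels$gfp))
})

test_that("PSF convolution conserves total intensity for interior cells", {
  base <- list(frame_shape = c(64L, 64L), n_slices = 30L,
               noise_read_sd = 0, photon_scale = 0)
  cells <- list(cell_spec(c(3.3, 3.3, 4.5), 4))
  off <- generate_field(do.call(acquisition_spec,
                                c(base, psf_sigma_xy = 0, psf_sigma_z = 0)),
                        cells, seed = 1, channels = "gfp")
  on <- generate_field(do.call(acquisition_spec, base), cells, seed = 1,
                       channels = "gfp")
  s0 <- sum(off$field$channels$gfp)
  s1 <- sum(on$field$channels$gfp)
  expect_lt(abs(s1 - s0) / s0, 0.005)
})

test_that("nuclear and cytoplasmic classes are separable without noise", {
  spec <- clean_spec()
  for (cls in c("nuclear", "cytoplasmic")) {
    fg <- generate_field(spec, list(cell_spec(c(3.3, 3.3, 4.5), 4, cls)),
                         seed = 3, channels = "gfp")
    gfp <- fg$field$channels$gfp
    nuc <- fg$truth$nucleus_label_volume == 1
    cyt <- fg$truth$cell_label_volume == 1 & !nuc
    ratio <- mean(gfp[nuc]) / mean(gfp[cyt])
    if (cls == "nuclear") expect_gt(ratio, 2)
    else expect_true(ratio >= 0.8 && ratio <= 1.2)
  }
})

test_that("cells that overlap or leave the frame are rejected", {
  spec <- tiny_spec(nz = 5)
  expect_error(
    generate_field(spec, list(cell_spec(c(3, 3, 0.75), 4),
                              cell_spec(c(4, 3, 0.75), 4)), seed = 1),
    "overlap")
  expect_error(
    generate_field(spec, list(cell_spec(c(1, 3, 0.75), 4)), seed = 1),
    "frame too small")
})

test_that("targeted mitochondrial volume is realized in the ground truth", {
  spec <- mito_acquisition_spec(frame_shape = c(96L, 96L))
  cells <- layout_cells(4, spec, class = "mitochondrial", seed = 5,
                        mito_volume_um3 = c(1, 2, 4, 6))
  fg <- generate_field(spec, cells, seed = 6, channels = "gfp")
  expect_equal(fg$truth$cells$true_mito_volume, c(1, 2, 4, 6),
               tolerance = 0.08)
  # mitochondria stay out of the nucleus
  expect_equal(sum(fg$truth$mito_label_volume > 0 &
                   fg$truth$nucleus_label_volume > 0), 0)
})

test_that("screen dataset injects intensity folds into the ground truth", {
  spec <- screen_acquisition_spec()
  hp <- screen_hit_plan("G1", 1.65)
  ds <- generate_screen_dataset(3, hp, spec, seed = 7, cells_per_field = 12L)
  expect_length(ds, 3)
  expect_true("G1" %in% names(ds))
  null_gene <- setdiff(names(ds), "G1")[1]
  tm <- function(side) mean(unlist(lapply(side, function(x)
    x$truth$cells$true_mean_gfp)))
  expect_equal(tm(ds$G1$mut) / tm(ds$G1$wt), 1.65, tolerance = 0.08)
  expect_equal(tm(ds[[null_gene]]$mut) / tm(ds[[null_gene]]$wt), 1,
               tolerance = 0.08)
  expect_error(
    generate_screen_dataset(3, screen_hit_plan(c("A", "A"), c(1, 2)),
                            spec, seed = 1),
    "duplicate")
})

test_that("growth curves double on schedule and stay monotone", {
  gc <- generate_growth_curve(0.1, 1.5, carrying_capacity = 1000,
                              duration_h = 8, noise_sd = 0)
  expect_equal(gc$od600[gc$time_h == 1.5], 0.2, tolerance = 1e-3)
  expect_true(all(diff(gc$od600) >= 0))
  expect_error(generate_growth_curve(-0.1, 1.5), "positive")
  expect_error(generate_growth_curve(0.1, 0), "positive")
})

test_that("doubling time is recovered from noiseless logistic output", {
  gc <- generate_growth_curve(0.05, 2.0, carrying_capacity = 100,
                              duration_h = 10, noise_sd = 0)
  expect_equal(doubling_time(gc$time_h, gc$od600), 2.0, tolerance = 0.01)
})
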