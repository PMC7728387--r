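test_that("sphere-approximated cell volume follows the closed form exactly", {
  expect_equal(estimate_cell_volume(4, 4), 4 / 3 * pi * 2^3)
  expect_equal(estimate_cell_volume(4, 4), 33.510, tolerance = 1e-4)
  expect_equal(estimate_cell_volume(3, 5), estimate_cell_volume(4, 4))
  expect_equal(estimate_cell_volume(2, 2), 4.18879, tolerance = 1e-5)
  expect_error(estimate_cell_volume(0, 4), "positive")
  expect_error(estimate_cell_volume(3, -1), "positive")
})

seg_field <- function(n = 25, seed = 11, nx = 320) {
  spec <- acquisition_spec(frame_shape = c(nx, nx), n_slices = 3,
                           z_step = 0.6)
  cells <- layout_cells(n, spec, seed = seed)
  list(spec = spec,
       fg = generate_field(spec, cells, seed = seed + 1,
                           channels = c("gfp", "brightfield", "dapi")))
}

test_that("brightfield segmentation recovers non-touching cells", {
  sf <- seg_field()
  seg <- segment_cells(sf$fg$field$channels$brightfield, sf$spec)
  expect_equal(nrow(seg$cells), 25)
  m <- match_labels(sf$fg$truth$cell_label_volume, seg$labels)
  expect_gte(mean(m$iou >= 0.8), 0.95)
  # diameters close to truth
  idx <- match(m$matched_label, seg$cells$label)
  est_d <- (seg$cells$diameter_a_um[idx] + seg$cells$diameter_b_um[idx]) / 2
  expect_equal(mean(est_d / sf$fg$truth$cells$diameter_um), 1,
               tolerance = 0.05)
})

test_that("segmentation is deterministic and intensity-scale invariant", {
  sf <- seg_field(n = 8, nx = 192)
  bf <- sf$fg$field$channels$brightfield
  s1 <- segment_cells(bf, sf$spec)
  s2 <- segment_cells(bf, sf$spec)
  s3 <- segment_cells(bf * 7.3, sf$spec)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$labels, s3$labels)
})

test_that("a blank brightfield yields an empty cell table with a warning", {
  spec <- tiny_spec(nz = 3)
  expect_warning(seg <- segment_cells(array(0, c(64, 64, 3)), spec), "empty")
  expect_equal(nrow(seg$cells), 0)
})

test_that("population volume ratio of enlarged mutants is recovered", {
  sf_wt <- seg_field(n = 16, seed = 21, nx = 256)
  spec_mut <- acquisition_spec(frame_shape = c(320, 320), n_slices = 3,
                               z_step = 0.6)
  cells_mut <- layout_cells(16, spec_mut, diameter_range = c(3.6, 4.4) * 2^(1 / 3),
                            seed = 22)
  fg_mut <- generate_field(spec_mut, cells_mut, seed = 23,
                           channels = "brightfield")
  v_wt <- segment_cells(sf_wt$fg$field$channels$brightfield, sf_wt$spec)
  v_mut <- segment_cells(fg_mut$field$channels$brightfield, spec_mut)
  ratio <- mean(v_mut$cells$cell_volume_um3) / mean(v_wt$cells$cell_volume_um3)
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("nucleus detection finds DAPI blobs inside cells", {
  sf <- seg_field(n = 20, seed = 31)
  nuc <- detect_nuclei(sf$fg$field$channels$dapi,
                       sf$fg$truth$cell_label_volume)
  expect_true(all(nuc$has_nucleus))
  tr <- sf$fg$truth$cells
  d <- sqrt((nuc$nucleus_x_px - tr$centroid_x_px)^2 +
            (nuc$nucleus_y_px - tr$centroid_y_px)^2)
  expect_gte(mean(d <= 3), 0.95)
})

test_that("nucleus detection flags absent nuclei and breaks ties low", {
  labels <- matrix(0L, 40, 40)
  labels[5:35, 5:35] <- 1L
  expect_error(detect_nuclei(NULL, labels), "missing")
  nuc0 <- detect_nuclei(matrix(0, 40, 40), labels)
  expect_false(any(nuc0$has_nucleus))
  # two blobs in one cell: the larger wins
  dapi <- matrix(0, 40, 40)
  dapi[8:10, 8:10] <- 1     # 9 px blob
  dapi[20:25, 20:25] <- 1   # 36 px blob
  nuc <- detect_nuclei(dapi, labels)
  expect_true(nuc$has_nucleus[1])
  expect_equal(nuc$nucleus_area_px[1], 36)
  expect_equal(round(nuc$nucleus_x_px[1]), 22)
})
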