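test_that("line profiles sample 60 bilinear values centered on the nucleus", {
  img <- matrix(4.2, 120, 120)
  lp <- line_profile(img, c(60, 60))
  expect_length(lp$values, 60)
  expect_true(all(lp$values == 4.2))
  expect_equal(lp$positions[31], 0)  # centre sample, 0-based index 30
  expect_error(line_profile(img, c(NA, 60)), "absent")
  # samples beyond the frame are NA
  lp_edge <- line_profile(img, c(5, 60))
  expect_true(any(is.na(lp_edge$values)))
})

noiseless_loc <- function(cls, seed = 5) {
  spec <- loc_acquisition_spec(noise_read_sd = 0, photon_scale = 0,
                               frame_shape = c(96L, 96L))
  fg <- generate_field(spec, list(cell_spec(c(5, 5, 1.75), 4.2, cls)),
                       seed = seed, channels = "gfp")
  list(spec = spec, fg = fg,
       proj = project_z(fg$field$channels$gfp, "max"),
       ctr = c(fg$truth$cells$centroid_x_px, fg$truth$cells$centroid_y_px))
}

test_that("a nuclear cell's profile peaks at the centre and is symmetric", {
  nl <- noiseless_loc("nuclear")
  lp <- line_profile(nl$proj, nl$ctr)
  expect_equal(which.max(lp$values), 31)
  v <- lp$values
  # mirror pairs around the centre sample (1-based index 31)
  asym <- max(abs(v[31 + 1:29] - v[31 - 1:29]), na.rm = TRUE)
  expect_lt(asym, 0.05 * max(v, na.rm = TRUE))
})

test_that("profiles are rotation-consistent for radially symmetric cells", {
  nl <- noiseless_loc("nuclear")
  p0 <- line_profile(nl$proj, nl$ctr, angle = 0)
  p90 <- line_profile(nl$proj, nl$ctr, angle = pi / 2)
  expect_equal(p0$values, p90$values, tolerance = 0.03)
})

test_that("mean profiles weight replicates equally, not cells", {
  mk <- function(val, rep, n = 1) lapply(seq_len(n), function(i)
    structure(list(positions = -30:29, values = rep(val, 60),
                   cell_label = i, replicate = rep),
              class = "line_profile"))
  one <- mean_profile(mk(7, 1))
  expect_true(all(one$mean == 7))
  # replicate 1 has two cells at 10, replicate 2 one cell at 20
  mp <- mean_profile(c(mk(10, 1, 2), mk(20, 2, 1)))
  expect_true(all(mp$mean == 15))
  expect_error(mean_profile(list()), "empty")
})

test_that("dispersed populations lose the centre/edge profile contrast", {
  spec <- loc_acquisition_spec(frame_shape = c(160L, 160L))
  contrast <- function(cls, seed) {
    cells <- layout_cells(6, spec, class = cls, seed = seed)
    fg <- generate_field(spec, cells, seed = seed + 1, channels = "gfp")
    proj <- project_z(fg$field$channels$gfp, "max")
    tr <- fg$truth$cells
    lps <- lapply(seq_len(nrow(tr)), function(i)
      line_profile(proj, c(tr$centroid_x_px[i], tr$centroid_y_px[i]),
                   replicate = 1))
    mp <- mean_profile(lps)$mean
    mp[31] / mean(mp[c(4, 57)], na.rm = TRUE)
  }
  expect_gt(contrast("nuclear", 11), contrast("cytoplasmic", 12))
})

test_that("nuclear enrichment and percent nuclear follow the ratio cut", {
  f <- data.frame(nc_ratio = c(1.0, 2.1, 1.6, 0.8),
                  cytoplasmic_mean = c(1, 1, 1, 1))
  expect_equal(nuclear_enrichment(f), c(FALSE, TRUE, TRUE, FALSE))
  pn <- percent_nuclear(f, min_cells = 4)
  expect_equal(pn$percent, 50)
  fz <- data.frame(nc_ratio = c(2, Inf), cytoplasmic_mean = c(1, 0))
  expect_warning(flags <- nuclear_enrichment(fz), "zero cytoplasmic")
  expect_true(is.na(flags[2]))
})

test_that("percent nuclear is invariant to global intensity scaling", {
  spec <- loc_acquisition_spec(frame_shape = c(160L, 160L))
  cells <- layout_cells(9, spec, class = rep(c("nuclear", "cytoplasmic"),
                                             c(6, 3)), seed = 3)
  fg <- generate_field(spec, cells, seed = 4, channels = "gfp")
  feat <- function(k) localization_features(
    k * fg$field$channels$gfp, fg$truth$cell_label_volume,
    fg$truth$nucleus_label_volume, spec, skeleton = FALSE)
  p1 <- percent_nuclear(feat(1), min_cells = 9)
  p2 <- percent_nuclear(feat(5), min_cells = 9)
  expect_equal(p1$percent, p2$percent)
  expect_equal(p1$percent, 100 * 6 / 9, tolerance = 1e-6)
})

test_that("the change classifier applies its ordered rule list", {
  base <- list(nuclear_mean = 1, cytoplasmic_mean = 1, peripheral_mean = 0.7,
               nc_ratio = 1.0, n_puncta = 0, punctate_cv = 0.2,
               skeleton_length_um = 0, mito_likeness = 0, cell_area_um2 = 12)
  expect_equal(classify_change(base, base, 1.0), "no change")
  expect_equal(classify_change(base, base, 1.65), "increased abundance")
  expect_equal(classify_change(base, base, 0.51), "decreased abundance")
  pun <- modifyList(base, list(n_puncta = 4, punctate_cv = 0.6))
  expect_equal(classify_change(base, pun, 1.65), "cytoplasm to punctate")
  nuc <- modifyList(base, list(nc_ratio = 3))
  expect_equal(classify_change(nuc, base, 1.0), "nucleus to cytoplasm")
  expect_equal(classify_change(base, nuc, 1.0), "cytoplasm to nucleus")
  per <- modifyList(base, list(peripheral_mean = 2.0))
  expect_equal(classify_change(per, base, 1.0), "cell periphery to cytoplasm")
  mito_s <- modifyList(base, list(skeleton_length_um = 3))
  mito_l <- modifyList(base, list(skeleton_length_um = 9))
  expect_equal(classify_change(mito_s, mito_l, 1.3),
               "mitochondrial elongation")
})
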