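make_rois <- function(h, w) {
  iridoquant:::scene_rois(h, w)
}

test_that("peripheral calibration averages the two area-level ratios", {
  h <- 96; w <- 96
  rois <- make_rois(h, w)
  control <- matrix(50, h, w)
  control[rois$masks$peripheral_1] <- 20
  control[rois$masks$peripheral_2] <- 30
  sample <- matrix(50, h, w)
  sample[rois$masks$peripheral_1] <- 10
  sample[rois$masks$peripheral_2] <- 20
  cf <- peripheral_calibration(gray_image(sample, 16L),
                               gray_image(control, 16L), rois)
  expect_equal(cf$per_area_ratios, c(2, 1.5))
  expect_equal(cf$value, 1.75)
  # pooled-mean variant differs when areas are unequal in brightness
  cf2 <- peripheral_calibration(gray_image(sample, 16L),
                                gray_image(control, 16L), rois,
                                method = "ratio_of_means")
  expect_equal(cf2$value, (20 + 30) / (10 + 20))
})

test_that("calibration is 1 for identical images and inverse to global gain", {
  s <- quiet_scene()
  cf <- peripheral_calibration(s$control_transmitted, s$control_transmitted,
                               s$rois)
  expect_equal(cf$value, 1)
  brighter <- gray_image(s$control_transmitted$pixels * 1.2, 16L)
  cf2 <- peripheral_calibration(brighter, s$control_transmitted, s$rois)
  expect_equal(cf2$value, 1 / 1.2, tolerance = 1e-12)
  dark <- gray_image(matrix(0, 96, 96), 16L)
  expect_error(peripheral_calibration(dark, s$control_transmitted, s$rois),
               "degenerate")
})

test_that("transparency map implements 100 * sample/control * factor", {
  h <- 40; w <- 40
  control <- gray_image(matrix(200, h, w), 16L)
  expect_equal(transparency_map(control, control, 1)$values,
               matrix(100, h, w))
  half <- gray_image(matrix(100, h, w), 16L)
  expect_equal(transparency_map(half, control, 1)$values, matrix(50, h, w))
  expect_equal(transparency_map(half, control, 1.2)$values[1, 1], 60)
  expect_error(transparency_map(half, gray_image(matrix(0, h, w), 16L), 1),
               "entirely zero")
  expect_error(transparency_map(half, control, -1), "positive")
})

test_that("zero-control pixels are flagged undefined, not substituted", {
  control <- matrix(100, 10, 10); control[3, 4] <- 0
  tm <- transparency_map(gray_image(matrix(50, 10, 10), 16L),
                         gray_image(control, 16L), 1)
  expect_true(is.na(tm$values[3, 4]))
  expect_equal(sum(is.na(tm$values)), 1L)
  # and excluded from aggregation rather than biasing it
  rois <- roi_set(list(peripheral_1 = matrix(TRUE, 10, 10) & row(control) == 1,
                       peripheral_2 = matrix(TRUE, 10, 10) & row(control) == 2,
                       measurement = row(control) >= 3),
                  require_standard = TRUE)
  row <- summarize_region(tm, rois)
  expect_equal(row$value, 50)
})

test_that("optional clipping caps specular highlights at 100", {
  control <- gray_image(matrix(100, 5, 5), 16L)
  bright <- gray_image(matrix(150, 5, 5), 16L)
  expect_equal(transparency_map(bright, control, 1)$values[1, 1], 150)
  expect_equal(transparency_map(bright, control, 1, clip = TRUE)$values[1, 1],
               100)
})

test_that("calibration cancels global rescaling of either image", {
  s <- quiet_scene(transmittance = 0.6, seed = 5)
  base <- transparency_map(s$sample_transmitted, s$control_transmitted,
                           peripheral_calibration(s$sample_transmitted,
                                                  s$control_transmitted,
                                                  s$rois))
  for (c_fac in c(0.5, 1.25)) {
    scaled <- gray_image(s$sample_transmitted$pixels * c_fac, 16L)
    tm <- transparency_map(scaled, s$control_transmitted,
                           peripheral_calibration(scaled,
                                                  s$control_transmitted,
                                                  s$rois))
    expect_lt(max(abs(tm$values - base$values) / base$values), 1e-6)
    cscaled <- gray_image(s$control_transmitted$pixels * c_fac, 16L)
    tm2 <- transparency_map(s$sample_transmitted, cscaled,
                            peripheral_calibration(s$sample_transmitted,
                                                   cscaled, s$rois))
    expect_lt(max(abs(tm2$values - base$values) / base$values), 1e-6)
  }
})

test_that("region summaries use the configured statistic", {
  vals <- matrix(50, 8, 8)
  vals[1, 1:2] <- c(40, 60)
  tm <- structure(list(values = vals, factor = 1, clipped = FALSE),
                  class = "transparency_map")
  rois <- roi_set(list(measurement = matrix(TRUE, 8, 8)),
                  require_standard = FALSE)
  expect_equal(summarize_region(tm, rois)$value, mean(vals))
  expect_equal(summarize_region(tm, rois, statistic = "median")$value, 50)
  expect_error(summarize_region(tm, rois, regions = "nope"), "unknown")
})

test_that("noise-free scenes recover planted transmittance to 1e-6", {
  for (tt in c(0.3, 0.7, 0.9)) {
    s <- quiet_scene(transmittance = tt, seed = 17)
    row <- quantify_scene(s)
    expect_equal(row$value[row$measure_name == "transparency"], 100 * tt,
                 tolerance = 1e-6)
  }
})

test_that("segmentation counts strictly-above-threshold pixels in the ROI", {
  h <- 32; w <- 32
  rois <- roi_set(list(measurement = matrix(TRUE, h, w)),
                  require_standard = FALSE)
  img <- matrix(10, h, w)
  res <- segment_iridophores(gray_image(img, 8L), rois, threshold = 0.5)
  expect_equal(res$fraction, 0)
  # exactly one quarter of the ROI above threshold
  img[1:16, 1:16] <- 200
  res <- segment_iridophores(gray_image(img, 8L), rois, threshold = 0.5)
  expect_equal(res$iridophore_pixels, 256L)
  expect_equal(res$roi_pixels, 1024L)
  expect_equal(res$fraction, 25)
  # strict inequality: pixels exactly at threshold are background
  img[] <- 0.5 * 255
  res <- segment_iridophores(gray_image(img, 8L), rois, threshold = 0.5)
  expect_equal(res$fraction, 0)
  expect_error(segment_iridophores(gray_image(img, 8L), rois, threshold = 2),
               "fraction")
})

test_that("raising the threshold never increases the area fraction", {
  s <- render_scene(scene_params(iridophore_count = 10L, noise_sd = 0.02,
                                 seed = 31L))
  fr <- vapply(seq(0.2, 0.9, by = 0.1), function(th)
    segment_iridophores(s$sample_reflected, s$rois, th)$fraction, 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("segmentation recovers planted blob coverage", {
  s0 <- quiet_scene(count = 6L, seed = 13L)
  expect_equal(segment_iridophores(s0$sample_reflected, s0$rois)$fraction,
               truth_fraction(s0))
  s1 <- render_scene(scene_params(iridophore_count = 6L, noise_sd = 0.01,
                                  seed = 13L))
  expect_lt(abs(segment_iridophores(s1$sample_reflected, s1$rois)$fraction -
                  truth_fraction(s1)), 1)
})

test_that("gsi is percent gonad weight over body weight, with guards", {
  expect_equal(gsi(0.5, 10), 5)
  expect_equal(gsi(0, 10), 0)
  expect_error(gsi(1, 0), "positive")
  expect_error(gsi(11, 10), "\\[0, body weight\\]")
})

test_that("DEG filter applies strict FDR and fold-change cutoffs", {
  degs <- data.frame(
    gene_id = paste0("g", 1:6),
    log2FC = c(1.5, 3.0, 1.0, -1.2, -0.9, -4),
    FDR = c(0.01, 0.05, 0.01, 0.01, 0.001, 0.049))
  out <- filter_degs(degs)
  expect_equal(out$gene_id, c("g1", "g4", "g6"))
  expect_equal(out$direction, c("up", "down", "down"))
  expect_error(filter_degs(transform(degs, FDR = FDR + 1)), "\\[0, 1\\]")
  expect_error(filter_degs(degs[, 1:2]), "columns")
})

test_that("pseudo-color export writes a PNG and a lossless side-car CSV", {
  s <- quiet_scene(transmittance = 0.4, seed = 2)
  control <- s$control_transmitted$pixels
  control[1, 1] <- 0
  tm <- transparency_map(s$sample_transmitted, gray_image(control, 16L), 1)
  path <- withr::local_tempfile(fileext = ".png")
  out <- pseudocolor_export(tm, path)
  expect_true(file.exists(out[["png"]]))
  arr <- png::readPNG(out[["png"]])
  # undefined pixel rendered in the sentinel color (magenta)
  expect_equal(unname(arr[1, 1, ]), c(1, 0, 1))
  back <- as.matrix(utils::read.table(out[["csv"]], sep = ","))
  dimnames(back) <- NULL
  expect_equal(back, tm$values, tolerance = 1e-12)
  # constant map gives a single color
  tconst <- transparency_map(s$control_transmitted, s$control_transmitted, 1)
  out2 <- pseudocolor_export(tconst, path)
  arr2 <- png::readPNG(path)
  expect_equal(length(unique(as.vector(arr2[, , 1]))), 1L)
})
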