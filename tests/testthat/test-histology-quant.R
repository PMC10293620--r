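two_level_image <- function() {
  px <- matrix(10, 64, 64)
  px[20:40, 20:40] <- 200
  fluorescence_image(px, scale = 1)
}

test_that("thresholding separates a bimodal image exactly and records itself", {
  img <- two_level_image()
  mask <- threshold_positive(img, "otsu")
  expect_identical(as.vector(mask), as.vector(img$pixels == 200))
  expect_true(attr(mask, "threshold") > 10 && attr(mask, "threshold") <= 200)
  fixed <- threshold_positive(fluorescence_image(matrix(0, 8, 8)), "fixed",
                              fixed_value = 1)
  expect_false(any(fixed))
  expect_error(threshold_positive(fluorescence_image(matrix(3, 8, 8)), "otsu"),
               "fixed")
})

test_that("segmentation of synthetic cells overlaps ground truth (Dice > 0.9)", {
  g <- gen_ihc_image_set(ihc_config(n_images = 2, seed = 6))
  for (i in seq_along(g$images)) {
    m <- threshold_positive(g$images[[i]])
    gt <- g$masks[[i]]
    dice <- 2 * sum(m & gt) / (sum(m) + sum(gt))
    expect_gt(dice, 0.9)
  }
})

test_that("area fraction is the positive-pixel proportion", {
  expect_equal(area_fraction(matrix(FALSE, 10, 10)), 0)
  expect_equal(area_fraction(matrix(TRUE, 10, 10)), 1)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(area_fraction(half), 0.5)
  # generator-known coverage recovered within segmentation tolerance
  cfg <- ihc_config(n_images = 3, n_cells_mean = 45, seed = 2)
  g <- gen_ihc_image_set(cfg)
  for (i in seq_along(g$images)) {
    af <- area_fraction(threshold_positive(g$images[[i]]))
    expect_lt(abs(af - g$truth$true_area_fraction[i]), 0.03)
  }
})

test_that("cell counting uses 8-connectivity and the size filter", {
  mask <- matrix(FALSE, 100, 100)
  set.seed(1)
  for (k in 1:10) mask <- paint_disk(mask, 10 * k - 4, 50, 3)
  expect_equal(count_cells(mask, scale = 1, min_area = 20), 10)
  # single disk below the size filter
  small <- paint_disk(matrix(FALSE, 50, 50), 25, 25, 2)
  expect_equal(count_cells(small, scale = 1, min_area = 20), 0)
  expect_error(count_cells(small, scale = 1, min_area = 0), "min_area")
  # two blobs touching only diagonally form one 8-connected component
  diag2 <- matrix(FALSE, 30, 30)
  diag2[5:10, 5:10] <- TRUE
  diag2[11:16, 11:16] <- TRUE
  expect_equal(count_cells(diag2, scale = 1, min_area = 10), 1)
  expect_equal(count_cells(matrix(FALSE, 10, 10), scale = 1), 0L)
})

test_that("non-overlapping generated cells are counted exactly", {
  cfg <- ihc_config(n_images = 2, n_cells_mean = 50, seed = 13)
  g <- gen_ihc_image_set(cfg)
  sham <- which(g$truth$group == "sham")
  for (i in sham) {
    n <- count_cells(threshold_positive(g$images[[i]]), scale = cfg$scale)
    expect_lt(abs(n - g$truth$true_cell_count[i]) /
                max(g$truth$true_cell_count[i], 1), 0.1)
  }
})

test_that("integrated density is a sum of raw intensities", {
  img <- fluorescence_image(matrix(7, 20, 30), scale = 2)
  expect_equal(integrated_density(img), 7 * 600)
  doubled <- fluorescence_image(2 * img$pixels, scale = 2)
  expect_equal(integrated_density(doubled), 2 * integrated_density(img))
  region <- matrix(FALSE, 20, 30); region[1:5, 1:4] <- TRUE
  expect_equal(integrated_density(img, region), 7 * 20)
  # identity: mean intensity x pixel count
  set.seed(3)
  rnd <- fluorescence_image(matrix(runif(600, 0, 50), 20, 30))
  expect_equal(integrated_density(rnd), mean(rnd$pixels) * 600)
})

test_that("a +30% intensity effect moves group mean integrated density by ~30%", {
  cfg <- ihc_config(n_images = 16, count_effect = 1, radius_effect = 1,
                    intensity_effect = 1.3, bg_level = 0, noise_sd = 2,
                    seed = 19)
  g <- gen_ihc_image_set(cfg)
  q <- do.call(rbind, lapply(g$images, quantify_image))
  ratio <- mean(q$integrated_density[q$group == "blast"]) /
    mean(q$integrated_density[q$group == "sham"])
  expect_equal(ratio, 1.3, tolerance = 0.08)
})

test_that("area per cell is inverse in count and undefined at zero cells", {
  mask <- paint_disk(matrix(FALSE, 60, 60), 30, 30, sqrt(100 / pi))
  area <- sum(mask)  # ~100 px^2 at scale 1
  one <- area_per_cell(mask, 1, scale = 1)
  expect_true(one$defined)
  expect_equal(one$area_per_cell_um2, area)
  expect_equal(area_per_cell(mask, 2, scale = 1)$area_per_cell_um2, area / 2)
  none <- area_per_cell(mask, 0, scale = 1)
  expect_false(none$defined)
  expect_true(is.na(none$area_per_cell_um2))
  # generator mean footprint (~pi r^2 = 79 um^2) recovered within 15%
  g <- gen_ihc_image_set(ihc_config(n_images = 6, seed = 23))
  q <- do.call(rbind, lapply(g$images, quantify_image))
  sham <- q[q$group == "sham", ]
  expect_lt(abs(mean(sham$area_per_cell_um2) / (pi * 25) - 1), 0.15)
})

test_that("measures are invariant to affine intensity rescaling with a rescaled threshold", {
  g <- gen_ihc_image_set(ihc_config(n_images = 1, seed = 30))
  img <- g$images[[1L]]
  q1 <- quantify_image(img, method = "fixed", fixed_value = 90)
  scaled <- fluorescence_image(img$pixels * 4, scale = img$scale,
                               channel = img$channel,
                               subject_id = img$subject_id, group = img$group)
  q2 <- quantify_image(scaled, method = "fixed", fixed_value = 360)
  expect_equal(q2$area_fraction, q1$area_fraction)
  expect_equal(q2$cell_count, q1$cell_count)
  expect_equal(q2$area_per_cell_um2, q1$area_per_cell_um2)
  expect_equal(q2$integrated_density, 4 * q1$integrated_density)
})

test_that("quantification is deterministic for identical image and config", {
  g <- gen_ihc_image_set(ihc_config(n_images = 1, seed = 44))
  expect_identical(quantify_image(g$images[[1L]]), quantify_image(g$images[[1L]]))
})
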