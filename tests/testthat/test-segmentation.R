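test_that("region properties are exact on analytic shapes", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  r <- region_properties(sq, pixel_size = 0.1)
  expect_equal(r$area_px, 100)
  expect_equal(r$length_um, 1.0)
  expect_equal(r$width_um, 1.0)
  expect_equal(r$perimeter_px, 36)  # boundary-pixel count convention
  expect_equal(c(r$centroid_row, r$centroid_col), c(10.5, 10.5))

  px1 <- matrix(c(4L, 7L), ncol = 2)
  r1 <- region_properties(px1, pixel_size = 0.16)
  expect_equal(r1$area_px, 1)
  expect_equal(r1$length_um, 0.16)
  expect_equal(r1$width_um, 0.16)
  expect_equal(r1$perimeter_px, 1)

  expect_error(region_properties(matrix(FALSE, 5, 5), 0.1), "Empty")
})

test_that("measured length of a rasterized spherocylinder is within 10%", {
  g <- list(spherocylinder(2.0, 0.5, center = c(4, 3), orientation = 0.5))
  mask <- footprint_mask(g, c(50, 50), 0.16) > 0
  r <- region_properties(mask, 0.16)
  expect_lt(abs(r$length_um - 3.0) / 3.0, 0.10)
  expect_lt(abs(r$width_um - 1.0) / 1.0, 0.15)
  expect_gte(r$length_um, r$width_um)
})

test_that("length and width are invariant under rotation and translation", {
  g <- list(spherocylinder(1.8, 0.5, center = c(3, 3), orientation = 0.3))
  m <- footprint_mask(g, c(40, 40), 0.16) > 0
  r0 <- region_properties(m, 0.16)
  # 90-degree rotation of the image
  m90 <- t(m)[ncol(m):1, ]
  r90 <- region_properties(m90, 0.16)
  expect_equal(r90$length_um, r0$length_um, tolerance = 1e-9)
  expect_equal(r90$width_um, r0$width_um, tolerance = 1e-9)
  # translation
  px <- which(m, arr.ind = TRUE)
  rsh <- region_properties(px + 3L, 0.16)
  expect_equal(rsh$length_um, r0$length_um, tolerance = 1e-9)
  expect_equal(rsh$width_um, r0$width_um, tolerance = 1e-9)
})

test_that("segmentation finds exactly the synthetic cells", {
  opt <- optics_config()
  set.seed(30)
  g <- sample_cell_geometries(5, field_size = c(30, 30), rng_seed = 30)
  img <- render_autofluorescence(g, opt, field_size = c(30, 30),
                                 amplitude = 100, rng_seed = 31)
  regs <- segment_cells(img, pixel_size = opt$pixel_size)
  expect_equal(nrow(regs), 5)
  # each centroid within 2 px of a generating center
  for (i in seq_len(nrow(regs))) {
    ctr <- c(regs$centroid_col[i], regs$centroid_row[i]) * opt$pixel_size
    d <- min(vapply(g, function(x) sqrt(sum((x$center - ctr)^2)), numeric(1)))
    expect_lt(d / opt$pixel_size, 2)
  }
  # regions are pairwise disjoint and respect min_area
  keys <- unlist(lapply(regs$pixels, function(p) paste(p[, 1], p[, 2])))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(regs$area_px >= 50))
})

test_that("blank noise yields no regions; border cells are removed; exclusions drop", {
  opt <- optics_config()
  blank <- render_autofluorescence(list(), opt, field_size = c(20, 20),
                                   rng_seed = 32)
  expect_equal(nrow(segment_cells(blank)), 0)
  expect_error(segment_cells(array(0, c(3, 3, 3))), "2D")

  # one cell overlapping the border is excluded
  g <- list(spherocylinder(2, 0.5, center = c(5, 5)),
            spherocylinder(2, 0.5, center = c(1.2, 1.2), orientation = 0.8))
  img <- render_autofluorescence(g, opt, field_size = c(10, 10),
                                 amplitude = 100, rng_seed = 33)
  regs <- segment_cells(img)
  expect_equal(nrow(regs), 1)

  g5 <- sample_cell_geometries(5, field_size = c(30, 30), rng_seed = 34)
  img5 <- render_autofluorescence(g5, opt, field_size = c(30, 30),
                                  amplitude = 100, rng_seed = 35)
  all5 <- segment_cells(img5)
  kept <- segment_cells(img5, exclusions = all5$cell_id[2])
  expect_equal(nrow(kept), 4)
  expect_false(all5$cell_id[2] %in% kept$cell_id)
})

test_that("newborn filter keeps strictly sub-threshold lengths and is idempotent", {
  regs <- dplyr::bind_rows(
    region_properties(matrix(c(1L, 1L), ncol = 2), 3.4),
    region_properties(matrix(c(5L, 5L), ncol = 2), 3.6))
  regs$cell_id <- 1:2
  kept <- filter_newborn(regs, 3.5)
  expect_equal(kept$length_um, 3.4)

  expect_equal(nrow(filter_newborn(regs[0, ], 3.5)), 0)
  # boundary: exactly 3.5 um is excluded ("lower than")
  r35 <- region_properties(matrix(c(2L, 2L), ncol = 2), 3.5)
  expect_equal(nrow(filter_newborn(r35, 3.5)), 0)
  # idempotent subset
  expect_identical(filter_newborn(kept, 3.5), kept)
  expect_true(all(kept$cell_id %in% regs$cell_id))
})

test_that("intensity-based segmentation handles flat, sparse and trimmed cases", {
  expect_equal(nrow(segment_by_intensity(matrix(7, 50, 50))), 0)

  set.seed(36)
  opt <- optics_config()
  g <- sample_cell_geometries(4, field_size = c(25, 25), rng_seed = 36)
  img <- matrix(opt$background_level, 156, 156)
  foot <- footprint_mask(g, dim(img), opt$pixel_size)
  img <- img + 300 * (foot > 0)
  img[] <- rpois(length(img), img)
  si <- segment_by_intensity(img)
  expect_equal(nrow(si), 4)

  # low_fraction = 0 regions are supersets of the trimmed ones
  si0 <- segment_by_intensity(img, low_fraction = 0)
  k0 <- unlist(lapply(si0$pixels, function(p) paste(p[, 1], p[, 2])))
  k2 <- unlist(lapply(si$pixels, function(p) paste(p[, 1], p[, 2])))
  expect_true(all(k2 %in% k0))
  expect_error(segment_by_intensity(img, low_fraction = 1))
})

test_that("mean intensity per area equals the brute-force mask mean", {
  img <- matrix(7, 10, 10)
  px <- cbind(rep(2:4, each = 3), rep(2:4, 3))
  expect_equal(mean_intensity_per_area(img, px), 7)

  set.seed(37)
  img2 <- matrix(runif(100), 10, 10)
  acc <- 0
  for (k in seq_len(nrow(px))) acc <- acc + img2[px[k, 1], px[k, 2]]
  expect_equal(mean_intensity_per_area(img2, px), acc / nrow(px))

  # two-level image with two regions
  img3 <- matrix(10, 10, 10); img3[, 6:10] <- 20
  left <- cbind(rep(1:10, 2), rep(1:2, each = 10))
  right <- cbind(rep(1:10, 2), rep(7:8, each = 10))
  expect_equal(mean_intensity_per_area(img3, left), 10)
  expect_equal(mean_intensity_per_area(img3, right), 20)

  expect_error(mean_intensity_per_area(img, cbind(11L, 1L)), "outside")
})

test_that("detection is perfect on well-contrasted, well-separated fields", {
  # contrast ~7x the ambient noise SD, gaps >= 10 px by construction
  opt <- optics_config()
  set.seed(38)
  hits <- 0; total_true <- 0; total_found <- 0
  for (f in 1:6) {
    g <- sample_cell_geometries(5, field_size = c(30, 30), min_gap = 1.6)
    img <- render_autofluorescence(g, opt, field_size = c(30, 30),
                                   amplitude = 100)
    regs <- segment_cells(img)
    total_true <- total_true + length(g)
    total_found <- total_found + nrow(regs)
    for (i in seq_len(nrow(regs))) {
      ctr <- c(regs$centroid_col[i], regs$centroid_row[i]) * opt$pixel_size
      d <- min(vapply(g, function(x) sqrt(sum((x$center - ctr)^2)),
                      numeric(1)))
      if (d < 0.5) hits <- hits + 1
    }
  }
  expect_equal(total_found, total_true)  # precision
  expect_equal(hits, total_true)         # recall
})
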