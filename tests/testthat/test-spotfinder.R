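test_that("max projection excludes the first plane and matches brute force", {
  # hot pixel in plane 1 must not leak into the projection
  planes <- lapply(1:5, function(i) matrix(5, 8, 8))
  planes[[1]][4, 4] <- 100
  st <- image_stack(planes)
  expect_true(all(max_projection(st) <= 5))
  expect_equal(max_projection(st, skip_first = FALSE)[4, 4], 100)

  # all planes identical -> projection equals any plane
  same <- image_stack(lapply(1:4, function(i) matrix(1:64, 8, 8)))
  expect_equal(max_projection(same), matrix(1:64, 8, 8))

  # brute-force elementwise oracle on a random integer stack
  set.seed(40)
  arr <- array(sample(0:99, 4 * 4 * 4, TRUE), c(4, 4, 4))
  st2 <- image_stack(arr)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) ref[i, j] <- max(arr[2:4, i, j])
  expect_equal(max_projection(st2), ref)

  # permutation invariance over retained planes
  st3 <- image_stack(arr[c(1, 4, 2, 3), , ])
  expect_equal(max_projection(st3), ref)

  expect_error(max_projection(image_stack(array(0, c(1, 4, 4)))), ">= 2")
})

test_that("crops have exact shape, median padding and invertible offsets", {
  set.seed(41)
  img <- matrix(rpois(200 * 200, 50), 200, 200)
  cr <- crop_around(img, c(100, 100), c(30, 35))
  expect_equal(dim(cr$crop), c(30, 35))

  corner <- crop_around(img, c(1, 1), c(30, 35))
  expect_equal(dim(corner$crop), c(30, 35))
  expect_equal(corner$crop[1, 1], median(img))  # padded region

  for (k in 1:100) {
    ctr <- c(sample(200, 1), sample(200, 1))
    cr <- crop_around(img, ctr, c(30, 35))
    p <- c(sample(30, 1), sample(35, 1))
    full <- p + cr$offset
    if (all(full >= 1 & full <= 200))
      expect_identical(cr$crop[p[1], p[2]], as.numeric(img[full[1], full[2]]))
  }
  expect_error(crop_around(img, c(0, 5)), "outside")
})

test_that("band-pass removes DC, suppresses impulses, preserves spot positions", {
  expect_true(all(bandpass(matrix(3, 30, 30)) == 0))

  # impulse vs a Gaussian spot of sigma = feature_size/4 with equal raw peak
  imp <- matrix(0, 31, 31); imp[16, 16] <- 100
  spot <- add_test_spot(matrix(0, 31, 31), 16, 16, 100, sigma = 7 / 4)
  out_i <- bandpass(imp); out_s <- bandpass(spot)
  expect_lt(max(out_i), 0.2 * max(out_s))  # >= 80% relative suppression

  # oracle: direct (naive) convolution of both patterns with the same kernels
  w <- 7; sg <- sqrt(2)
  x <- -w:w; g1 <- exp(-x^2 / (2 * sg^2)); g1 <- g1 / sum(g1)
  K <- outer(g1, g1)
  B <- matrix(1 / (2 * w + 1)^2, 2 * w + 1, 2 * w + 1)
  ref_i <- pmax(naive_conv2(imp, K) - naive_conv2(imp, B), 0)
  expect_equal(matrix(bandpass(imp), 31), ref_i, tolerance = 1e-9)

  # argmax is preserved for a noiseless spot
  sp2 <- add_test_spot(matrix(10, 40, 40), 22, 17, 500, sigma = 1)
  bp <- bandpass(sp2)
  expect_equal(as.integer(which(bp == max(bp), arr.ind = TRUE)[1, ]),
               c(22L, 17L))

  expect_error(bandpass(matrix(0, 10, 10), feature_size = 8), "larger")
  expect_error(bandpass(matrix(0, 30, 30), noise_size = 7, feature_size = 7))
})

test_that("peak calling resolves, merges and tie-breaks as specified", {
  expect_equal(nrow(find_peaks(matrix(4, 30, 30))), 0)

  mk2 <- function(sep) {
    img <- matrix(100, 40, 40)
    img <- add_test_spot(img, 20, 15, 2000, 0.6)
    add_test_spot(img, 20, 15 + sep, 2000, 0.6)
  }
  img10 <- mk2(10)
  pk <- find_peaks(bandpass(img10), window = 6, threshold = 3 * mad(img10))
  expect_equal(nrow(pk), 2)
  expect_true(all(abs(pk$row - 20) <= 1))
  expect_true(all(abs(sort(pk$col) - c(15, 25)) <= 1))

  img2 <- mk2(2)
  pk2 <- find_peaks(bandpass(img2), window = 6, threshold = 3 * mad(img2))
  expect_equal(nrow(pk2), 1)

  # plateau tie-break: keep the topmost-then-leftmost of equal maxima
  flat <- matrix(0, 20, 20); flat[10, 10] <- 5; flat[10, 12] <- 5
  pk3 <- find_peaks(flat, window = 6, threshold = 1)
  expect_equal(nrow(pk3), 1)
  expect_equal(c(pk3$row, pk3$col), c(10L, 10L))

  expect_error(find_peaks(matrix(0, 10, 10), window = 2), ">= 3")
})

test_that("per-cell counting recovers {0, 1, 3} on a controlled field", {
  opt <- optics_config()
  set.seed(42)
  g <- list(spherocylinder(2.2, 0.5, center = c(5, 5)),
            spherocylinder(2.2, 0.5, center = c(5, 12)),
            spherocylinder(2.2, 0.5, center = c(12, 8), orientation = pi / 2))
  # true counts 0, 1, 3 with spots >= 8 px apart within each cell
  pos <- rbind(to_field_coordinates(g[[2]], matrix(c(0, 0, 0), ncol = 3)),
               to_field_coordinates(g[[3]], cbind(c(-1.35, 0, 1.35), 0, 0)))
  stack <- render_zstack(g, pos, opt, field_size = c(17, 17), rng_seed = 43)
  af <- render_autofluorescence(g, opt, field_size = c(17, 17),
                                amplitude = 100, rng_seed = 44)
  regs <- segment_cells(af)
  expect_equal(nrow(regs), 3)
  cs <- count_spots(stack, regs)
  got <- integer(3)
  for (i in 1:3) {
    ctr <- c(regs$centroid_col[i], regs$centroid_row[i]) * opt$pixel_size
    j <- which.min(vapply(g, function(x) sum((x$center - ctr)^2), numeric(1)))
    got[j] <- cs$counts$n_spots[i]
  }
  expect_equal(got, c(0L, 1L, 3L))

  # determinism: same inputs, same output
  expect_identical(cs$counts, count_spots(stack, regs)$counts)

  # counts never exceed truth and are monotone in threshold_k
  cfg_hi <- spot_config(threshold_k = 10)
  cs_hi <- count_spots(stack, regs, cfg_hi)
  expect_true(all(cs_hi$counts$n_spots <= cs$counts$n_spots))
})

test_that("blank noise fields produce no spots in segmented cells", {
  opt <- optics_config()
  set.seed(45)
  g <- sample_cell_geometries(5, field_size = c(30, 30), rng_seed = 45)
  stack <- render_zstack(g, matrix(numeric(0), ncol = 3), opt,
                         field_size = c(30, 30), rng_seed = 46)
  af <- render_autofluorescence(g, opt, field_size = c(30, 30),
                                amplitude = 100, rng_seed = 47)
  regs <- filter_newborn(segment_cells(af))
  cs <- count_spots(stack, regs)
  expect_gt(nrow(cs$counts), 0)
  expect_true(all(cs$counts$n_spots == 0))

  # empty region table -> empty counts table
  empty <- count_spots(stack, regs[0, ])
  expect_equal(nrow(empty$counts), 0)
})
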