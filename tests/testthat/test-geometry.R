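test_that("spherocylinder construction validates and derives total length", {
  sc <- spherocylinder(2, 0.5)
  expect_equal(sc$total_length, 3)
  expect_error(spherocylinder(-1, 0.5))
  expect_error(spherocylinder(2, 0))
  expect_error(spherocylinder(2, 0.5, center = c(1, NA)))
})

test_that("cell geometry sampling honours n, truncation and the newborn regime", {
  expect_equal(sample_cell_geometries(0), list())

  g <- sample_cell_geometries(
    60, length_distribution = list("uniform", min = 2.0, max = 3.4),
    field_size = c(80, 80), length_range = c(1.5, 6), rng_seed = 1)
  lens <- vapply(g, function(x) x$total_length, numeric(1))
  expect_length(lens, 60)
  expect_true(all(lens < 3.5))  # every cell satisfies the newborn criterion
  expect_true(all(lens >= 2.0))
})

test_that("lognormal length sampling matches its configured mean (MC oracle)", {
  g <- sample_cell_geometries(
    1000, length_distribution = list("lognormal", meanlog = log(2.5),
                                     sdlog = 0.15),
    field_size = c(400, 400), rng_seed = 2)
  lens <- vapply(g, function(x) x$total_length, numeric(1))
  # oracle: big independent draw from the same truncated distribution
  set.seed(99)
  ref <- rlnorm(2e5, log(2.5), 0.15)
  ref <- ref[ref >= 1.5 & ref <= 6]
  se <- sd(ref) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - mean(ref)), 3 * se)
})

test_that("sampled cells never overlap and errors are informative", {
  g <- sample_cell_geometries(12, field_size = c(35, 35), min_gap = 1.6,
                              rng_seed = 3)
  for (i in seq_along(g)) for (j in seq_len(i - 1)) {
    e1 <- halocount:::.axis_endpoints(g[[i]])
    e2 <- halocount:::.axis_endpoints(g[[j]])
    d <- halocount:::.seg_seg_dist(e1$a, e1$b, e2$a, e2$b)
    expect_gte(d, g[[i]]$radius + g[[j]]$radius + 1.6 - 1e-9)
  }
  expect_error(sample_cell_geometries(50, field_size = c(8, 8),
                                      max_retries = 20, rng_seed = 4),
               "dense")
  expect_error(sample_cell_geometries(2, length_distribution = list("nope")),
               "Unknown length distribution")
})

test_that("molecule placement is uniform over the spherocylinder", {
  g <- spherocylinder(2, 0.5)
  expect_identical(nrow(sample_molecule_positions(g, 0)), 0L)
  expect_error(sample_molecule_positions(g, -1))

  # degenerate radius: everything collapses onto the axis
  thin <- spherocylinder(2, 1e-6)
  p <- sample_molecule_positions(thin, 50, rng_seed = 5)
  expect_true(all(sqrt(p[, 2]^2 + p[, 3]^2) <= 1e-6 + 1e-12))

  p <- sample_molecule_positions(g, 2e4, rng_seed = 6)
  expect_true(all(in_spherocylinder(g, p)))
  # cap occupancy equals the analytic volume ratio (4r/3)/(L + 4r/3) = 0.25
  cap_frac <- mean(abs(p[, 1]) > g$cyl_length / 2)
  se <- sqrt(0.25 * 0.75 / nrow(p))
  expect_lt(abs(cap_frac - 0.25), 3 * se)

  # oracle: rejection sampling in the bounding box agrees
  set.seed(7)
  n_try <- 2e4
  bb <- cbind(runif(n_try, -1.5, 1.5), runif(n_try, -0.5, 0.5),
              runif(n_try, -0.5, 0.5))
  inside <- in_spherocylinder(g, bb)
  cap_frac_oracle <- mean(abs(bb[inside, 1]) > 1)
  expect_lt(abs(cap_frac - cap_frac_oracle),
            3 * sqrt(0.25 * 0.75 * (1 / nrow(p) + 1 / sum(inside))) + 0.01)
})

test_that("samplers are bit-identical under a fixed seed", {
  g <- spherocylinder(2, 0.5)
  expect_identical(sample_molecule_positions(g, 10, rng_seed = 8),
                   sample_molecule_positions(g, 10, rng_seed = 8))
  expect_identical(sample_poisson_counts(4.9, 10, rng_seed = 8),
                   sample_poisson_counts(4.9, 10, rng_seed = 8))
  g2 <- sample_cell_geometries(5, rng_seed = 9)
  g3 <- sample_cell_geometries(5, rng_seed = 9)
  expect_identical(g2, g3)
})

test_that("separation-constrained placement satisfies its metric in the image frame", {
  g <- spherocylinder(2.2, 0.5)
  p <- sample_molecule_positions(g, 6, min_separation_2d = 0.6,
                                 metric = "euclidean", rng_seed = 10)
  expect_true(all(dist(p[, 1:2]) >= 0.6 - 1e-9))
  expect_true(all(in_spherocylinder(g, p, tol = 1e-6)))

  rot <- 0.7
  p2 <- sample_molecule_positions(g, 6, min_separation_2d = 0.7,
                                  metric = "chebyshev",
                                  constraint_rotation = rot, rng_seed = 11)
  xr <- cos(rot) * p2[, 1] - sin(rot) * p2[, 2]
  yr <- sin(rot) * p2[, 1] + cos(rot) * p2[, 2]
  ch <- pmax(abs(outer(xr, xr, "-")), abs(outer(yr, yr, "-")))
  diag(ch) <- Inf
  expect_true(all(ch >= 0.7 - 1e-9))

  # infeasible packing fails with a clear error
  expect_error(sample_molecule_positions(spherocylinder(0.5, 0.5), 30,
                                         min_separation_2d = 0.9,
                                         max_retries = 2, rng_seed = 12),
               "Could not place")
})

test_that("Poisson copy-number sampler has the right moments and edge cases", {
  expect_identical(sample_poisson_counts(0, 20, rng_seed = 13),
                   rep(0L, 20))
  expect_error(sample_poisson_counts(-1, 5))
  x <- sample_poisson_counts(5, 1e5, rng_seed = 14)
  se_mean <- sqrt(5 / 1e5)
  expect_lt(abs(mean(x) - 5), 3 * se_mean)
  # Var = lambda; SE of the sample variance of a Poisson ~ sqrt((2l^2+l)/n)
  se_var <- sqrt((2 * 25 + 5) / 1e5)
  expect_lt(abs(var(x) - 5), 3 * se_var)
})

test_that("field-frame transform rotates, translates and lifts z", {
  g <- spherocylinder(2, 0.5, center = c(10, 20), orientation = pi / 2)
  f <- to_field_coordinates(g, matrix(c(1, 0, 0), ncol = 3))
  expect_equal(unname(f[1, ]), c(10, 21, 0.5), tolerance = 1e-12)
  expect_true(all(to_field_coordinates(g, sample_molecule_positions(
    g, 200, rng_seed = 15))[, 3] >= 0))
})
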