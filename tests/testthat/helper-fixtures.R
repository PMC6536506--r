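# shared fixture builders and independent mini-oracles

# naive O(n^2 k^2) 2D convolution with replicated edges — independent check
# for the separable band-pass implementation
naive_conv2 <- function(img, kernel) {
  kr <- (nrow(kernel) - 1) %/% 2
  kc <- (ncol(kernel) - 1) %/% 2
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      ii <- min(max(i + a, 1), nrow(img))
      jj <- min(max(j + b, 1), ncol(img))
      acc <- acc + img[ii, jj] * kernel[a + kr + 1, b + kc + 1]
    }
    out[i, j] <- acc
  }
  out
}

# literal union-find over all pairwise distances — brute-force clustering
# oracle, written independently of cluster_points()
brute_cluster_count <- function(pts, eps) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && sqrt(sum((pts[i, ] - pts[j, ])^2)) <= eps &&
          comp[j] != comp[i]) {
        old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
        comp[comp == old] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# match pipeline-reported cells back to generating cells by centroid (um);
# returns tibble of (true_count, detected)
match_counts_to_truth <- function(sim, regions, counts, max_dist = 0.5) {
  px <- sim$optics$pixel_size
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    ctr <- c(regions$centroid_col[i], regions$centroid_row[i]) * px
    dd <- vapply(sim$geoms, function(g) sqrt(sum((g$center - ctr)^2)),
                 numeric(1))
    j <- which.min(dd)
    if (dd[j] < max_dist)
      out <- rbind(out, data.frame(true_count = sim$truth$true_count[j],
                                   detected = counts$n_spots[i]))
  }
  out
}

# place an ideal Gaussian spot (amplitude at peak ~ amp) on an image
add_test_spot <- function(img, row, col, amp, sigma = 0.6) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    img[i, j] <- img[i, j] +
      amp * exp(-((i - row)^2 + (j - col)^2) / (2 * sigma^2))
  img
}
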