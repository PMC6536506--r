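#' Project 3D molecule positions to the image plane
#'
#' Epifluorescence detection sees the 2D projection of the 3D molecule
#' distribution: the optical-axis coordinate (third column) is dropped and
#' the in-plane coordinates are unchanged. Projection can only shrink
#' pairwise distances, which is one of the two sources of diffraction-limited
#' undercounting.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) or an empty matrix.
#' @return Matrix with the first two columns of `points`.
#' @export
project_2d <- function(points) {
  points <- matrix(as.numeric(points), ncol = max(3, ncol(as.matrix(points))))
  if (nrow(points) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  out <- points[, 1:2, drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Cluster points at the diffraction limit
#'
#' Density clustering with minimum cluster size 1: every point belongs to a
#' cluster, and two points share a cluster whenever they are connected by a
#' chain of neighbours each within `eps` of the next. This is exactly the
#' connected components of the eps-proximity graph (DBSCAN with minPts = 1),
#' computed by union-find over all pairwise Euclidean distances.
#'
#' @param points2d Numeric matrix of 2D points (um).
#' @param eps Clustering distance = diffraction limit, um (>= 0).
#' @return List with `labels` (integer cluster id per point, numbered by
#'   first occurrence) and `n_clusters`.
#' @export
cluster_points <- function(points2d, eps) {
  if (eps < 0) abort("`eps` must be >= 0.")
  pts <- matrix(as.numeric(points2d), ncol = 2)
  n <- nrow(pts)
  if (n == 0) return(list(labels = integer(0), n_clusters = 0L))
  if (n == 1) return(list(labels = 1L, n_clusters = 1L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d <- as.matrix(dist(pts))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] <= eps) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  list(labels = labels, n_clusters = length(unique(labels)))
}

#' Configuration for the undercounting simulation
#'
#' @param eps Clustering distance (diffraction limit), um.
#' @param lambda_grid Poisson means at which to simulate.
#' @param n_cells_per_lambda Simulated cells per Poisson mean.
#' @param geometry_source Length-distribution spec passed to
#'   [sample_cell_geometries()]'s `length_distribution`, or
#'   `list("fixed", value =)` etc. Default: lognormal newborn-like lengths
#'   truncated below 3.5 um.
#' @param radius Cell radius, um.
#' @param length_range Truncation range for total lengths, um.
#' @param rng_seed Optional integer seed.
#' @return List of class `undercount_config`.
#' @export
undercount_config <- function(eps = 0.25,
                              lambda_grid = seq(0.5, 15, by = 0.5),
                              n_cells_per_lambda = 10000,
                              geometry_source = list("lognormal",
                                                     meanlog = log(2.5),
                                                     sdlog = 0.15),
                              radius = 0.5,
                              length_range = c(1.5, 3.5),
                              rng_seed = NULL) {
  if (eps < 0) abort("`eps` must be >= 0.")
  if (any(lambda_grid < 0)) abort("All Poisson means must be >= 0.")
  if (n_cells_per_lambda < 1) abort("`n_cells_per_lambda` must be >= 1.")
  structure(list(eps = eps, lambda_grid = lambda_grid,
                 n_cells_per_lambda = as.integer(n_cells_per_lambda),
                 geometry_source = geometry_source, radius = radius,
                 length_range = length_range, rng_seed = rng_seed),
            class = "undercount_config")
}

#' Simulate diffraction-limited undercounting
#'
#' For each Poisson mean in the grid: a cell length is drawn from the
#' geometry source, `N ~ Poisson(lambda)` molecules are placed uniformly in
#' the spherocylinder, projected to 2D, and clustered at `eps`. The cluster
#' count is what a diffraction-limited spot counter would report; comparing
#' its mean to the true mean measures the undercounting bias.
#'
#' @param config An [undercount_config()].
#' @return Tibble of class `undercount_result` with one row per lambda:
#'   `lambda`, `mean_true`, `mean_detected`, `detection_ratio`, `n_cells`,
#'   plus a `cells` list-column of per-cell tibbles (n_true, n_detected).
#' @export
simulate_undercount <- function(config = undercount_config()) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  res <- purrr::map(config$lambda_grid, function(lam) {
    lens <- .sample_lengths(config$n_cells_per_lambda,
                            config$geometry_source, config$length_range)
    ns <- rpois(config$n_cells_per_lambda, lam)
    det <- integer(length(ns))
    for (i in seq_along(ns)) {
      if (ns[i] == 0) { det[i] <- 0L; next }
      g <- spherocylinder(max(lens[i] - 2 * config$radius, 0), config$radius)
      pts <- .draw_uniform_spherocyl(g, ns[i])
      det[i] <- cluster_points(project_2d(pts), config$eps)$n_clusters
    }
    tibble(lambda = lam, mean_true = mean(ns), mean_detected = mean(det),
           detection_ratio = if (mean(ns) > 0) mean(det) / mean(ns) else NA_real_,
           n_cells = length(ns),
           cells = list(tibble(n_true = ns, n_detected = det)))
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("undercount_result", class(out))
  out
}

#' Largest Poisson mean with acceptable undercounting bias
#'
#' Finds the largest lambda (with linear interpolation between grid points)
#' at which the relative undercounting of the mean, `1 - detection_ratio`,
#' does not exceed `max_relative_bias`. Returns `Inf` if the bias never
#' exceeds the bound on the grid.
#'
#' @param results An `undercount_result` tibble (sorted by lambda).
#' @param max_relative_bias Tolerated relative bias of the mean (default
#'   0.05).
#' @return The threshold lambda (scalar; `Inf` if never exceeded).
#' @export
bias_threshold <- function(results, max_relative_bias = 0.05) {
  if (nrow(results) == 0) abort("`results` is empty.")
  results <- dplyr::arrange(results, .data$lambda)
  bias <- 1 - results$detection_ratio
  lam <- results$lambda
  above <- which(bias > max_relative_bias)
  if (!length(above)) return(Inf)
  i <- above[1]
  if (i == 1) return(lam[1] * max_relative_bias / max(bias[1], 1e-12))
  # linear interpolation of the bias curve between the bracketing grid points
  lam[i - 1] + (max_relative_bias - bias[i - 1]) /
    (bias[i] - bias[i - 1]) * (lam[i] - lam[i - 1])
}
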