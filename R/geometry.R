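#' Spherocylinder cell geometry
#'
#' A spherocylinder (a cylinder capped by two hemispheres) is the standard
#' geometric model of a rod-shaped bacterium. The cylindrical axis lies in the
#' image plane; `orientation` is the in-plane angle of the axis and `center`
#' the in-plane position of the geometric center. The pole-to-pole length is
#' `cyl_length + 2 * radius`.
#'
#' @param cyl_length Length of the cylindrical section, um (>= 0).
#' @param radius Cap/cylinder radius, um (> 0).
#' @param center Numeric length-2, in-plane (x, y) position of the center, um.
#' @param orientation In-plane axis angle, radians.
#'
#' @return An object of class `spherocylinder`: a list with fields
#'   `cyl_length`, `radius`, `center`, `orientation` and derived
#'   `total_length`.
#' @export
#' @examples
#' sc <- spherocylinder(2, 0.5)
#' sc$total_length  # 3
spherocylinder <- function(cyl_length, radius, center = c(0, 0),
                           orientation = 0) {
  if (!is.numeric(cyl_length) || length(cyl_length) != 1L || cyl_length < 0)
    abort("`cyl_length` must be a single non-negative number.")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    abort("`radius` must be a single positive number.")
  if (length(center) != 2L || !all(is.finite(center)))
    abort("`center` must be two finite numbers.")
  structure(
    list(cyl_length = cyl_length, radius = radius,
         center = as.numeric(center), orientation = as.numeric(orientation),
         total_length = cyl_length + 2 * radius),
    class = "spherocylinder"
  )
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf(
    "<spherocylinder> total length %.3f um (cyl %.3f, r %.3f), center (%.2f, %.2f), angle %.2f rad\n",
    x$total_length, x$cyl_length, x$radius, x$center[1], x$center[2],
    x$orientation))
  invisible(x)
}

#' Test whether 3D points lie inside a spherocylinder
#'
#' Points are given in cell-local coordinates: x along the cylinder axis
#' (centered), y in-plane lateral, z along the optical axis relative to the
#' axis plane.
#'
#' @param geom A [spherocylinder()].
#' @param pts Numeric matrix with columns x, y, z (um, cell-local frame).
#' @param tol Numerical slack on the radius, um.
#' @return Logical vector, one element per row of `pts`.
#' @export
in_spherocylinder <- function(geom, pts, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  h <- geom$cyl_length / 2
  ax <- pmax(abs(pts[, 1]) - h, 0)  # axial excess beyond the cylinder
  sqrt(ax^2 + pts[, 2]^2 + pts[, 3]^2) <= geom$radius + tol
}

# segment-to-segment minimum distance between the axes of two spherocylinders
# (2D, in-plane); used for non-overlap placement.
.axis_endpoints <- function(g) {
  h <- g$cyl_length / 2
  d <- c(cos(g$orientation), sin(g$orientation))
  list(a = g$center - h * d, b = g$center + h * d)
}

.seg_seg_dist <- function(p1, q1, p2, q2) {
  # standard closest-distance between two 2D segments
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom > 1e-12) min(max((b * f - c_ * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp1 <- p1 + s * d1; cp2 <- p2 + t * d2
  sqrt(sum((cp1 - cp2)^2))
}

#' Sample non-overlapping cell geometries in a field
#'
#' Draws cell total lengths (pole-to-pole) from a configurable distribution,
#' truncated to a positive range, and places the resulting spherocylinders in
#' the field with random positions and orientations so that no two cell
#' surfaces come closer than `min_gap` and no cell touches the field border.
#' Placement is by rejection with a retry cap.
#'
#' @param n_cells Number of cells (>= 0).
#' @param length_distribution A list naming the total-length distribution and
#'   its parameters. Supported: `list("lognormal", meanlog=, sdlog=)` (meanlog
#'   given on the log-um scale), `list("uniform", min=, max=)`,
#'   `list("fixed", value=)`, `list("empirical", values=)` (resampled with
#'   replacement). Defaults to a lognormal with median 2.5 um.
#' @param radius Cap/cylinder radius, um. Default 0.5 (typical E. coli
#'   half-width).
#' @param field_size Numeric length-2, field extent (x, y) in um.
#' @param min_gap Minimum surface-to-surface clearance between cells, um.
#' @param length_range Truncation range for sampled total lengths, um.
#' @param border Clearance kept between any cell surface and the field edge,
#'   um; the default keeps segmentation halos clear of the border rule.
#' @param max_retries Placement attempts per cell before giving up.
#' @param rng_seed Optional integer seed (set once before sampling).
#'
#' @return A list of [spherocylinder()] objects (length `n_cells`).
#' @export
sample_cell_geometries <- function(n_cells,
                                   length_distribution = list("lognormal",
                                                              meanlog = log(2.5),
                                                              sdlog = 0.15),
                                   radius = 0.5,
                                   field_size = c(40, 40),
                                   min_gap = 1.6,
                                   length_range = c(1.5, 6),
                                   border = 1.0,
                                   max_retries = 2000,
                                   rng_seed = NULL) {
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (n_cells == 0) return(list())

  lens <- .sample_lengths(n_cells, length_distribution, length_range)
  placed <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    Lc <- max(lens[i] - 2 * radius, 0)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ang <- runif(1, 0, pi)
      half <- Lc / 2 + radius + border
      ext <- abs(c(cos(ang), sin(ang))) * Lc / 2 + radius + border
      if (any(field_size < 2 * ext)) next
      ctr <- c(runif(1, ext[1], field_size[1] - ext[1]),
               runif(1, ext[2], field_size[2] - ext[2]))
      cand <- spherocylinder(Lc, radius, ctr, ang)
      e1 <- .axis_endpoints(cand)
      clear <- TRUE
      for (g in placed[seq_len(i - 1)]) {
        e2 <- .axis_endpoints(g)
        if (.seg_seg_dist(e1$a, e1$b, e2$a, e2$b) <
            cand$radius + g$radius + min_gap) { clear <- FALSE; break }
      }
      if (clear) { placed[[i]] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      abort(sprintf(
        "Could not place cell %d of %d after %d retries; field %g x %g um is too dense for %d cells.",
        i, n_cells, max_retries, field_size[1], field_size[2], n_cells))
  }
  placed
}

.sample_lengths <- function(n, spec, range) {
  name <- spec[[1]]
  draw <- switch(
    name,
    lognormal = function(m) rlnorm(m, meanlog = spec$meanlog, sdlog = spec$sdlog),
    uniform   = function(m) runif(m, spec$min, spec$max),
    fixed     = function(m) rep(spec$value, m),
    empirical = function(m) sample(spec$values, m, replace = TRUE),
    abort(sprintf("Unknown length distribution '%s'.", name))
  )
  out <- numeric(0)
  for (it in 1:1000) {
    x <- draw(n - length(out))
    out <- c(out, x[x >= range[1] & x <= range[2] & x > 0])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  abort("Length distribution produced no values inside the truncation range.")
}

#' Sample molecule positions uniformly inside a spherocylinder
#'
#' Uniform sampling over the volume is done by a volume-weighted choice
#' between the cylindrical section and the two hemispherical caps: with
#' probability \eqn{(4r/3) / (L + 4r/3)} a point is drawn in the caps (a
#' uniform draw in the full sphere attached to the pole on the side of its
#' axial coordinate), otherwise in the cylinder. Optionally, a minimum
#' pairwise in-plane (projected) separation can be imposed, emulating the
#' well-separated regime in which every diffraction-limited spot is
#' individually resolvable: the constrained draw starts from a uniform
#' configuration and applies pairwise repulsion (with re-projection into the
#' cell body) until all projected pairs satisfy the separation. The result is
#' then no longer uniform — it is a spread-out configuration, which is the
#' point of that regime. `metric = "chebyshev"` constrains
#' `max(|dx|, |dy|)`, matching the resolution geometry of a square
#' local-maximum detection window.
#'
#' @param geom A [spherocylinder()].
#' @param count Number of molecules (>= 0).
#' @param min_separation_2d Minimum pairwise distance after projection to the
#'   image plane, um; 0 (default) disables the constraint and the draw is
#'   exactly uniform.
#' @param metric Distance used for the separation constraint: `"euclidean"`
#'   or `"chebyshev"`.
#' @param constraint_rotation Angle (radians) by which the projected
#'   coordinates are rotated before evaluating a Chebyshev constraint —
#'   normally the cell's in-field orientation, so the constraint holds in
#'   image axes (Chebyshev distance is not rotation invariant). Ignored for
#'   the Euclidean metric.
#' @param max_retries Restarts of the relaxation before giving up.
#' @param rng_seed Optional integer seed.
#'
#' @return Numeric matrix with `count` rows and columns `x`, `y`, `z`:
#'   cell-local coordinates (um), x along the axis (centered), z along the
#'   optical axis relative to the axis plane.
#' @export
sample_molecule_positions <- function(geom, count, min_separation_2d = 0,
                                      metric = c("euclidean", "chebyshev"),
                                      constraint_rotation = 0,
                                      max_retries = 8, rng_seed = NULL) {
  if (count < 0) abort("`count` must be >= 0.")
  metric <- match.arg(metric)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (count == 0) return(empty)
  if (min_separation_2d <= 0 || count == 1)
    return(.draw_uniform_spherocyl(geom, count))
  for (try in seq_len(max_retries)) {
    pts <- .relax_separation(geom, .draw_uniform_spherocyl(geom, count),
                             min_separation_2d, metric, constraint_rotation)
    if (!is.null(pts)) return(pts)
  }
  abort(sprintf(
    "Could not place %d molecules with pairwise 2D separation >= %g um in a %.2f um cell after %d restarts.",
    count, min_separation_2d, geom$total_length, max_retries))
}

.pair_dist_2d <- function(pts, metric, rot = 0) {
  if (metric == "euclidean") {
    as.matrix(dist(pts[, 1:2, drop = FALSE]))
  } else {
    ca <- cos(rot); sa <- sin(rot)
    xr <- ca * pts[, 1] - sa * pts[, 2]
    yr <- sa * pts[, 1] + ca * pts[, 2]
    pmax(abs(outer(xr, xr, "-")), abs(outer(yr, yr, "-")))
  }
}

# push violating pairs apart in the projection, re-projecting into the body;
# returns NULL when the configuration does not converge
.relax_separation <- function(geom, pts, s, metric, rot = 0, max_iter = 150) {
  ca <- cos(rot); sa <- sin(rot)
  for (it in seq_len(max_iter)) {
    d <- .pair_dist_2d(pts, metric, rot)
    diag(d) <- Inf
    viol <- which(d < s, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol) == 0) return(pts)
    for (v in seq_len(nrow(viol))) {
      i <- viol[v, 1]; j <- viol[v, 2]
      dx <- pts[j, 1] - pts[i, 1]; dy <- pts[j, 2] - pts[i, 2]
      if (metric == "euclidean") {
        dd <- sqrt(dx^2 + dy^2)
        dir <- if (dd < 1e-9) {
          a <- runif(1, 0, 2 * pi); c(cos(a), sin(a))
        } else c(dx, dy) / dd
        push <- (s - dd) / 2 * 1.05
      } else {
        # work in the rotated (image) frame, push along the dominating
        # coordinate, rotate the push back to the local frame
        dxr <- ca * dx - sa * dy; dyr <- sa * dx + ca * dy
        if (abs(dxr) >= abs(dyr)) {
          dir_r <- c(if (dxr == 0) sample(c(-1, 1), 1) else sign(dxr), 0)
          push <- (s - abs(dxr)) / 2 * 1.05
        } else {
          dir_r <- c(0, sign(dyr))
          push <- (s - abs(dyr)) / 2 * 1.05
        }
        dir <- c(ca * dir_r[1] + sa * dir_r[2],
                 -sa * dir_r[1] + ca * dir_r[2])
      }
      pts[i, 1:2] <- pts[i, 1:2] - dir * push
      pts[j, 1:2] <- pts[j, 1:2] + dir * push
      pts[i, ] <- .project_into_spherocyl(geom, pts[i, ])
      pts[j, ] <- .project_into_spherocyl(geom, pts[j, ])
    }
  }
  NULL
}

.project_into_spherocyl <- function(geom, p) {
  L <- geom$cyl_length; r <- geom$radius * 0.999
  if (abs(p[1]) <= L / 2) {
    ryz <- sqrt(p[2]^2 + p[3]^2)
    if (ryz > r) p[2:3] <- p[2:3] * r / ryz
  } else {
    cx <- sign(p[1]) * L / 2
    d <- c(p[1] - cx, p[2], p[3])
    dd <- sqrt(sum(d^2))
    if (dd > r) p <- c(cx, 0, 0) + d * (r / dd)
  }
  p
}

.draw_uniform_spherocyl <- function(geom, count) {
  L <- geom$cyl_length; r <- geom$radius
  p_cap <- (4 * r / 3) / (L + 4 * r / 3)
  in_cap <- runif(count) < p_cap
  pts <- matrix(0, count, 3, dimnames = list(NULL, c("x", "y", "z")))
  n_cyl <- sum(!in_cap)
  if (n_cyl > 0) {
    # uniform in the disc via sqrt-radius, uniform along the axis
    rr <- r * sqrt(runif(n_cyl)); th <- runif(n_cyl, 0, 2 * pi)
    pts[!in_cap, ] <- cbind(runif(n_cyl, -L / 2, L / 2),
                            rr * cos(th), rr * sin(th))
  }
  n_cap <- sum(in_cap)
  if (n_cap > 0) {
    # uniform in the sphere; attach to the pole matching the axial sign
    rr <- r * runif(n_cap)^(1 / 3)
    u <- runif(n_cap, -1, 1); th <- runif(n_cap, 0, 2 * pi)
    sx <- rr * u; sy <- rr * sqrt(1 - u^2) * cos(th)
    sz <- rr * sqrt(1 - u^2) * sin(th)
    pole <- ifelse(sx >= 0, L / 2, -L / 2)
    pts[in_cap, ] <- cbind(pole + sx, sy, sz)
  }
  pts
}

#' Transform cell-local molecule coordinates to field coordinates
#'
#' Rotates by the cell orientation, translates by the cell center, and lifts
#' the optical-axis coordinate so the cell rests on the coverslip: the
#' returned z is `radius + z_local`, in `[0, 2 * radius]`.
#'
#' @param geom A [spherocylinder()].
#' @param pts Matrix of cell-local (x, y, z) positions, as returned by
#'   [sample_molecule_positions()].
#' @return Matrix of field-frame (x, y, z) positions in um.
#' @export
to_field_coordinates <- function(geom, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  ca <- cos(geom$orientation); sa <- sin(geom$orientation)
  cbind(x = geom$center[1] + ca * pts[, 1] - sa * pts[, 2],
        y = geom$center[2] + sa * pts[, 1] + ca * pts[, 2],
        z = geom$radius + pts[, 3])
}

#' Sample per-cell molecule copy numbers
#'
#' Copy numbers are modelled as Poisson with mean `mean`, the standard model
#' for low-abundance protein counts across a clonal population.
#'
#' @param mean Poisson mean (>= 0).
#' @param n Number of cells.
#' @param rng_seed Optional integer seed.
#' @return Integer vector of `n` independent Poisson draws.
#' @export
sample_poisson_counts <- function(mean, n, rng_seed = NULL) {
  if (!is.numeric(mean) || length(mean) != 1L || mean < 0)
    abort("`mean` must be a single number >= 0.")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rpois(n, mean)
}
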