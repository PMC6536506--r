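#' Rasterize the 2D footprint of spherocylinder cells
#'
#' A pixel belongs to a cell footprint when its center lies within `radius`
#' of the cell's axis segment. Pixel centers are at `(i - 0.5) * pixel_size`
#' (row i maps to the field y coordinate, column j to x).
#'
#' @param cells List of [spherocylinder()].
#' @param dims Integer (rows, cols) of the image.
#' @param pixel_size um per pixel.
#' @return Integer label matrix: 0 outside, the cell index inside.
#' @export
footprint_mask <- function(cells, dims, pixel_size) {
  lab <- matrix(0L, dims[1], dims[2])
  if (!length(cells)) return(lab)
  for (k in seq_along(cells)) {
    g <- cells[[k]]
    e <- .axis_endpoints(g)
    # bounding box in pixels
    xmin <- min(e$a[1], e$b[1]) - g$radius; xmax <- max(e$a[1], e$b[1]) + g$radius
    ymin <- min(e$a[2], e$b[2]) - g$radius; ymax <- max(e$a[2], e$b[2]) + g$radius
    j0 <- max(1L, floor(xmin / pixel_size)); j1 <- min(dims[2], ceiling(xmax / pixel_size) + 1L)
    i0 <- max(1L, floor(ymin / pixel_size)); i1 <- min(dims[1], ceiling(ymax / pixel_size) + 1L)
    if (j1 < j0 || i1 < i0) next
    jj <- j0:j1; ii <- i0:i1
    px <- (jj - 0.5) * pixel_size; py <- (ii - 0.5) * pixel_size
    # distance of each pixel center to the axis segment
    d <- e$b - e$a; L2 <- sum(d * d)
    PX <- matrix(px, length(ii), length(jj), byrow = TRUE)
    PY <- matrix(py, length(ii), length(jj))
    if (L2 < 1e-12) {
      dist2 <- (PX - e$a[1])^2 + (PY - e$a[2])^2
    } else {
      t <- ((PX - e$a[1]) * d[1] + (PY - e$a[2]) * d[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      dist2 <- (PX - (e$a[1] + t * d[1]))^2 + (PY - (e$a[2] + t * d[2]))^2
    }
    inside <- dist2 <= g$radius^2
    sub <- lab[ii, jj, drop = FALSE]
    sub[inside & sub == 0L] <- k
    lab[ii, jj] <- sub
  }
  lab
}

# add one pixel-integrated 2D Gaussian (total mass `photons`) to `img`
.add_gaussian <- function(img, x_um, y_um, sigma_um, photons, pixel_size) {
  s <- sigma_um
  r <- ceiling((4 * s) / pixel_size) + 1L
  jc <- ceiling(x_um / pixel_size); ic <- ceiling(y_um / pixel_size)
  jj <- max(1L, jc - r):min(ncol(img), jc + r)
  ii <- max(1L, ic - r):min(nrow(img), ic + r)
  if (!length(jj) || !length(ii)) return(img)
  fx <- pnorm((jj * pixel_size - x_um) / s) - pnorm(((jj - 1) * pixel_size - x_um) / s)
  fy <- pnorm((ii * pixel_size - y_um) / s) - pnorm(((ii - 1) * pixel_size - y_um) / s)
  img[ii, jj] <- img[ii, jj] + photons * (fy %o% fx)
  img
}

.apply_camera_noise <- function(img, optics) {
  if (optics$shot_noise) {
    img[] <- rpois(length(img), lambda = pmax(img, 0))
  }
  if (optics$read_noise_sd > 0) {
    img[] <- img + rnorm(length(img), 0, optics$read_noise_sd)
  }
  img
}

#' Render a synthetic fluorescence z-stack
#'
#' Each molecule is drawn as a pixel-integrated 2D Gaussian on every plane;
#' its width grows linearly with the defocus distance between the molecule's
#' z position and the plane's focal z (planes sit at `(p - 1) * z_spacing`).
#' The integrated signal per plane is `photons_per_molecule`. Pixel values are
#' `background_level + signal`, then Poisson shot noise and additive Gaussian
#' read noise per the optics configuration. The first plane additionally
#' carries a uniform autofluorescence-like haze inside cell footprints, which
#' is why downstream spot counting excludes that plane from the maximum
#' projection.
#'
#' @param cells List of [spherocylinder()] (used for the plane-1 haze
#'   footprints).
#' @param positions Matrix of molecule positions in field coordinates
#'   (columns x, y, z in um), e.g. rows of [to_field_coordinates()] output.
#' @param optics An [optics_config()].
#' @param field_size Field extent (x, y), um.
#' @param haze_level Amplitude of the plane-1 in-cell haze, counts.
#' @param rng_seed Optional integer seed.
#' @return An [image_stack()] with `optics$n_planes` planes.
#' @export
render_zstack <- function(cells, positions, optics = optics_config(),
                          field_size = c(40, 40), haze_level = 40,
                          rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  positions <- matrix(as.numeric(positions), ncol = 3)
  dims <- c(round(field_size[2] / optics$pixel_size),
            round(field_size[1] / optics$pixel_size))
  if (nrow(positions) &&
      (any(positions[, 1] < 0 | positions[, 1] > field_size[1]) ||
       any(positions[, 2] < 0 | positions[, 2] > field_size[2])))
    abort("Molecule positions outside the field.")
  planes <- vector("list", optics$n_planes)
  foot <- if (length(cells)) footprint_mask(cells, dims, optics$pixel_size)
  for (p in seq_len(optics$n_planes)) {
    zp <- (p - 1) * optics$z_spacing
    img <- matrix(optics$background_level, dims[1], dims[2])
    if (p == 1L && length(cells) && haze_level > 0)
      img <- img + haze_level * (foot > 0)
    if (nrow(positions)) {
      for (m in seq_len(nrow(positions))) {
        sig <- optics$psf_sigma *
          (1 + optics$defocus_scale * abs(positions[m, 3] - zp))
        img <- .add_gaussian(img, positions[m, 1], positions[m, 2], sig,
                             optics$photons_per_molecule, optics$pixel_size)
      }
    }
    planes[[p]] <- .apply_camera_noise(img, optics)
  }
  image_stack(planes, pixel_size = optics$pixel_size,
              z_spacing = optics$z_spacing, axis = "z")
}

#' Render a synthetic autofluorescence (segmentation) image
#'
#' Emulates the green-channel autofluorescence used to find cells: a single
#' frame whose mean intensity is elevated by `amplitude` inside every cell
#' footprint, with the camera noise model applied.
#'
#' @inheritParams render_zstack
#' @param amplitude In-cell intensity elevation, counts.
#' @return Numeric matrix `[row, col]`.
#' @export
render_autofluorescence <- function(cells, optics = optics_config(),
                                    field_size = c(40, 40), amplitude = 100,
                                    rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dims <- c(round(field_size[2] / optics$pixel_size),
            round(field_size[1] / optics$pixel_size))
  img <- matrix(optics$background_level, dims[1], dims[2])
  if (length(cells)) {
    foot <- footprint_mask(cells, dims, optics$pixel_size)
    img <- img + amplitude * (foot > 0)
  }
  .apply_camera_noise(img, optics)
}
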