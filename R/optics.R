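#' Optical and camera model for the synthetic generator
#'
#' Defaults describe a conventional epifluorescence setup: a 100x / NA 1.45
#' objective with a 16-um-pixel EMCCD gives 0.16 um/pixel; the lateral PSF is
#' approximated as a 2D Gaussian with sigma = 0.21 * lambda / NA ~ 0.084 um
#' for ~580 nm emission (consistent with a ~250 nm two-point resolution
#' limit); z-stacks are 4-5 planes spaced 200 nm. Defocus widens the Gaussian
#' linearly: sigma(dz) = psf_sigma * (1 + defocus_scale * |dz|).
#'
#' @param pixel_size um per pixel.
#' @param psf_sigma In-focus lateral Gaussian PSF sigma, um.
#' @param z_spacing um between z planes.
#' @param n_planes Number of z planes (default 5).
#' @param defocus_scale PSF-sigma growth per um of defocus (1/um).
#' @param photons_per_molecule Expected integrated signal per molecule per
#'   plane, camera counts.
#' @param background_level Mean background, counts.
#' @param read_noise_sd Gaussian read noise SD, counts (0 disables).
#' @param shot_noise Apply Poisson shot noise to background + signal?
#'
#' @return A validated list of class `optics_config`.
#' @export
optics_config <- function(pixel_size = 0.16,
                          psf_sigma = 0.084,
                          z_spacing = 0.2,
                          n_planes = 5,
                          defocus_scale = 3,
                          photons_per_molecule = 5000,
                          background_level = 100,
                          read_noise_sd = 2,
                          shot_noise = TRUE) {
  vals <- c(pixel_size = pixel_size, psf_sigma = psf_sigma,
            z_spacing = z_spacing, n_planes = n_planes,
            defocus_scale = defocus_scale,
            photons_per_molecule = photons_per_molecule,
            background_level = background_level)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  bad <- setdiff(bad, c("background_level", "defocus_scale"))  # these may be 0
  if (background_level < 0) bad <- c(bad, "background_level")
  if (defocus_scale < 0) bad <- c(bad, "defocus_scale")
  if (read_noise_sd < 0) bad <- c(bad, "read_noise_sd")
  if (length(bad))
    abort(paste0("Invalid optics parameters: ", paste(bad, collapse = ", ")))
  if (n_planes < 1 || n_planes != round(n_planes))
    abort("`n_planes` must be a positive integer.")
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 z_spacing = z_spacing, n_planes = as.integer(n_planes),
                 defocus_scale = defocus_scale,
                 photons_per_molecule = photons_per_molecule,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "optics_config")
}

#' Image stack container
#'
#' A light container for a z- (or time-) stack: a 3D numeric array indexed
#' `[plane, row, col]` plus pixel-size and plane-spacing metadata.
#'
#' @param data 3D array `[plane, row, col]`, or a list of equally sized
#'   matrices.
#' @param pixel_size um per pixel.
#' @param z_spacing um (or seconds for time series) between planes.
#' @param axis `"z"` or `"t"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size = 0.16, z_spacing = 0.2,
                        axis = c("z", "t")) {
  axis <- match.arg(axis)
  if (is.list(data)) {
    dims <- vapply(data, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      abort("All pages must have identical dimensions.")
    arr <- array(0, c(length(data), dims[1, 1], dims[2, 1]))
    for (i in seq_along(data)) arr[i, , ] <- data[[i]]
    data <- arr
  }
  if (length(dim(data)) != 3) abort("`data` must be a 3D array (plane, row, col).")
  structure(list(data = data, pixel_size = pixel_size, z_spacing = z_spacing,
                 axis = axis),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d plane(s) of %d x %d px (%.3g um/px, %s-spacing %.3g)\n",
              d[1], d[2], d[3], x$pixel_size, x$axis, x$z_spacing))
  invisible(x)
}

#' Number of planes in a stack
#' @param stack An [image_stack()].
#' @return Integer plane count.
#' @export
n_planes <- function(stack) dim(stack$data)[1]

#' Extract one plane of a stack as a matrix
#' @param stack An [image_stack()].
#' @param i Plane index (1-based).
#' @return Numeric matrix `[row, col]`.
#' @export
get_plane <- function(stack, i) stack$data[i, , ]
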